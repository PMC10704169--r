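#' Pipeline run configuration
#'
#' Defaults are the standard parameters of the workflow: 0.01 / 0.05 Da
#' annotation tolerances with a 70% total-score threshold, 10x blank
#' filtering, 0.7 min alignment RT tolerance with 0.8 min maximum
#' internal-standard deviation, and the networking settings of
#' [network_config()]. Unknown keys in a config file are rejected.
#'
#' @param path optional YAML file overriding the defaults.
#' @return nested `run_config` list.
#' @export
run_config <- function(path = NULL) {
  defaults <- list(
    seed = 42L,
    filter = list(min_peak_height = 3000, align_rt_tol = 0.7,
                  align_mz_tol = 0.05, mass_slice_width = 0.1,
                  blank_factor = 10, rt_correction_max_dev = 0.8),
    annotation = list(ms1_tol = 0.01, ms2_tol = 0.05, threshold = 70),
    network = list(frag_mz_tol = 0.05, precursor_mz_tol = 0.05,
                   topk = 6, window = 50, precursor_exclusion = 17,
                   min_cosine = 0.7, min_matched_peaks = 6,
                   min_component_size = 4, min_node_mz = 500),
    analysis = list(linkages = c("complete", "single", "ward", "average"),
                    k = 3, n_components = 2)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    defaults <- .merge_config(defaults, user, "")
  }
  structure(defaults, class = "run_config")
}

.merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- .merge_config(base[[key]], user[[key]],
                                   paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

.artifact <- function(out_dir, name, producer) {
  path <- file.path(out_dir, name)
  if (!file.exists(path)) {
    stop("missing artifact '", name, "'; run the '", producer,
         "' stage first")
  }
  path
}

.log <- function(...) message("[halolipid ", format(Sys.time(), "%H:%M:%S"),
                              "] ", ...)

#' Run one pipeline stage
#'
#' Stages: `build-library` (species table + MSP), `simulate` (synthetic
#' input bundle), `annotate` (library matching, unique lipids, class
#' summary), `cores` (core-lipid profile and chain statistics), `network`
#' (molecular network, categories, GraphML), `chemotax` (clustering,
#' concordance against the 16S NJ tree, PCA, VIP), `report` (aggregate
#' table). Stages are deterministic given identical config and seed, and
#' read only artifacts written by earlier stages into `out_dir`.
#'
#' @param stage stage name.
#' @param config a [run_config()].
#' @param out_dir artifact directory (created if needed).
#' @return invisibly, a list of artifact paths (or the report data frame).
#' @export
run_stage <- function(stage = c("build-library", "simulate", "annotate",
                                "cores", "network", "chemotax", "report"),
                      config = run_config(), out_dir = "halolipid_out") {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log("stage=", stage, " package=halolipid ",
       as.character(utils::packageVersion("halolipid")),
       " seed=", config$seed)
  switch(stage,
    "build-library" = .stage_build_library(config, out_dir),
    "simulate" = .stage_simulate(config, out_dir),
    "annotate" = .stage_annotate(config, out_dir),
    "cores" = .stage_cores(config, out_dir),
    "network" = .stage_network(config, out_dir),
    "chemotax" = .stage_chemotax(config, out_dir),
    "report" = .stage_report(config, out_dir)
  )
}

.stage_build_library <- function(config, out_dir) {
  species <- enumerate_library()
  lib <- build_spectral_library(species)
  utils::write.table(species, file.path(out_dir, "species.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  export_msp(lib, file.path(out_dir, "library.msp"))
  .log("library: ", nrow(species), " species, ", length(lib), " spectra")
  invisible(list(species = file.path(out_dir, "species.tsv"),
                 msp = file.path(out_dir, "library.msp")))
}

.stage_simulate <- function(config, out_dir) {
  sim <- simulate_lipidome(config = sim_config(seed = config$seed))
  write_feature_table(sim$features, file.path(out_dir, "features.csv"))
  write_sample_metadata(sim$samples, file.path(out_dir, "samples.tsv"))
  write_mgf(sim$spectra, file.path(out_dir, "spectra.mgf"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(paste0(">", names(sim$alignment), "\n", sim$alignment),
             file.path(out_dir, "sixteen_s.fasta"))
  writeLines(sim$is_feature_id, file.path(out_dir, "internal_standard.txt"))
  .log("simulated ", nrow(sim$features), " features, ",
       length(sim$spectra), " MS2 spectra")
  invisible(list(features = file.path(out_dir, "features.csv")))
}

.stage_annotate <- function(config, out_dir) {
  msp <- .artifact(out_dir, "library.msp", "build-library")
  features <- read_feature_table(.artifact(out_dir, "features.csv",
                                           "simulate"))
  samples <- read_sample_metadata(.artifact(out_dir, "samples.tsv",
                                            "simulate"))
  spectra <- read_mgf(.artifact(out_dir, "spectra.mgf", "simulate"))
  lib <- read_msp(msp)
  lib <- lapply(lib, function(e) {
    e$lipid_class <- sub("\\(.*$", "", e$species)
    e
  })
  features <- blank_filter(features, samples,
                           config$filter$blank_factor)
  is_fid <- readLines(file.path(out_dir, "internal_standard.txt"))
  quant <- semi_quantify(features, samples, is_feature_id = is_fid,
                         spike_amount = 50)
  ann <- annotate_features(features, spectra, lib,
                           ms1_tol = config$annotation$ms1_tol,
                           ms2_tol = config$annotation$ms2_tol,
                           threshold = config$annotation$threshold)
  uniq <- collapse_unique(ann, quant, samples, enumerate_library())
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(uniq, file.path(out_dir, "unique_lipids.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cs <- class_summary(uniq)
  utils::write.table(cs$per_group, file.path(out_dir, "class_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .log("annotated ", sum(ann$accepted), " features -> ", cs$total,
       " unique lipids")
  invisible(list(annotations = file.path(out_dir, "annotations.tsv")))
}

.stage_cores <- function(config, out_dir) {
  uniq <- utils::read.delim(.artifact(out_dir, "unique_lipids.tsv",
                                      "annotate"), check.names = FALSE)
  samples <- read_sample_metadata(.artifact(out_dir, "samples.tsv",
                                            "simulate"))
  prof <- to_core_profile(uniq, samples)
  st <- core_profile_stats(prof)
  utils::write.table(prof, file.path(out_dir, "core_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(st, file.path(out_dir, "core_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .log("core profile over ", nrow(prof), " core variants")
  invisible(list(core_stats = file.path(out_dir, "core_stats.tsv")))
}

.stage_network <- function(config, out_dir) {
  features <- read_feature_table(.artifact(out_dir, "features.csv",
                                           "simulate"))
  samples <- read_sample_metadata(.artifact(out_dir, "samples.tsv",
                                            "simulate"))
  spectra <- read_mgf(.artifact(out_dir, "spectra.mgf", "simulate"))
  ann <- utils::read.delim(.artifact(out_dir, "annotations.tsv",
                                     "annotate"))
  nc <- do.call(network_config, config$network)
  net <- build_network(spectra, nc)
  blank_ids <- samples$sample_id[samples$role == "blank"]
  in_blank <- features$feature_id[
    apply(features[, blank_ids, drop = FALSE], 1, max) > 0]
  net <- filter_network(net, in_blank, nc)
  sample_meta <- samples[samples$role == "sample", ]
  occ <- do.call(rbind, lapply(unique(sample_meta$strain), function(st) {
    ids <- sample_meta$sample_id[sample_meta$strain == st]
    present <- features$feature_id[
      apply(features[, ids, drop = FALSE], 1, max) > 0]
    if (length(present) == 0) return(NULL)
    data.frame(feature_id = present, strain = st)
  }))
  taxa <- data.frame(strain = unique(sample_meta$strain))
  taxa$taxon <- sub("_.*", "", taxa$strain)
  cat_ <- categorize_components(net, ann, occ, taxa)
  summ <- network_summary(net, ann$feature_id[ann$accepted])
  write_graphml(net, file.path(out_dir, "network.graphml"), ann, cat_)
  utils::write.table(cat_, file.path(out_dir, "network_categories.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(summ),
                     file.path(out_dir, "network_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .log("network: ", summ$n_nodes, " nodes (", summ$n_identified,
       " identified, ", summ$n_analogs, " analogs, ", summ$n_new, " new)")
  invisible(list(graphml = file.path(out_dir, "network.graphml")))
}

.stage_chemotax <- function(config, out_dir) {
  uniq <- utils::read.delim(.artifact(out_dir, "unique_lipids.tsv",
                                      "annotate"), check.names = FALSE)
  samples <- read_sample_metadata(.artifact(out_dir, "samples.tsv",
                                            "simulate"))
  aln_path <- .artifact(out_dir, "sixteen_s.fasta", "simulate")
  mat <- strain_matrix(uniq, samples)
  prepared <- prepare_matrix(mat, "cluster")
  nj <- nj_tree(p_distance(aln_path))
  res <- list()
  for (lk in config$analysis$linkages) {
    hc <- hcluster(prepared, lk)
    writeLines(dendrogram_newick(hc),
               file.path(out_dir, paste0("dendrogram_", lk, ".nwk")))
    orders <- stats::setNames(
      vapply(default_profiles(), `[[`, character(1), "order"),
      vapply(default_profiles(), `[[`, character(1), "strain"))
    cc <- concordance(hc, orders[colnames(prepared)],
                      k = config$analysis$k, ref_tree = nj)
    res[[lk]] <- data.frame(linkage = lk, ari = cc$ari, rf = cc$rf)
  }
  conc <- do.call(rbind, res)
  utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(ape::write.tree(nj), file.path(out_dir, "nj_16s.nwk"))
  orders <- stats::setNames(
    vapply(default_profiles(), `[[`, character(1), "order"),
    vapply(default_profiles(), `[[`, character(1), "strain"))
  # VIP on replicate-level samples so every order has several observations
  samp <- samples[samples$role == "sample", ]
  smat <- as.matrix(uniq[, samp$sample_id, drop = FALSE])
  rownames(smat) <- uniq$species
  vip <- plsda_vip(prepare_matrix(smat, "ordination"),
                   orders[samp$strain], config$analysis$n_components)
  utils::write.table(vip, file.path(out_dir, "vip.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  .log("chemotaxonomy: ARI by linkage ",
       paste(sprintf("%s=%.2f", conc$linkage, conc$ari), collapse = " "))
  invisible(list(concordance = file.path(out_dir, "concordance.tsv")))
}

.stage_report <- function(config, out_dir) {
  features <- read_feature_table(.artifact(out_dir, "features.csv",
                                           "simulate"))
  spectra <- read_mgf(.artifact(out_dir, "spectra.mgf", "simulate"))
  ann <- utils::read.delim(.artifact(out_dir, "annotations.tsv",
                                     "annotate"))
  summ <- utils::read.delim(.artifact(out_dir, "network_summary.tsv",
                                      "network"))
  conc <- utils::read.delim(.artifact(out_dir, "concordance.tsv",
                                      "chemotax"))
  cs <- utils::read.delim(.artifact(out_dir, "class_summary.tsv",
                                    "annotate"))
  cov <- summarize_coverage(
    features, spectra, ann,
    network_ids = character(0))
  cov <- coverage_stats(cov$n_features, cov$n_with_ms2, cov$n_annotated,
                        summ$n_nodes)
  report <- data.frame(
    metric = c("n_features", "n_with_ms2", "n_annotated", "pct_annotated",
               "n_network", "pct_network", "n_unique_lipids",
               paste0("ari_", conc$linkage)),
    value = c(cov$n_features, cov$n_with_ms2, cov$n_annotated,
              cov$pct_annotated, cov$n_network, cov$pct_network,
              sum(cs$n), conc$ari))
  utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  .log("report written: ", file.path(out_dir, "report.tsv"))
  invisible(report)
}

#' Run the full pipeline end to end
#'
#' @param config a [run_config()].
#' @param out_dir artifact directory.
#' @return the report data frame, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         out_dir = "halolipid_out") {
  for (st in c("build-library", "simulate", "annotate", "cores",
               "network", "chemotax", "report")) {
    res <- run_stage(st, config, out_dir)
  }
  invisible(res)
}
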