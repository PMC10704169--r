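# Greedy nearest-m/z peak matching: every peak used at most once; candidate
# pairs within tol are assigned in order of increasing m/z difference.
.match_peaks <- function(query, lib, tol) {
  nq <- nrow(query); nl <- nrow(lib)
  if (nq == 0 || nl == 0) {
    return(data.frame(q = integer(0), l = integer(0)))
  }
  pairs <- list()
  for (i in seq_len(nq)) {
    d <- abs(lib$mz - query$mz[i])
    for (j in which(d <= tol)) {
      pairs[[length(pairs) + 1L]] <- c(i, j, d[j])
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(q = integer(0), l = integer(0)))
  }
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 3]), , drop = FALSE]
  used_q <- logical(nq); used_l <- logical(nl)
  qs <- ls_ <- integer(0)
  for (k in seq_len(nrow(pm))) {
    i <- pm[k, 1]; j <- pm[k, 2]
    if (used_q[i] || used_l[j]) next
    used_q[i] <- TRUE; used_l[j] <- TRUE
    qs <- c(qs, i); ls_ <- c(ls_, j)
  }
  data.frame(q = qs, l = ls_)
}

# Four component scores in [0,1]: MS1 gaussian similarity, dot product and
# reverse dot product on square-root intensities, matched library-peak
# fraction.
.score_components <- function(dmz, query, lib, ms1_tol, ms2_tol) {
  sigma <- ms1_tol / 2
  ms1_sim <- exp(-0.5 * (dmz / sigma)^2)
  m <- .match_peaks(query, lib, ms2_tol)
  q <- sqrt(query$intensity); l <- sqrt(lib$intensity)
  num <- sum(q[m$q] * l[m$l])
  dot <- if (num == 0) 0 else num / (sqrt(sum(q^2)) * sqrt(sum(l^2)))
  rev <- if (num == 0) 0 else
    num / (sqrt(sum(q[m$q]^2)) * sqrt(sum(l^2)))
  frac <- nrow(m) / nrow(lib)
  c(ms1_sim = ms1_sim, dot = dot, rev_dot = rev, frac = frac,
    n_matched = nrow(m))
}

#' Match one feature against the spectral library
#'
#' Candidates are library entries whose precursor lies within `ms1_tol` of
#' the feature m/z. The total score is 100 x the unweighted mean of four
#' components: a gaussian MS1 similarity (sigma = `ms1_tol`/2), dot product
#' and reverse dot product on square-root-transformed intensities with
#' greedy nearest-m/z peak matching at `ms2_tol` (each peak used once), and
#' the matched fraction of library peaks. Candidates are ranked by total
#' score, then smaller MS1 error, then name. A candidate is accepted when
#' its total score exceeds `threshold` and the feature carries MS2; without
#' MS2 the MS1-only candidates are returned flagged and never accepted.
#'
#' @param feature_mz observed feature m/z.
#' @param peaks MS2 peak data frame (`mz`, `intensity`) or `NULL`.
#' @param library list of library spectra ([build_spectral_library()] or
#'   [read_msp()]).
#' @param ms1_tol,ms2_tol mass tolerances in Da.
#' @param threshold total-score acceptance threshold (percent).
#' @return data frame of scored candidates (possibly empty).
#' @export
match_feature <- function(feature_mz, peaks, library, ms1_tol = 0.01,
                          ms2_tol = 0.05, threshold = 70) {
  res <- list()
  for (entry in library) {
    dmz <- feature_mz - entry$precursor_mz
    if (abs(dmz) > ms1_tol) next
    if (is.null(peaks) || nrow(peaks) == 0) {
      res[[length(res) + 1L]] <- data.frame(
        species = entry$species, adduct = entry$adduct,
        lipid_class = entry$lipid_class, ms1_error = dmz,
        ms1_sim = 100 * exp(-0.5 * (dmz / (ms1_tol / 2))^2),
        dot = NA_real_, rev_dot = NA_real_, frac = NA_real_,
        n_matched = 0L, total = NA_real_, ms1_only = TRUE,
        accepted = FALSE)
      next
    }
    sc <- .score_components(dmz, peaks, entry$peaks, ms1_tol, ms2_tol)
    total <- 100 * mean(sc[c("ms1_sim", "dot", "rev_dot", "frac")])
    res[[length(res) + 1L]] <- data.frame(
      species = entry$species, adduct = entry$adduct,
      lipid_class = entry$lipid_class, ms1_error = dmz,
      ms1_sim = 100 * sc[["ms1_sim"]], dot = 100 * sc[["dot"]],
      rev_dot = 100 * sc[["rev_dot"]], frac = 100 * sc[["frac"]],
      n_matched = as.integer(sc[["n_matched"]]), total = total,
      ms1_only = FALSE, accepted = total > threshold)
  }
  if (length(res) == 0) {
    return(data.frame(species = character(0), adduct = character(0),
                      lipid_class = character(0), ms1_error = numeric(0),
                      ms1_sim = numeric(0), dot = numeric(0),
                      rev_dot = numeric(0), frac = numeric(0),
                      n_matched = integer(0), total = numeric(0),
                      ms1_only = logical(0), accepted = logical(0)))
  }
  out <- do.call(rbind, res)
  ord <- order(-ifelse(is.na(out$total), -Inf, out$total),
               abs(out$ms1_error), out$species)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a feature table against the library
#'
#' Scores every MS2-bearing feature with [match_feature()] and keeps the
#' best candidate per feature. Accepted hits missing a class-required
#' diagnostic ion (e.g. the tentative PI head-group ion at m/z 261.038) are
#' flagged `tentative`. An optional curation list (feature ids) rejects
#' annotations judged to be false positives or in-source fragments.
#'
#' @param features aligned feature data frame.
#' @param spectra MGF spectra list keyed by `feature_id`.
#' @param library spectral library list.
#' @param ms1_tol,ms2_tol,threshold see [match_feature()].
#' @param rules fragmentation rules (for diagnostic-ion tentativeness).
#' @param curation character vector of feature ids whose annotations are
#'   rejected.
#' @return annotation table, one row per MS2-bearing feature with at least
#'   one candidate.
#' @export
annotate_features <- function(features, spectra, library, ms1_tol = 0.01,
                              ms2_tol = 0.05, threshold = 70,
                              rules = fragmentation_rules(),
                              curation = character(0)) {
  spec_by_id <- stats::setNames(
    spectra, vapply(spectra, function(s) s$feature_id, character(1)))
  diag_rules <- rules[rules$kind == "diagnostic_ion", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(features))) {
    fid <- features$feature_id[i]
    sp <- spec_by_id[[fid]]
    if (is.null(sp)) next
    cand <- match_feature(features$mz[i], sp$peaks, library,
                          ms1_tol, ms2_tol, threshold)
    if (nrow(cand) == 0) next
    best <- cand[1, , drop = FALSE]
    tentative <- FALSE
    if (best$accepted && nrow(diag_rules) > 0) {
      dr <- diag_rules[diag_rules$lipid_class %in%
                         c("*", best$lipid_class), , drop = FALSE]
      dr <- dr[dr$lipid_class != "*", , drop = FALSE]
      for (k in seq_len(nrow(dr))) {
        ion <- if (!is.na(dr$mz[k])) as.numeric(dr$mz[k]) else
          monoisotopic_mass(comp_parse(dr$formula[k])) +
            adduct_delta("[M+H]+")
        if (!any(abs(sp$peaks$mz - ion) <= ms2_tol)) tentative <- TRUE
      }
    }
    best$tentative <- tentative
    best$curated_out <- fid %in% curation
    if (best$curated_out) best$accepted <- FALSE
    best <- cbind(data.frame(feature_id = fid), best)
    out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0) {
    return(data.frame(feature_id = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse accepted annotations to unique lipids
#'
#' Features annotated to the same species -- regardless of adduct form or
#' retention-time isomerism -- merge into one unique lipid; their per-sample
#' intensities are summed. Species attributes (class, core chains,
#' unsaturation) are joined from the species table.
#'
#' @param annotations annotation table from [annotate_features()].
#' @param features aligned feature table with intensity columns.
#' @param samples sample metadata.
#' @param species_table species attributes from [enumerate_library()].
#' @return data frame of unique lipids with summed per-sample abundances and
#'   a semicolon-separated `members` column.
#' @export
collapse_unique <- function(annotations, features, samples, species_table) {
  acc <- annotations[annotations$accepted, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted annotations to collapse")
  sample_ids <- samples$sample_id[samples$role == "sample"]
  out <- list()
  for (spn in sort(unique(acc$species))) {
    rows <- acc[acc$species == spn, , drop = FALSE]
    if (length(unique(rows$lipid_class)) != 1L) {
      stop("conflicting class assignments within species group ", spn)
    }
    meta <- species_table[species_table$name == spn, , drop = FALSE]
    if (nrow(meta) != 1L) stop("species not found in species table: ", spn)
    fidx <- match(rows$feature_id, features$feature_id)
    abund <- colSums(features[fidx, sample_ids, drop = FALSE])
    rec <- data.frame(species = spn, lipid_class = meta$lipid_class,
                      class_group = meta$class_group,
                      chain1 = meta$chain1, chain2 = meta$chain2,
                      unsat = meta$unsat, n_cores = meta$n_cores,
                      n_members = nrow(rows),
                      members = paste(rows$feature_id, collapse = ";"))
    out[[length(out) + 1L]] <- cbind(rec, as.data.frame(t(abund)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Semi-quantification against a spiked internal standard
#'
#' Abundance is intensity relative to the internal-standard intensity in the
#' same sample, times the spiked amount. Response factors are fixed at 1
#' (no compound-specific calibration).
#'
#' @param features feature data frame with intensity columns.
#' @param samples sample metadata.
#' @param is_feature_id feature id of the internal standard, or `NULL` to
#'   locate it by `is_mz`.
#' @param is_mz internal-standard m/z (nearest feature within `mz_tol`).
#' @param spike_amount spiked amount (abundance units).
#' @param mz_tol m/z window for locating the standard.
#' @return features with intensity columns replaced by semi-quantified
#'   abundances (the standard's own row is dropped).
#' @export
semi_quantify <- function(features, samples, is_feature_id = NULL,
                          is_mz = NULL, spike_amount = 1, mz_tol = 0.01) {
  if (is.null(is_feature_id)) {
    stopifnot(!is.null(is_mz))
    d <- abs(features$mz - is_mz)
    if (min(d) > mz_tol) stop("internal standard not found near m/z ", is_mz)
    is_row <- which.min(d)
  } else {
    is_row <- match(is_feature_id, features$feature_id)
    if (is.na(is_row)) stop("internal standard feature not found: ",
                            is_feature_id)
  }
  sample_ids <- samples$sample_id[samples$role == "sample"]
  is_int <- unlist(features[is_row, sample_ids])
  missing <- sample_ids[is.na(is_int) | is_int <= 0]
  if (length(missing) > 0) {
    stop("internal standard missing in sample(s): ",
         paste(missing, collapse = ", "))
  }
  for (sid in sample_ids) {
    features[[sid]] <- features[[sid]] / is_int[[sid]] * spike_amount
  }
  out <- features[-is_row, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class and per-group lipid counts
#'
#' @param unique_lipids data frame from [collapse_unique()] (needs
#'   `lipid_class` and `class_group`).
#' @return list with `per_class` counts, `per_group` counts (core,
#'   phospholipid, glycolipid, cardiolipin, quinone, carotenoid) and the
#'   grand `total`.
#' @export
class_summary <- function(unique_lipids) {
  groups <- c("core", "phospholipid", "glycolipid", "cardiolipin",
              "quinone", "carotenoid")
  if (nrow(unique_lipids) == 0) {
    return(list(per_class = data.frame(lipid_class = character(0),
                                       n = integer(0)),
                per_group = data.frame(class_group = groups,
                                       n = rep(0L, length(groups))),
                total = 0L))
  }
  per_class <- as.data.frame(table(unique_lipids$lipid_class),
                             stringsAsFactors = FALSE)
  names(per_class) <- c("lipid_class", "n")
  tab <- table(factor(unique_lipids$class_group, levels = groups))
  per_group <- data.frame(class_group = groups, n = as.integer(tab))
  list(per_class = per_class, per_group = per_group,
       total = nrow(unique_lipids))
}

#' Evaluate annotation against generator ground truth
#'
#' Feature-level recall is the fraction of emitted library-species features
#' that were accepted with the correct species; the false-discovery rate is
#' the fraction of accepted annotations whose species disagrees with the
#' ground truth (decoys and unknown analogs annotated as anything count as
#' false).
#'
#' @param annotations annotation table.
#' @param truth ground-truth table (`feature_id`, `species`; species is
#'   `NA`/`"decoy"`-like for non-library features).
#' @return list with `recall`, `fdr`, `n_true`, `n_accepted`.
#' @export
evaluate_annotation <- function(annotations, truth) {
  lib_truth <- truth[!is.na(truth$species) & truth$species != "", ,
                     drop = FALSE]
  acc <- annotations[annotations$accepted, , drop = FALSE]
  key <- stats::setNames(lib_truth$species, lib_truth$feature_id)
  correct <- acc$feature_id %in% names(key) &
    acc$species == key[acc$feature_id]
  recall <- sum(correct) / nrow(lib_truth)
  fdr <- if (nrow(acc) == 0) 0 else 1 - sum(correct) / nrow(acc)
  list(recall = recall, fdr = fdr, n_true = nrow(lib_truth),
       n_accepted = nrow(acc))
}
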