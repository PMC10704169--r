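#' Default strain lipidome profiles
#'
#' Seven halobacterial strains spanning three orders, with per-class
#' abundance tiers (major / trace / absent), the fraction of unsaturated
#' diether cores, the poly-unsaturated share among them, and the C25 chain
#' fraction. Class presence follows the survey design: e.g. TGD-PA occurs
#' only in *Haloarcula argentinensis*, the bis-sulfated glycolipids only in
#' *Haloterrigena turkmenica* and *Natrialba asiatica*, bacterioruberin is
#' absent from *Na. asiatica*, and extended archaeol exceeds a 10% chain
#' fraction only in the *Natrialbales*.
#'
#' @return list of 7 strain profiles (`strain`, `order`, `genus`, `tiers`,
#'   `f_unsat`, `f_poly`, `f_c25`).
#' @export
default_profiles <- function() {
  tier <- function(major = character(0), trace = character(0)) {
    all_classes <- head_groups()$lipid_class
    stopifnot(all(c(major, trace) %in% all_classes))
    tiers <- stats::setNames(rep("absent", length(all_classes)),
                             all_classes)
    tiers[major] <- "major"
    tiers[trace] <- "trace"
    tiers
  }
  list(
    list(strain = "Ha_argentinensis", order = "Halobacteriales",
         genus = "Haloarcula",
         tiers = tier(major = c("MK", "AR", "Me-PGP", "PG", "BR", "PGS",
                                "TGD", "BPG", "TGD-PA", "DGD-PA"),
                      trace = c("DGD", "PA", "MGD-PA")),
         f_unsat = 0.0032, f_poly = 0, f_c25 = 0.001),
    list(strain = "Hf_mediterranei", order = "Haloferacales",
         genus = "Haloferax",
         tiers = tier(major = c("MK", "AR", "Me-PGP", "PG", "PGS",
                                "DGD-PA", "S-DGD-PA", "S-DGD", "DGD",
                                "S-Gly-AHH", "PE", "PI"),
                      trace = c("BR", "BPG", "PA", "MGD-PA", "S-MGD")),
         f_unsat = 0.2072, f_poly = 0.0256, f_c25 = 0.001),
    list(strain = "Hf_larsenii", order = "Haloferacales",
         genus = "Haloferax",
         tiers = tier(major = c("MK", "AR", "Me-PGP", "PG", "BR", "BPG",
                                "DGD-PA", "S-DGD-PA", "S-DGD", "DGD",
                                "S-Gly-AHH", "PE"),
                      trace = c("MGD", "PI", "PA", "MGD-PA", "S-MGD")),
         f_unsat = 0.15, f_poly = 0.2127, f_c25 = 0.001),
    list(strain = "Hf_volcanii", order = "Haloferacales",
         genus = "Haloferax",
         tiers = tier(major = c("MK", "AR", "Me-PGP", "PG", "BR",
                                "DGD-PA", "S-DGD-PA", "S-DGD", "DGD",
                                "S-Gly-AHH", "MGD-PA"),
                      trace = c("BPG", "PE", "PI", "Gly-PG", "PA",
                                "S-MGD")),
         f_unsat = 0.1117, f_poly = 0.0039, f_c25 = 0.001),
    list(strain = "Ht_turkmenica", order = "Natrialbales",
         genus = "Haloterrigena",
         tiers = tier(major = c("MK", "AR", "Me-PGP", "PG", "BR", "S-DGD",
                                "DGD", "S-Gly-AHH", "PE", "MGD", "2S-DGD",
                                "2S-Gly-AHH"),
                      trace = c("Gly-PG", "PA", "S-MGD")),
         f_unsat = 0.0227, f_poly = 0.0905, f_c25 = 0.1344),
    list(strain = "Na_asiatica", order = "Natrialbales",
         genus = "Natrialba",
         tiers = tier(major = c("MK", "AR", "Me-PGP", "PG", "S-DGD",
                                "S-Gly-AHH", "PE", "MGD", "2S-DGD",
                                "2S-Gly-AHH"),
                      trace = c("DGD", "PA")),
         f_unsat = 0.0501, f_poly = 0.3393, f_c25 = 0.2616),
    list(strain = "Nn_gari", order = "Natrialbales", genus = "Natrinema",
         tiers = tier(major = c("MK", "AR", "Me-PGP", "PG", "BR", "PGS",
                                "TGD", "S-DGD", "DGD", "PE", "MGD",
                                "Gly-PG"),
                      trace = c("S-DGD-PA", "S-Gly-AHH", "PA")),
         f_unsat = 0.035, f_poly = 0.4443, f_c25 = 0.20)
  )
}

#' Simulation configuration
#'
#' @param seed RNG seed fixing all downstream randomness.
#' @param n_replicates culture replicates per strain.
#' @param n_blanks extraction blanks.
#' @param mz_sigma m/z jitter standard deviation per measurement (Da);
#'   feature consensus m/z averages over the samples in which the feature
#'   was detected.
#' @param intensity_cv log-normal intensity noise coefficient.
#' @param n_contaminants contaminant features dominating the blanks.
#' @param p_nh4 probability that a species also yields an ammonium-adduct
#'   feature.
#' @param n_analogs unknown structural analogs emitted per strain (share
#'   class fragments but have no library entry).
#' @param n_noise_peaks random low-intensity peaks added per MS2 spectrum.
#' @param emit_na_adducts emit sodium-adduct features for unsaturated
#'   PG-family lipids (never in the annotation library).
#' @param seq_length toy 16S alignment length (bases).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 42L, n_replicates = 3L, n_blanks = 2L,
                       mz_sigma = 0.005, intensity_cv = 0.1,
                       n_contaminants = 8L, p_nh4 = 0.6, n_analogs = 3L,
                       n_noise_peaks = 2L, emit_na_adducts = TRUE,
                       seq_length = 600L) {
  stopifnot(mz_sigma >= 0, intensity_cv >= 0, n_replicates >= 1)
  structure(list(seed = seed, n_replicates = n_replicates,
                 n_blanks = n_blanks, mz_sigma = mz_sigma,
                 intensity_cv = intensity_cv,
                 n_contaminants = n_contaminants, p_nh4 = p_nh4,
                 n_analogs = n_analogs, n_noise_peaks = n_noise_peaks,
                 emit_na_adducts = emit_na_adducts,
                 seq_length = seq_length),
            class = "sim_config")
}

# class-specific "backbone" fingerprint: 6 deterministic low-mass fragments
# shared by all species of a class (fragments the rule library does not
# model; they make same-class spectra link in the network)
.class_fingerprint <- function(lipid_class, n = 6L) {
  h <- sum(utf8ToInt(lipid_class) * seq_along(utf8ToInt(lipid_class)))
  base <- 150 + (h %% 97)
  data.frame(mz = base + 37.3 * (seq_len(n) - 1L) + (h %% 13) / 20,
             intensity = 25 + 5 * ((h + seq_len(n)) %% 4))
}

.lognormal <- function(mu, cv) mu * exp(stats::rnorm(1, 0, cv))

# distribute a diether class abundance over core variants according to the
# strain's unsaturation / C25 parameters (representative double-bond levels
# u = 2 for low and u = 5 for poly unsaturation)
.core_weights <- function(profile) {
  m25 <- 2 * profile$f_c25
  w <- c("20:20;u0" = 1 - m25 - profile$f_unsat,
         "20:20;u2" = profile$f_unsat * (1 - profile$f_poly),
         "20:20;u5" = profile$f_unsat * profile$f_poly,
         "20:25;u0" = m25)
  w[w > 1e-9]
}

.variant_species <- function(lipid_class, key) {
  parts <- strsplit(sub("u", "", key), "[:;]")[[1]]
  sprintf("%s(%s:%s;u%s)", lipid_class, parts[1], parts[2], parts[3])
}

.mutate_seq <- function(seq, p) {
  bases <- c("a", "c", "g", "t")
  hit <- stats::runif(length(seq)) < p
  if (any(hit)) {
    seq[hit] <- vapply(seq[hit], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))
  }
  seq
}

#' Simulate the full synthetic lipidomics input bundle
#'
#' Generates, from the strain profiles and the in-silico library, an
#' aligned feature table (strain triplicates plus blanks), linked MS2
#' spectra, sample metadata, a ground-truth table, and a toy 16S alignment
#' whose topology follows the three orders. Each emitted lipid yields
#' features for its adducts with jittered m/z and log-normal intensities;
#' spectra are the predicted library spectra plus a class fingerprint and
#' noise peaks; blanks contain only contaminants (plus sub-threshold
#' carry-over in samples); unknown analogs are mass-shifted class members
#' without library entries; sodium-adduct features of unsaturated
#' PG-family lipids are emitted as annotatable-by-network unknowns.
#'
#' @param profiles list from [default_profiles()].
#' @param config a [sim_config()].
#' @param species species table ([enumerate_library()]).
#' @param rules fragmentation rules.
#' @return list: `features`, `samples`, `spectra`, `truth`, `alignment`,
#'   `species_table`, `library`, `is_feature_id`.
#' @export
simulate_lipidome <- function(profiles = default_profiles(),
                              config = sim_config(),
                              species = enumerate_library(),
                              rules = fragmentation_rules()) {
  set.seed(config$seed)
  lib <- build_spectral_library(species, c("[M+H]+", "[M+NH4]+"), rules)
  lib_by_key <- stats::setNames(lib, vapply(lib, function(s)
    paste(s$species, s$adduct), character(1)))
  hg <- head_groups()
  diether <- hg$lipid_class[!hg$lipid_class %in% c("MK", "BR")]
  miss <- setdiff(unlist(lapply(profiles, function(p)
    names(p$tiers)[p$tiers != "absent"])), species$lipid_class)
  if (length(miss) > 0) {
    stop("profile requests class(es) absent from library: ",
         paste(miss, collapse = ", "))
  }

  strains <- vapply(profiles, `[[`, character(1), "strain")
  samples <- data.frame(
    sample_id = c(t(outer(strains, seq_len(config$n_replicates),
                          function(s, r) paste0(s, "_r", r))),
                  paste0("blank_", seq_len(config$n_blanks))),
    role = c(rep("sample", length(strains) * config$n_replicates),
             rep("blank", config$n_blanks)),
    strain = c(rep(strains, each = config$n_replicates),
               rep("", config$n_blanks)),
    replicate = c(rep(seq_len(config$n_replicates), length(strains)),
                  seq_len(config$n_blanks)))

  # per-species per-strain abundance map
  ab <- list()  # species name -> named numeric per strain
  add_ab <- function(spn, strain, x) {
    if (is.null(ab[[spn]])) {
      ab[[spn]] <<- stats::setNames(numeric(length(strains)), strains)
    }
    ab[[spn]][strain] <<- ab[[spn]][strain] + x
  }
  for (p in profiles) {
    cw <- .core_weights(p)
    for (cl in hg$lipid_class) {
      t_ <- p$tiers[[cl]]
      if (t_ == "absent") next
      total <- .lognormal(if (t_ == "major") 1e5 else 2e3, 0.3)
      if (cl == "MK") {
        add_ab("MK(8:8)", p$strain, total * 0.6)
        add_ab("MK(8:7)", p$strain, total * 0.4)
      } else if (cl == "BR") {
        add_ab("BR(OH4)", p$strain, total * 0.7)
        add_ab("BR(OH3)", p$strain, total * 0.3)
      } else {
        for (k in names(cw)) {
          add_ab(.variant_species(cl, k), p$strain, total * cw[[k]])
        }
      }
    }
  }

  feat_rows <- list()
  spectra <- list()
  truth <- list()
  fid_counter <- 0L
  new_fid <- function() {
    fid_counter <<- fid_counter + 1L
    sprintf("F%04d", fid_counter)
  }
  sample_cols <- samples$sample_id
  emit_feature <- function(mz_theo, rt, intensities, peaks_theo, kind,
                           species_name = "", source = "") {
    fid <- new_fid()
    n_det <- sum(intensities > 0)
    mz_obs <- mz_theo +
      stats::rnorm(1, 0, config$mz_sigma / sqrt(max(n_det, 1)))
    row <- data.frame(feature_id = fid, mz = mz_obs, rt = rt)
    row[sample_cols] <- as.list(intensities)
    feat_rows[[length(feat_rows) + 1L]] <<- row
    if (!is.null(peaks_theo)) {
      pk <- peaks_theo
      pk$mz <- pk$mz + stats::rnorm(nrow(pk), 0, config$mz_sigma)
      pk$intensity <- pmax(pk$intensity *
                             exp(stats::rnorm(nrow(pk), 0,
                                              config$intensity_cv)), 0.1)
      if (config$n_noise_peaks > 0) {
        noise <- data.frame(
          mz = stats::runif(config$n_noise_peaks, 100,
                            max(mz_obs - 20, 150)),
          intensity = stats::runif(config$n_noise_peaks, 1, 5))
        pk <- rbind(pk, noise)
      }
      pk <- pk[order(pk$mz), , drop = FALSE]
      rownames(pk) <- NULL
      spectra[[length(spectra) + 1L]] <<-
        list(feature_id = fid, title = fid, precursor_mz = mz_obs,
             rt = rt, peaks = pk)
    }
    det <- strains[vapply(strains, function(st) {
      any(intensities[samples$strain == st] > 0)
    }, logical(1))]
    truth[[length(truth) + 1L]] <<- data.frame(
      feature_id = fid, kind = kind, species = species_name,
      source = source, strains = paste(det, collapse = ";"))
    fid
  }
  sample_intensities <- function(per_strain, factor = 1) {
    ints <- stats::setNames(numeric(nrow(samples)), sample_cols)
    for (st in strains) {
      a <- per_strain[st]
      if (is.na(a) || a <= 0) next
      ids <- samples$sample_id[samples$strain == st]
      ints[ids] <- a * factor *
        exp(stats::rnorm(length(ids), 0, config$intensity_cv))
    }
    ints
  }

  all_lib_mz <- vapply(lib, function(s) s$precursor_mz, numeric(1))
  sp_names <- sort(names(ab))
  rt_map <- stats::setNames(stats::runif(length(sp_names), 3, 28),
                            sp_names)
  # ammonium-adduct formation is head-group chemistry: decide per class,
  # so within-class core-variant ratios survive adduct summation
  nh4_class <- stats::setNames(
    stats::runif(length(hg$lipid_class)) < config$p_nh4, hg$lipid_class)
  for (spn in sp_names) {
    adducts <- "[M+H]+"
    if (nh4_class[[sub("\\(.*$", "", spn)]]) {
      adducts <- c(adducts, "[M+NH4]+")
    }
    for (ad in adducts) {
      entry <- lib_by_key[[paste(spn, ad)]]
      cls <- entry$lipid_class
      peaks <- rbind(entry$peaks, .class_fingerprint(cls))
      emit_feature(entry$precursor_mz,
                   rt_map[[spn]] + stats::rnorm(1, 0, 0.05),
                   sample_intensities(ab[[spn]],
                                      if (ad == "[M+H]+") 1 else 0.45),
                   peaks, kind = "library", species_name = spn,
                   source = paste(spn, ad))
    }
  }

  # unknown structural analogs: CH2-homologs of a strain's major diether
  # classes, sharing the class fragments but absent from the library
  for (p in profiles) {
    major_diether <- intersect(names(p$tiers)[p$tiers == "major"], diether)
    if (length(major_diether) == 0 || config$n_analogs == 0) next
    picks <- sample(major_diether,
                    min(config$n_analogs, length(major_diether)))
    for (ii in seq_along(picks)) {
      cl <- picks[ii]
      entry <- lib_by_key[[paste(.variant_species(cl, "20:20;u0"),
                                 "[M+H]+")]]
      shift <- 14.01565 * ii
      mz_new <- entry$precursor_mz + shift
      if (min(abs(all_lib_mz - mz_new)) < 0.03) {
        mz_new <- mz_new + 0.35   # push clear of any library precursor
      }
      pk <- entry$peaks
      # precursor-derived peaks (neutral losses, i.e. close to precursor)
      # shift with the homolog; class fragments stay put
      shift_up <- pk$mz > entry$precursor_mz - 500
      pk$mz[shift_up] <- pk$mz[shift_up] + shift
      pk <- rbind(pk, .class_fingerprint(cl))
      ints <- stats::setNames(numeric(nrow(samples)), sample_cols)
      ids <- samples$sample_id[samples$strain == p$strain]
      ints[ids] <- .lognormal(3e4, 0.3) *
        exp(stats::rnorm(length(ids), 0, config$intensity_cv))
      emit_feature(mz_new, stats::runif(1, 3, 28), ints, pk,
                   kind = "analog", source = paste0("analog of ", cl))
    }
  }

  # sodium-adduct features of unsaturated PG-family lipids (not in the
  # annotation library; their spectra carry the intact-chain-loss pattern)
  if (config$emit_na_adducts) {
    for (spn in sp_names) {
      cls <- sub("\\(.*$", "", spn)
      if (!cls %in% c("PG", "Me-PGP", "Gly-PG")) next
      u <- as.integer(sub(".*u([0-9]+)\\)$", "\\1", spn))
      if (is.na(u) || u < 1) next
      if (stats::runif(1) > 0.5) next
      srow <- species[species$name == spn, ]
      entry <- predict_spectrum(srow, "[M+Na]+", rules)
      peaks <- rbind(entry$peaks, .class_fingerprint(cls))
      emit_feature(entry$precursor_mz,
                   rt_map[[spn]] + stats::rnorm(1, 0, 0.05),
                   sample_intensities(ab[[spn]], 0.25), peaks,
                   kind = "na_adduct",
                   source = paste(spn, "[M+Na]+"))
    }
  }

  # blank contaminants: dominant in blanks, sub-threshold carry-over in
  # samples (ratio < 10x), random spectra
  for (k in seq_len(config$n_contaminants)) {
    blank_int <- .lognormal(5e4, 0.3)
    ints <- stats::setNames(numeric(nrow(samples)), sample_cols)
    ints[samples$role == "blank"] <-
      blank_int * exp(stats::rnorm(config$n_blanks, 0,
                                   config$intensity_cv))
    carry <- stats::runif(1) < 0.5
    if (carry) {
      ids <- samples$sample_id[samples$role == "sample"]
      ints[ids] <- blank_int * stats::runif(1, 0.5, 5) *
        exp(stats::rnorm(length(ids), 0, config$intensity_cv))
    }
    mz <- stats::runif(1, 520, 900)
    pk <- data.frame(mz = sort(stats::runif(8, 100, mz - 30)),
                     intensity = stats::runif(8, 5, 80))
    emit_feature(mz, stats::runif(1, 1, 30), ints, pk,
                 kind = "contaminant", source = "blank contaminant")
  }

  # spiked internal standard (C19-PC), equal amount in every culture sample
  is_mass <- monoisotopic_mass("C46H92NO8P")
  is_ints <- stats::setNames(numeric(nrow(samples)), sample_cols)
  ids <- samples$sample_id[samples$role == "sample"]
  is_ints[ids] <- 1e5 * exp(stats::rnorm(length(ids), 0,
                                         config$intensity_cv))
  is_fid <- emit_feature(adduct_mz(is_mass, "[M+H]+"), 15.0, is_ints,
                         NULL, kind = "internal_standard",
                         source = "C19-PC spike")

  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # toy 16S alignment following the order topology
  bases <- c("a", "c", "g", "t")
  root <- sample(bases, config$seq_length, replace = TRUE)
  orders <- unique(vapply(profiles, `[[`, character(1), "order"))
  anc <- lapply(orders, function(o) .mutate_seq(root, 0.05))
  names(anc) <- orders
  alignment <- vapply(profiles, function(p) {
    paste(.mutate_seq(anc[[p$order]], 0.012), collapse = "")
  }, character(1))
  names(alignment) <- strains

  list(features = features, samples = samples, spectra = spectra,
       truth = truth, alignment = alignment, species_table = species,
       library = lib, is_feature_id = is_fid,
       profiles = profiles, config = config)
}

#' Strain-level abundance matrix from unique lipids
#'
#' Averages replicate columns per strain.
#'
#' @param unique_lipids table from [collapse_unique()].
#' @param samples sample metadata.
#' @return numeric matrix, lipids (rows, named by species) x strains.
#' @export
strain_matrix <- function(unique_lipids, samples) {
  samp <- samples[samples$role == "sample", , drop = FALSE]
  strains <- unique(samp$strain)
  m <- sapply(strains, function(st) {
    ids <- samp$sample_id[samp$strain == st]
    rowMeans(unique_lipids[, ids, drop = FALSE])
  })
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(unique_lipids))
  rownames(m) <- unique_lipids$species
  colnames(m) <- strains
  m
}
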