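#' Head-group definitions for halobacterial lipid classes
#'
#' Each lipid class is defined by the free head-group molecule that condenses
#' onto one or two diether cores (one H2O lost per core-head junction), the
#' number of cores it bridges, and its class group. Sulfated classes carry
#' k x SO3 on top of their glycosyl parent (added without water loss);
#' cardiolipin variants (BPG and the glyco-phosphatidic acid series) bridge
#' two archaeol cores. `MK` (menaquinone) and `BR` (bacterioruberin) are not
#' diether lipids and have no head group entry here beyond bookkeeping.
#'
#' @return data frame with columns `lipid_class`, `head_formula` (free
#'   molecule), `n_cores`, `class_group`.
#' @export
head_groups <- function() {
  hg <- rbind(
    data.frame(lipid_class = "AR",         head_formula = "",            n_cores = 1L, class_group = "core"),
    data.frame(lipid_class = "PG",         head_formula = "C3H9O6P",     n_cores = 1L, class_group = "phospholipid"),
    data.frame(lipid_class = "Me-PGP",     head_formula = "C4H12O9P2",   n_cores = 1L, class_group = "phospholipid"),
    data.frame(lipid_class = "PGS",        head_formula = "C3H9O9PS",    n_cores = 1L, class_group = "phospholipid"),
    data.frame(lipid_class = "PA",         head_formula = "H3O4P",       n_cores = 1L, class_group = "phospholipid"),
    data.frame(lipid_class = "PE",         head_formula = "C2H8NO4P",    n_cores = 1L, class_group = "phospholipid"),
    data.frame(lipid_class = "PI",         head_formula = "C6H13O9P",    n_cores = 1L, class_group = "phospholipid"),
    data.frame(lipid_class = "Gly-PG",     head_formula = "C9H19O11P",   n_cores = 1L, class_group = "phospholipid"),
    data.frame(lipid_class = "MGD",        head_formula = "C6H12O6",     n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "DGD",        head_formula = "C12H22O11",   n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "TGD",        head_formula = "C18H32O16",   n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "S-MGD",      head_formula = "C6H12O9S",    n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "S-DGD",      head_formula = "C12H22O14S",  n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "2S-DGD",     head_formula = "C12H22O17S2", n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "S-Gly-AHH",  head_formula = "C12H25NO14S", n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "2S-Gly-AHH", head_formula = "C12H25NO17S2", n_cores = 1L, class_group = "glycolipid"),
    data.frame(lipid_class = "BPG",        head_formula = "C3H10O9P2",   n_cores = 2L, class_group = "cardiolipin"),
    data.frame(lipid_class = "MGD-PA",     head_formula = "C6H13O9P",    n_cores = 2L, class_group = "cardiolipin"),
    data.frame(lipid_class = "DGD-PA",     head_formula = "C12H23O14P",  n_cores = 2L, class_group = "cardiolipin"),
    data.frame(lipid_class = "TGD-PA",     head_formula = "C18H33O19P",  n_cores = 2L, class_group = "cardiolipin"),
    data.frame(lipid_class = "S-DGD-PA",   head_formula = "C12H23O17PS", n_cores = 2L, class_group = "cardiolipin"),
    data.frame(lipid_class = "MK",         head_formula = "",            n_cores = 0L, class_group = "quinone"),
    data.frame(lipid_class = "BR",         head_formula = "",            n_cores = 0L, class_group = "carotenoid")
  )
  rownames(hg) <- NULL
  hg
}

#' Diether core labels and composition
#'
#' Archaeol cores are 2,3-di-O-alkyl glycerols with two isoprenoid chains of
#' 20 or 25 carbons; unsaturation removes H2 per double bond at the
#' composition level (positions are not modelled).
#'
#' @param chain1,chain2 chain carbon numbers, each 20 or 25.
#' @param unsat total number of double bonds across both chains, 0-8.
#' @return for `core_label()`, one of `"AR"`, `"Ext-AR"`, `"diExt-AR"`;
#'   for `core_composition()`, the `elem_comp` of the free core diether.
#' @export
core_label <- function(chain1, chain2) {
  stopifnot(chain1 %in% c(20L, 25L), chain2 %in% c(20L, 25L))
  n25 <- sum(c(chain1, chain2) == 25L)
  c("AR", "Ext-AR", "diExt-AR")[n25 + 1L]
}

#' @rdname core_label
#' @export
core_composition <- function(chain1, chain2, unsat = 0L) {
  stopifnot(chain1 %in% c(20L, 25L), chain2 %in% c(20L, 25L),
            unsat >= 0L, unsat <= 8L)
  # glycerol + two fatty alcohols - 2 H2O (ether condensation), - unsat x H2
  comp(C = 3L + chain1 + chain2,
       H = 2L * (chain1 + chain2) + 8L - 2L * unsat,
       O = 3L)
}

.water <- function() comp(H = 2, O = 1)

#' Construct one lipid species
#'
#' Builds composition and neutral mass for a (class, core, unsaturation)
#' combination. Each core-head junction loses one water; cardiolipin classes
#' incorporate two identical cores. `MK` species are menaquinones with 8
#' isoprene units and `unsat` double bonds in the side chain (MK 8:8 is fully
#' unsaturated); `BR` species are C50 carotenoid tetrol hydration variants
#' (`unsat` here counts removed waters, 0-3).
#'
#' @param lipid_class class name as in [head_groups()].
#' @param chain1,chain2 core chain lengths (ignored for MK/BR).
#' @param unsat double-bond count (MK: side-chain double bonds 1-8; BR:
#'   anhydro count 0-3).
#' @return one-row data frame (name, lipid_class, class_group, chain1,
#'   chain2, unsat, n_cores, formula, neutral_mass).
#' @export
lipid_species <- function(lipid_class, chain1 = 20L, chain2 = 20L,
                          unsat = 0L) {
  hg <- head_groups()
  row <- hg[hg$lipid_class == lipid_class, ]
  if (nrow(row) != 1L) stop("unknown lipid class: ", lipid_class)
  if (lipid_class == "MK") {
    stopifnot(unsat >= 1L, unsat <= 8L)
    cmp <- comp(C = 51L, H = 72L + 2L * (8L - unsat), O = 2L)
    name <- sprintf("MK(8:%d)", unsat)
    chain1 <- chain2 <- NA_integer_
  } else if (lipid_class == "BR") {
    stopifnot(unsat >= 0L, unsat <= 3L)
    cmp <- comp(C = 50L, H = 76L - 2L * unsat, O = 4L - unsat)
    name <- sprintf("BR(OH%d)", 4L - unsat)
    chain1 <- chain2 <- NA_integer_
  } else {
    core <- core_composition(chain1, chain2, unsat)
    n <- row$n_cores
    cmp <- core
    if (n == 2L) cmp <- comp_add(cmp, core)
    if (row$head_formula != "") {
      cmp <- comp_add(cmp, comp_parse(row$head_formula))
      for (i in seq_len(n)) cmp <- comp_sub(cmp, .water())
    }
    name <- sprintf("%s(%d:%d;u%d)", lipid_class, chain1, chain2, unsat)
  }
  data.frame(name = name, lipid_class = lipid_class,
             class_group = row$class_group,
             chain1 = chain1, chain2 = chain2, unsat = as.integer(unsat),
             n_cores = row$n_cores,
             formula = comp_format(cmp),
             neutral_mass = monoisotopic_mass(cmp),
             stringsAsFactors = FALSE)
}

#' Library enumeration configuration
#'
#' Defaults mirror the halobacterial survey design: all diether classes with
#' AR and Ext-AR cores, 0-8 double bonds, MK 8:1-8:8, four bacterioruberin
#' hydration states, and the two adducts used for peak integration
#' ([M+H]+ and [M+NH4]+). Sodium adducts and the diExt-AR core are disabled
#' by default (not part of the annotation library); enabling `allow_diext`
#' permits `c(25, 25)` chain pairs.
#'
#' @param classes lipid classes to enumerate.
#' @param chains list of length-2 chain-carbon vectors.
#' @param unsat_range integer vector of double-bond counts for diether cores.
#' @param adducts adducts for spectral-library generation.
#' @param allow_diext allow the di-extended (25,25) core.
#' @param mz_convention charge-carrier convention for precursor m/z.
#' @return a `library_config` list.
#' @export
library_config <- function(classes = head_groups()$lipid_class,
                           chains = list(c(20L, 20L), c(20L, 25L)),
                           unsat_range = 0:8,
                           adducts = c("[M+H]+", "[M+NH4]+"),
                           allow_diext = FALSE,
                           mz_convention = "proton") {
  stopifnot(length(classes) >= 1L)
  structure(list(classes = classes, chains = chains,
                 unsat_range = unsat_range, adducts = adducts,
                 allow_diext = allow_diext, mz_convention = mz_convention),
            class = "library_config")
}

#' Enumerate the lipid species library
#'
#' Cartesian product of class-allowed cores, deduplicated on
#' (class, unordered chain pair, unsaturation), in deterministic order
#' (class order of the config, then chain carbons, then unsaturation).
#'
#' @param config a [library_config()].
#' @return data frame of species (one row per unique species).
#' @export
enumerate_library <- function(config = library_config()) {
  stopifnot(inherits(config, "library_config"))
  for (ch in config$chains) {
    if (all(ch == 25L) && !config$allow_diext) {
      stop("diExt-AR core (25,25) is disabled in this configuration")
    }
  }
  out <- list()
  for (cl in config$classes) {
    if (cl == "MK") {
      for (m in 1:8) out[[length(out) + 1L]] <- lipid_species("MK", unsat = m)
    } else if (cl == "BR") {
      for (k in 0:3) out[[length(out) + 1L]] <- lipid_species("BR", unsat = k)
    } else {
      seen <- character(0)
      for (ch in config$chains) {
        key_ch <- paste(sort(ch), collapse = ":")
        for (u in sort(config$unsat_range)) {
          key <- paste(key_ch, u)
          if (key %in% seen) next
          seen <- c(seen, key)
          out[[length(out) + 1L]] <-
            lipid_species(cl, min(ch), max(ch), u)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default fragmentation rules
#'
#' Reads the editable TSV rules table shipped with the package (or a user
#' file of the same layout). Rules are reconstructions from published
#' archaeal lipid fragmentation behaviour: head-group neutral losses,
#' hexose loss (162.05282), SO3 loss (79.95682), phytanyl chain loss, the
#' tentative PI head-group diagnostic ion at m/z 261.038, and the
#' sodium-adduct intact unsaturated chain loss. Columns: `lipid_class`
#' (`*` = any), `adduct` (`*` = any), `kind` (`neutral_loss`,
#' `diagnostic_ion`, `unsat_chain_loss`), `formula`, `mz`, `label`,
#' `rel_intensity`.
#'
#' @param path TSV path; default is the packaged rules file.
#' @return data frame of fragmentation rules.
#' @export
fragmentation_rules <- function(path = system.file("extdata",
                                                   "fragment_rules.tsv",
                                                   package = "halolipid")) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = character(0))
  needed <- c("lipid_class", "adduct", "kind", "formula", "mz", "label",
              "rel_intensity")
  if (!all(needed %in% names(rules))) {
    stop("rules file missing columns: ",
         paste(setdiff(needed, names(rules)), collapse = ", "))
  }
  stopifnot(all(rules$rel_intensity > 0), all(rules$rel_intensity <= 100))
  rules
}

.rule_applies <- function(rule, lipid_class, adduct) {
  (rule$lipid_class == "*" || rule$lipid_class == lipid_class) &&
    (rule$adduct == "*" || rule$adduct == adduct)
}

#' Predict a rule-based MS2 spectrum
#'
#' The spectrum contains the precursor (relative intensity 100) plus peaks
#' generated by the applicable rules: neutral losses subtract the loss mass
#' from the precursor; diagnostic ions appear at their fixed m/z; the
#' sodium-adduct rule emits sequential intact-chain alkene losses
#' (C_n H_(2n-2u)) for unsaturated diether species, splitting the double
#' bonds over the two chains (chain 1 gets the larger share). Peaks closer
#' than 1e-4 Da are merged keeping the larger intensity, output is sorted by
#' m/z, and every fragment must fall below the precursor.
#'
#' @param species one-row species data frame from [lipid_species()] /
#'   [enumerate_library()].
#' @param adduct adduct string.
#' @param rules rules table from [fragmentation_rules()].
#' @param mz_convention charge-carrier convention.
#' @return list with `name`, `species`, `lipid_class`, `adduct`, `formula`,
#'   `precursor_mz` and `peaks` (data frame `mz`, `intensity`).
#' @export
predict_spectrum <- function(species, adduct,
                             rules = fragmentation_rules(),
                             mz_convention = "proton") {
  stopifnot(nrow(species) == 1L)
  prec <- adduct_mz(species$neutral_mass, adduct, mz_convention)
  mzs <- prec
  ints <- 100
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    if (!.rule_applies(rule, species$lipid_class, adduct)) next
    if (rule$kind == "neutral_loss") {
      loss <- monoisotopic_mass(comp_parse(rule$formula))
      frag <- prec - loss
      if (frag <= 0) stop("rule '", rule$label,
                          "' produces non-positive m/z")
      mzs <- c(mzs, frag); ints <- c(ints, rule$rel_intensity)
    } else if (rule$kind == "diagnostic_ion") {
      frag <- if (!is.na(rule$mz) && rule$mz != "") {
        as.numeric(rule$mz)
      } else {
        monoisotopic_mass(comp_parse(rule$formula)) +
          adduct_delta("[M+H]+", mz_convention)
      }
      if (frag <= 0) stop("rule '", rule$label,
                          "' produces non-positive m/z")
      if (frag < prec) {
        mzs <- c(mzs, frag); ints <- c(ints, rule$rel_intensity)
      }
    } else if (rule$kind == "unsat_chain_loss") {
      if (is.na(species$chain1) || species$unsat < 1L) next
      u1 <- ceiling(species$unsat / 2)
      u2 <- species$unsat - u1
      loss1 <- monoisotopic_mass(comp(C = species$chain1,
                                      H = 2L * species$chain1 - 2L * u1))
      frag1 <- prec - loss1
      if (frag1 <= 0) stop("chain-loss rule produces non-positive m/z")
      mzs <- c(mzs, frag1); ints <- c(ints, rule$rel_intensity)
      if (u2 >= 1L) {
        loss2 <- monoisotopic_mass(comp(C = species$chain2,
                                        H = 2L * species$chain2 - 2L * u2))
        frag2 <- frag1 - loss2
        if (frag2 <= 0) stop("chain-loss rule produces non-positive m/z")
        mzs <- c(mzs, frag2)
        ints <- c(ints, rule$rel_intensity * 0.8)
      }
    } else {
      stop("unknown rule kind: ", rule$kind)
    }
  }
  peaks <- .merge_peaks(data.frame(mz = mzs, intensity = ints))
  list(name = paste(species$name, adduct),
       species = species$name, lipid_class = species$lipid_class,
       adduct = adduct, formula = species$formula,
       precursor_mz = prec, peaks = peaks)
}

# merge peaks closer than `tol` keeping the maximum intensity; sort by m/z
.merge_peaks <- function(peaks, tol = 1e-4) {
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  keep <- logical(nrow(peaks))
  i <- 1L
  while (i <= nrow(peaks)) {
    j <- i
    while (j < nrow(peaks) && peaks$mz[j + 1L] - peaks$mz[i] < tol) {
      j <- j + 1L
    }
    best <- i - 1L + which.max(peaks$intensity[i:j])
    keep[best] <- TRUE
    i <- j + 1L
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the full in-silico spectral library
#'
#' Predicts one spectrum per species x adduct. Sodium-adduct spectra are
#' generated only for unsaturated diether species (saturated species resist
#' CID under Na+ and carry no structural fragments), and `[M+Na]+` is not in
#' the default adduct set used for annotation.
#'
#' @param species species table from [enumerate_library()].
#' @param adducts adduct set.
#' @param rules fragmentation rules table.
#' @param mz_convention charge-carrier convention.
#' @return list of spectra (see [predict_spectrum()]).
#' @export
build_spectral_library <- function(species,
                                   adducts = c("[M+H]+", "[M+NH4]+"),
                                   rules = fragmentation_rules(),
                                   mz_convention = "proton") {
  out <- list()
  for (i in seq_len(nrow(species))) {
    for (ad in adducts) {
      if (ad == "[M+Na]+" &&
          (is.na(species$chain1[i]) || species$unsat[i] < 1L)) next
      out[[length(out) + 1L]] <-
        predict_spectrum(species[i, ], ad, rules, mz_convention)
    }
  }
  out
}

#' Export / import an MSP spectral library
#'
#' NIST-style text records (NAME, PRECURSORMZ, PRECURSORTYPE, FORMULA,
#' Num Peaks, tab-separated peak lines). m/z are written to 4 decimals and
#' intensities to 1 decimal, so export -> import -> export is idempotent.
#'
#' @param spectra list of spectra from [build_spectral_library()].
#' @param path output file.
#' @return `export_msp()` returns `path` invisibly; `read_msp()` returns a
#'   list of spectra.
#' @export
export_msp <- function(spectra, path) {
  stopifnot(length(spectra) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      paste0("NAME: ", sp$name),
      sprintf("PRECURSORMZ: %.4f", sp$precursor_mz),
      paste0("PRECURSORTYPE: ", sp$adduct),
      paste0("FORMULA: ", sp$formula),
      sprintf("Num Peaks: %d", nrow(sp$peaks))
    ), con)
    writeLines(sprintf("%.4f\t%.1f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname export_msp
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  peaks_mz <- peaks_int <- numeric(0)
  n_expected <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    cur$peaks <<- data.frame(mz = peaks_mz, intensity = peaks_int)
    if (nrow(cur$peaks) != n_expected) {
      stop("MSP record '", cur$name, "': expected ", n_expected,
           " peaks, found ", nrow(cur$peaks))
    }
    out[[length(out) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") { flush(); peaks_mz <- peaks_int <- numeric(0); next }
    if (grepl("^NAME:", ln)) {
      flush(); peaks_mz <- peaks_int <- numeric(0)
      cur <- list(name = trimws(sub("^NAME:", "", ln)),
                  species = NA_character_, lipid_class = NA_character_,
                  adduct = NA_character_, formula = NA_character_,
                  precursor_mz = NA_real_)
      cur$species <- sub(" \\[.*$", "", cur$name)
    } else if (grepl("^PRECURSORMZ:", ln)) {
      cur$precursor_mz <- as.numeric(sub("^PRECURSORMZ:", "", ln))
    } else if (grepl("^PRECURSORTYPE:", ln)) {
      cur$adduct <- trimws(sub("^PRECURSORTYPE:", "", ln))
    } else if (grepl("^FORMULA:", ln)) {
      cur$formula <- trimws(sub("^FORMULA:", "", ln))
    } else if (grepl("^Num Peaks:", ln)) {
      n_expected <- as.integer(sub("^Num Peaks:", "", ln))
    } else {
      parts <- strsplit(ln, "[\t ]+")[[1]]
      peaks_mz <- c(peaks_mz, as.numeric(parts[1]))
      peaks_int <- c(peaks_int, as.numeric(parts[2]))
    }
  }
  flush()
  out
}
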