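#' Read and write aligned feature tables
#'
#' The table layout mirrors a peak-alignment export: columns `feature_id`,
#' `mz`, `rt` (minutes), then one intensity column per sample. Sample roles
#' (sample / blank / qc) come from a separate metadata table, see
#' [read_sample_metadata()].
#'
#' @param path CSV (`.csv`) or TSV file.
#' @param samples optional sample metadata data frame; if given, every
#'   sample listed must have an intensity column.
#' @return data frame of aligned features.
#' @export
read_feature_table <- function(path, samples = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("feature_id", "mz", "rt")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("feature table missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  int_cols <- setdiff(names(df), required)
  for (cc in int_cols) {
    vals <- df[[cc]]
    if (!is.numeric(vals) || anyNA(vals)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(vals))))[1]
      stop("non-numeric or missing intensity in column '", cc,
           "', row ", bad, " (file line ", bad + 1L, ")")
    }
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples$sample_id, int_cols)
    if (length(miss) > 0) {
      stop("feature table lacks intensity column(s) for sample(s): ",
           paste(miss, collapse = ", "))
    }
  }
  stopifnot(all(df$mz > 0), all(df$rt >= 0))
  df
}

#' @rdname read_feature_table
#' @param features feature data frame.
#' @export
write_feature_table <- function(features, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(features, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Sample-role metadata
#'
#' Tab-separated table with columns `sample_id`, `role` (one of `sample`,
#' `blank`, `qc`), `strain`, `replicate`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "role", "strain", "replicate")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(df$role), c("sample", "blank", "qc"))
  if (length(bad) > 0) stop("unknown sample role(s): ",
                            paste(bad, collapse = ", "))
  df
}

#' @rdname read_sample_metadata
#' @param samples sample metadata data frame.
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write MGF MS2 files
#'
#' Minimal Mascot Generic Format support: BEGIN IONS / END IONS blocks with
#' PEPMASS, RTINSECONDS, TITLE and optional FEATURE_ID. Retention time is
#' converted to minutes on read.
#'
#' @param path MGF file.
#' @return list of spectra; each has `feature_id`, `title`, `precursor_mz`,
#'   `rt` (minutes) and `peaks` (data frame `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  mzs <- ints <- numeric(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "BEGIN IONS") {
      if (!is.null(cur)) stop("nested BEGIN IONS block")
      cur <- list(feature_id = NA_character_, title = NA_character_,
                  precursor_mz = NA_real_, rt = NA_real_)
      mzs <- ints <- numeric(0)
    } else if (ln == "END IONS") {
      if (is.null(cur)) stop("END IONS without BEGIN IONS")
      cur$peaks <- data.frame(mz = mzs, intensity = ints)
      stopifnot(all(cur$peaks$intensity > 0))
      cur$peaks <- cur$peaks[order(cur$peaks$mz), , drop = FALSE]
      rownames(cur$peaks) <- NULL
      out[[length(out) + 1L]] <- cur
      cur <- NULL
    } else if (is.null(cur) || ln == "") {
      next
    } else if (grepl("^PEPMASS=", ln)) {
      cur$precursor_mz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                              " ")[[1]][1])
    } else if (grepl("^RTINSECONDS=", ln)) {
      cur$rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
    } else if (grepl("^TITLE=", ln)) {
      cur$title <- sub("^TITLE=", "", ln)
    } else if (grepl("^FEATURE_ID=", ln)) {
      cur$feature_id <- sub("^FEATURE_ID=", "", ln)
    } else if (grepl("^[0-9]", ln)) {
      parts <- strsplit(ln, "[\t ]+")[[1]]
      mzs <- c(mzs, as.numeric(parts[1]))
      ints <- c(ints, as.numeric(parts[2]))
    }
  }
  if (!is.null(cur)) stop("unterminated BEGIN IONS block")
  out
}

#' @rdname read_mgf
#' @param spectra list of spectra.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(sp$feature_id)) {
      writeLines(paste0("FEATURE_ID=", sp$feature_id), con)
    }
    if (!is.null(sp$title) && !is.na(sp$title)) {
      writeLines(paste0("TITLE=", sp$title), con)
    }
    writeLines(sprintf("PEPMASS=%.4f", sp$precursor_mz), con)
    if (!is.na(sp$rt)) {
      writeLines(sprintf("RTINSECONDS=%.2f", sp$rt * 60), con)
    }
    writeLines(sprintf("%.4f %.1f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Retention-time correction from internal standards
#'
#' Locates each internal standard in the feature table by m/z, fits a
#' piecewise-linear mapping from observed to expected RT through the
#' located anchors (a constant shift when only one standard is usable), and
#' applies it to all features. Standards deviating more than
#' `max_dev` minutes from their expected RT are excluded from the fit with a
#' warning.
#'
#' @param features feature data frame (`mz`, `rt`).
#' @param standards data frame with `name`, `expected_rt`, `mz`.
#' @param mz_tol m/z window for locating a standard.
#' @param max_dev maximum tolerated RT deviation (minutes) for an anchor.
#' @return features with corrected `rt`; attribute `"rt_anchors"` records
#'   the anchors used and flags the excluded ones.
#' @export
rt_correct <- function(features, standards, mz_tol = 0.01, max_dev = 0.8) {
  anchors <- data.frame(name = character(0), observed = numeric(0),
                        expected = numeric(0), excluded = logical(0))
  for (i in seq_len(nrow(standards))) {
    hit <- which(abs(features$mz - standards$mz[i]) <= mz_tol)
    if (length(hit) == 0) next
    hit <- hit[which.min(abs(features$mz[hit] - standards$mz[i]))]
    obs <- features$rt[hit]
    excl <- abs(obs - standards$expected_rt[i]) > max_dev
    if (excl) {
      warning("internal standard '", standards$name[i], "' deviates ",
              sprintf("%.2f", abs(obs - standards$expected_rt[i])),
              " min from expected RT; excluded from correction")
    }
    anchors <- rbind(anchors,
                     data.frame(name = standards$name[i], observed = obs,
                                expected = standards$expected_rt[i],
                                excluded = excl))
  }
  usable <- anchors[!anchors$excluded, , drop = FALSE]
  if (nrow(usable) == 0) stop("no usable internal standard located")
  if (nrow(usable) == 1L) {
    shift <- usable$expected - usable$observed
    features$rt <- features$rt + shift
  } else {
    usable <- usable[order(usable$observed), ]
    features$rt <- stats::approx(usable$observed, usable$expected,
                                 xout = features$rt, rule = 2)$y
  }
  features$rt <- pmax(features$rt, 0)
  attr(features, "rt_anchors") <- anchors
  features
}

#' Blank filtering
#'
#' Keeps a feature when its maximum intensity across biological samples is
#' at least `factor` times its maximum across blanks ("lower than
#' `factor`-fold of the blank is filtered", so a ratio of exactly `factor`
#' survives). Features absent from all blanks are always kept.
#'
#' @param features feature data frame with intensity columns.
#' @param samples sample metadata (roles `sample` / `blank`).
#' @param factor fold-change threshold (default 10).
#' @return filtered feature data frame.
#' @export
blank_filter <- function(features, samples, factor = 10) {
  stopifnot(factor > 0)
  blank_ids <- samples$sample_id[samples$role == "blank"]
  sample_ids <- samples$sample_id[samples$role == "sample"]
  if (length(blank_ids) == 0) return(features)
  bmax <- apply(features[, blank_ids, drop = FALSE], 1, max)
  smax <- apply(features[, sample_ids, drop = FALSE], 1, max)
  keep <- bmax == 0 | smax >= factor * bmax
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotation and network coverage statistics
#'
#' Percentages are taken over the number of MS2-bearing features (the
#' denominator used when reporting annotation coverage) and rounded to two
#' decimals.
#'
#' @param n_features total aligned features.
#' @param n_with_ms2 features carrying an MS2 spectrum (> 0).
#' @param n_annotated features annotated against the library.
#' @param n_network features retained in the molecular network (optional).
#' @return list with the counts plus `pct_annotated` and `pct_network`.
#' @export
#' @examples
#' coverage_stats(6470, 2347, 162, 444)
coverage_stats <- function(n_features, n_with_ms2, n_annotated,
                           n_network = NA_integer_) {
  if (n_with_ms2 <= 0) stop("n_with_ms2 must be positive")
  list(n_features = n_features,
       n_with_ms2 = n_with_ms2,
       n_annotated = n_annotated,
       pct_annotated = round(100 * n_annotated / n_with_ms2, 2),
       n_network = n_network,
       pct_network = if (is.na(n_network)) NA_real_ else
         round(100 * n_network / n_with_ms2, 2))
}

#' @rdname coverage_stats
#' @param features feature data frame.
#' @param spectra MGF spectra list (linked by `feature_id`).
#' @param annotations annotation table (uses accepted rows).
#' @param network_ids feature ids retained in the filtered network.
#' @export
summarize_coverage <- function(features, spectra, annotations = NULL,
                               network_ids = character(0)) {
  ms2_ids <- unique(vapply(spectra, function(s) s$feature_id, character(1)))
  ms2_ids <- intersect(ms2_ids, features$feature_id)
  ann_ids <- if (is.null(annotations)) character(0) else
    unique(annotations$feature_id[annotations$accepted])
  coverage_stats(nrow(features), length(ms2_ids),
                 length(intersect(ann_ids, ms2_ids)),
                 length(intersect(network_ids, ms2_ids)))
}
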