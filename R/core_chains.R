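#' Aggregate intact polar lipids into diether core profiles
#'
#' Every diether-bearing lipid (core, phospholipid, glycolipid, cardiolipin)
#' contributes its abundance to the core variant it is built on; cardiolipins
#' carry two cores and contribute with weight 2. Menaquinones and
#' bacterioruberin have no isoprenoid diether core and are excluded.
#' Replicate columns are averaged per strain.
#'
#' @param unique_lipids unique-lipid table from [collapse_unique()] (or a
#'   compatible data frame with `lipid_class`, `class_group`, `chain1`,
#'   `chain2`, `unsat`, `n_cores` and per-sample abundances).
#' @param samples sample metadata (`sample_id`, `role`, `strain`).
#' @return data frame: `core`, `chain1`, `chain2`, `unsat`, then one
#'   abundance column per strain.
#' @export
to_core_profile <- function(unique_lipids, samples) {
  core_groups <- c("core", "phospholipid", "glycolipid", "cardiolipin")
  skip_groups <- c("quinone", "carotenoid")
  bad <- setdiff(unique(unique_lipids$class_group),
                 c(core_groups, skip_groups))
  if (length(bad) > 0) {
    stop("lipid without a diether core in core aggregation: ",
         paste(bad, collapse = ", "))
  }
  li <- unique_lipids[unique_lipids$class_group %in% core_groups, ,
                      drop = FALSE]
  samp <- samples[samples$role == "sample", , drop = FALSE]
  strains <- unique(samp$strain)
  strain_ab <- sapply(strains, function(st) {
    ids <- samp$sample_id[samp$strain == st]
    rowMeans(li[, ids, drop = FALSE])
  })
  if (is.null(dim(strain_ab))) strain_ab <- matrix(strain_ab, nrow = nrow(li))
  colnames(strain_ab) <- strains
  key <- sprintf("%s(%d:%d;u%d)",
                 mapply(core_label, li$chain1, li$chain2),
                 li$chain1, li$chain2, li$unsat)
  w <- li$n_cores
  out <- list()
  for (k in sort(unique(key))) {
    sel <- key == k
    first <- which(sel)[1]
    ab <- colSums(strain_ab[sel, , drop = FALSE] * w[sel])
    rec <- data.frame(core = k, chain1 = li$chain1[first],
                      chain2 = li$chain2[first], unsat = li$unsat[first])
    out[[length(out) + 1L]] <- cbind(rec, as.data.frame(t(ab)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-strain chain-level statistics of a core profile
#'
#' For each strain: the percentage of core abundance carried by unsaturated
#' cores, the percentage of isoprenoid chains (two per core) that are C25,
#' and -- among the unsaturated cores only -- the split into low
#' (`unsat < 4`) and poly (`unsat >= 4`) unsaturation. When a strain has no
#' unsaturated cores the low/poly split is reported as 0/0 with
#' `all_saturated = TRUE`.
#'
#' @param profile core profile from [to_core_profile()].
#' @return data frame, one row per strain: `strain`, `pct_unsaturated`,
#'   `pct_c25_chains`, `pct_low`, `pct_poly`, `all_saturated`.
#' @export
core_profile_stats <- function(profile) {
  stopifnot(nrow(profile) > 0)
  strains <- setdiff(names(profile), c("core", "chain1", "chain2", "unsat"))
  n25 <- (profile$chain1 == 25L) + (profile$chain2 == 25L)
  out <- lapply(strains, function(st) {
    ab <- profile[[st]]
    tot <- sum(ab)
    uns <- sum(ab[profile$unsat > 0])
    poly <- sum(ab[profile$unsat >= 4])
    c25 <- sum(ab * n25) / (2 * tot) * 100
    all_sat <- uns == 0
    data.frame(strain = st,
               pct_unsaturated = 100 * uns / tot,
               pct_c25_chains = c25,
               pct_low = if (all_sat) 0 else 100 * (uns - poly) / uns,
               pct_poly = if (all_sat) 0 else 100 * poly / uns,
               all_saturated = all_sat)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert a C25 chain fraction to an Ext-AR molecule fraction
#'
#' When no molecule carries two C25 chains (no diExt-AR), each extended
#' archaeol contributes exactly one C25 chain out of its two chains, so the
#' molecule-level percentage is twice the chain-level percentage.
#'
#' @param f_chain percentage of all isoprenoid chains that are C25
#'   (0 to 50 under the no-diExt-AR precondition).
#' @return percentage of core-lipid molecules that are Ext-AR.
#' @export
#' @examples
#' chain_fraction_to_molecule_fraction(13.44) # 26.88
chain_fraction_to_molecule_fraction <- function(f_chain) {
  stopifnot(is.numeric(f_chain))
  if (any(f_chain < 0)) stop("chain fraction must be non-negative")
  if (any(f_chain > 50)) {
    stop("chain fraction > 50% implies molecules with two C25 chains ",
         "(diExt-AR), violating the no-diExt-AR precondition")
  }
  2 * f_chain
}

#' Unsaturation summary of a core profile
#'
#' Convenience wrapper around [core_profile_stats()] returning only the
#' unsaturation columns; `pct_low + pct_poly = 100` whenever any unsaturated
#' core is present.
#'
#' @param profile core profile from [to_core_profile()].
#' @return data frame with `strain`, `pct_unsaturated`, `pct_low`,
#'   `pct_poly`, `all_saturated`.
#' @export
unsaturation_summary <- function(profile) {
  st <- core_profile_stats(profile)
  st[, c("strain", "pct_unsaturated", "pct_low", "pct_poly",
         "all_saturated")]
}
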