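test_that("the default strain profiles encode the survey presence pattern", {
  prof <- default_profiles()
  expect_length(prof, 7)
  tiers <- sapply(prof, function(p) p$tiers)
  colnames(tiers) <- sapply(prof, `[[`, "strain")
  # TGD-PA only in Ha. argentinensis
  expect_identical(names(which(tiers["TGD-PA", ] != "absent")),
                   "Ha_argentinensis")
  # bis-sulfated glycolipids only in Ht. turkmenica and Na. asiatica
  expect_setequal(names(which(tiers["2S-DGD", ] != "absent")),
                  c("Ht_turkmenica", "Na_asiatica"))
  # bacterioruberin absent from Na. asiatica only
  expect_identical(names(which(tiers["BR", ] == "absent")), "Na_asiatica")
  # universal classes
  for (cl in c("MK", "AR", "Me-PGP", "PG")) {
    expect_true(all(tiers[cl, ] == "major"))
  }
  # extended archaeol above a 10% chain fraction only in Natrialbales
  f25 <- sapply(prof, `[[`, "f_c25")
  orders <- sapply(prof, `[[`, "order")
  expect_true(all(f25[orders == "Natrialbales"] > 0.10))
  expect_true(all(f25[orders != "Natrialbales"] < 0.01))
})

test_that("simulation is deterministic and closed over ground truth", {
  a <- simulate_lipidome(config = sim_config(seed = 99))
  b <- simulate_lipidome(config = sim_config(seed = 99))
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  expect_identical(a$alignment, b$alignment)
  # every feature traces to exactly one ground-truth record
  expect_identical(sort(a$features$feature_id), sort(a$truth$feature_id))
  expect_false(any(duplicated(a$truth$feature_id)))
  expect_true(all(a$truth$kind %in% c("library", "analog", "contaminant",
                                      "internal_standard", "na_adduct")))
  # blanks contain only contaminants
  blank_cols <- a$samples$sample_id[a$samples$role == "blank"]
  in_blank <- apply(a$features[, blank_cols, drop = FALSE], 1, max) > 0
  expect_true(all(a$truth$kind[in_blank] == "contaminant"))
})

test_that("a noise-free decoy-free run is annotated perfectly", {
  sim <- simulate_lipidome(config = sim_config(
    seed = 8, mz_sigma = 0, intensity_cv = 0, n_contaminants = 0,
    n_analogs = 0, n_noise_peaks = 0, emit_na_adducts = FALSE))
  ann <- annotate_features(sim$features, sim$spectra, sim$library)
  ev <- evaluate_annotation(ann, sim$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$fdr, 0)
})

test_that("raising the m/z jitter never raises annotation recall", {
  recalls <- vapply(c(0.001, 0.005, 0.02, 0.05), function(sig) {
    sim <- simulate_lipidome(config = sim_config(seed = 17,
                                                 mz_sigma = sig))
    ann <- annotate_features(sim$features, sim$spectra, sim$library)
    evaluate_annotation(ann, sim$truth)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
  expect_lt(recalls[4], recalls[1])
})

test_that("configured chain fractions are recovered from the lipidome", {
  sim <- simulate_lipidome(config = sim_config(seed = 42))
  feats <- blank_filter(sim$features, sim$samples, 10)
  ann <- annotate_features(feats, sim$spectra, sim$library)
  uniq <- collapse_unique(ann, feats, sim$samples, sim$species_table)
  st <- core_profile_stats(to_core_profile(uniq, sim$samples))
  for (p in sim$profiles) {
    got <- st$pct_c25_chains[st$strain == p$strain]
    expect_lt(abs(got - 100 * p$f_c25), 1)
    got_u <- st$pct_unsaturated[st$strain == p$strain]
    expect_lt(abs(got_u - 100 * p$f_unsat), 2)
  }
})

test_that("the toy 16S alignment separates orders by p-distance", {
  sim <- simulate_lipidome(config = sim_config(seed = 23))
  d <- p_distance(sim$alignment)
  orders <- setNames(sapply(sim$profiles, `[[`, "order"),
                     sapply(sim$profiles, `[[`, "strain"))
  within <- between <- numeric(0)
  for (i in rownames(d)) for (j in colnames(d)) {
    if (i >= j) next
    if (orders[i] == orders[j]) within <- c(within, d[i, j])
    else between <- c(between, d[i, j])
  }
  expect_lt(max(within), min(between))
  # NJ tree on the toy alignment clusters strains by order
  tr <- nj_tree(d)
  for (o in unique(orders)) {
    tips <- names(orders)[orders == o]
    if (length(tips) < 2) next
    expect_true(ape::is.monophyletic(tr, tips))
  }
})
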