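small_library <- function() {
  sp <- enumerate_library(library_config(
    classes = c("AR", "PG", "S-DGD"), unsat_range = 0:1))
  build_spectral_library(sp)
}

test_that("a spectrum matches its own library entry with score 100", {
  lib <- small_library()
  entry <- lib[[5]]
  shuffled <- entry$peaks[sample(nrow(entry$peaks)), ]
  res <- match_feature(entry$precursor_mz, shuffled, lib)
  expect_equal(res$total[1], 100)
  expect_true(res$accepted[1])
  expect_identical(res$species[1], entry$species)
})

test_that("MS1 tolerance and the 70% threshold gate acceptance", {
  lib <- small_library()
  entry <- lib[[1]]
  expect_equal(nrow(match_feature(entry$precursor_mz + 0.02,
                                  entry$peaks, lib)), 0)
  # shared precursor but disjoint fragments: dot 0, rejected
  junk <- data.frame(mz = c(111.1, 222.2, 333.3), intensity = c(5, 5, 5))
  res <- match_feature(entry$precursor_mz, junk, lib)
  best <- res[res$species == entry$species & res$adduct == entry$adduct, ]
  expect_equal(best$dot, 0)
  expect_lt(best$total, 70)
  expect_false(best$accepted)
  # MS1-only candidates are flagged and never accepted
  res0 <- match_feature(entry$precursor_mz, NULL, lib)
  expect_true(all(res0$ms1_only))
  expect_false(any(res0$accepted))
})

test_that("lowering the threshold never decreases accepted candidates", {
  lib <- small_library()
  entry <- lib[[3]]
  noisy <- entry$peaks
  noisy$intensity <- noisy$intensity * runif(nrow(noisy), 0.2, 1)
  prev <- Inf
  for (th in c(30, 50, 70, 90)) {
    n <- sum(match_feature(entry$precursor_mz, noisy, lib,
                           threshold = th)$accepted)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("adduct forms and RT isomers collapse to one unique lipid", {
  sp <- enumerate_library()
  samples <- data.frame(sample_id = c("s1", "s2"),
                        role = "sample", strain = "A", replicate = 1:2)
  ann <- data.frame(feature_id = c("F1", "F2", "F3"),
                    species = "PG(20:20;u0)", adduct = c("[M+H]+",
                                                         "[M+NH4]+",
                                                         "[M+H]+"),
                    lipid_class = "PG", accepted = TRUE)
  feats <- data.frame(feature_id = c("F1", "F2", "F3"),
                      mz = c(805.7, 822.7, 805.7), rt = c(10, 10, 12),
                      s1 = c(100, 50, 10), s2 = c(200, 100, 20))
  uniq <- collapse_unique(ann, feats, samples, sp)
  expect_equal(nrow(uniq), 1)
  expect_equal(uniq$n_members, 3)
  expect_equal(uniq$s1, 160)
  expect_equal(uniq$s2, 320)
  # collapse conservation over a larger random assignment
  set.seed(7)
  species_pool <- sample(sp$name[sp$lipid_class %in% c("PG", "DGD")], 10)
  n <- 30
  ann2 <- data.frame(feature_id = sprintf("G%02d", 1:n),
                     species = sample(species_pool, n, replace = TRUE),
                     adduct = "[M+H]+", lipid_class = "x", accepted = TRUE)
  ann2$lipid_class <- sub("\\(.*$", "", ann2$species)
  feats2 <- data.frame(feature_id = ann2$feature_id, mz = 800, rt = 1,
                       s1 = runif(n), s2 = runif(n))
  uniq2 <- collapse_unique(ann2, feats2, samples, sp)
  expect_equal(sum(uniq2$n_members), n)
  expect_equal(sum(uniq2$s1), sum(feats2$s1))
})

test_that("semi-quantification is a ratio to the internal standard", {
  samples <- data.frame(sample_id = c("s1", "s2"),
                        role = "sample", strain = "A", replicate = 1:2)
  feats <- data.frame(feature_id = c("F1", "IS"), mz = c(700, 818.66),
                      rt = c(10, 15), s1 = c(2000, 2000),
                      s2 = c(500, 1000))
  q <- semi_quantify(feats, samples, is_feature_id = "IS",
                     spike_amount = 50)
  expect_equal(q$s1[1], 50)     # equal to IS -> spike amount
  expect_equal(q$s2[1], 25)
  # doubling all raw intensities leaves abundances unchanged
  feats2 <- feats
  feats2[, c("s1", "s2")] <- feats2[, c("s1", "s2")] * 2
  q2 <- semi_quantify(feats2, samples, is_feature_id = "IS",
                      spike_amount = 50)
  expect_equal(q2$s1, q$s1)
  feats$s2[2] <- 0
  expect_error(semi_quantify(feats, samples, is_feature_id = "IS"),
               "s2")
})

test_that("class summary groups counts and totals correctly", {
  expect_equal(class_summary(data.frame(lipid_class = character(0),
                                        class_group = character(0)))$total,
               0)
  hg <- head_groups()
  two <- data.frame(lipid_class = c("PG", "PG", "MK"))
  two$class_group <- hg$class_group[match(two$lipid_class,
                                          hg$lipid_class)]
  cs <- class_summary(two)
  expect_equal(cs$per_class$n[cs$per_class$lipid_class == "PG"], 2)
  expect_equal(cs$per_group$n[cs$per_group$class_group == "quinone"], 1)
  expect_equal(cs$total, 3)
})
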