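test_that("spectrum filtering removes precursor region and keeps top-k", {
  cfg <- network_config()
  pk <- data.frame(mz = c(100, 200, 300), intensity = c(10, 20, 30))
  expect_equal(filter_spectrum(pk, 800, cfg), pk)       # under top-6
  near <- data.frame(mz = c(100, 790), intensity = c(10, 99))
  out <- filter_spectrum(near, 800, cfg)
  expect_equal(out$mz, 100)                             # within 17 Da gone
  # 8 equally spaced peaks mutually within one window: exactly the 6 most
  # intense survive (checked against a brute-force window scan)
  dense <- data.frame(mz = 400 + 3 * (0:7), intensity = c(8, 3, 7, 1, 5,
                                                          2, 6, 4))
  out2 <- filter_spectrum(dense, 900, cfg)
  brute_keep <- sapply(seq_len(8), function(i) {
    win <- abs(dense$mz - dense$mz[i]) <= 25
    rank(-dense$intensity[win])[which(which(win) == i)] <= 6
  })
  expect_equal(out2$mz, sort(dense$mz[brute_keep]))
  expect_equal(nrow(out2), 6)
})

test_that("spectrum filtering is idempotent", {
  cfg <- network_config()
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    pk <- data.frame(mz = runif(n, 100, 900),
                     intensity = runif(n, 1, 100))
    once <- filter_spectrum(pk, 900, cfg)
    if (nrow(once) == 0) next
    expect_equal(filter_spectrum(once, 900, cfg), once)
  }
})

test_that("modified cosine is a proper similarity", {
  s <- make_spec(c(100, 200, 300, 400, 500, 550, 600),
                 c(10, 20, 30, 40, 50, 60, 70), 700)
  self <- modified_cosine(s, s)
  expect_equal(self$score, 1)
  expect_equal(self$n_matched, 7L)
  a <- make_spec(c(100, 200), c(5, 5), 600)
  b <- make_spec(c(310, 420), c(5, 5), 600)
  expect_equal(modified_cosine(a, b)$score, 0)
  empty <- make_spec(numeric(0), numeric(0), 600)
  expect_equal(modified_cosine(empty, s)$score, 0)
})

test_that("modified cosine equals the exhaustive assignment oracle", {
  set.seed(21)
  for (rep in 1:40) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    amz <- sort(runif(na, 100, 600))
    prec_a <- 700; prec_b <- 700 + sample(c(0, 18.03, -14.02, 5.5), 1)
    # engineer overlap: some B peaks copy A directly, some shifted
    k <- min(3, na)
    bmz <- sort(c(amz[sample(na, k)] + runif(k, -0.03, 0.03),
                  amz[sample(na, min(2, na))] + (prec_b - prec_a),
                  runif(nb, 100, 600)))[seq_len(nb)]
    a <- make_spec(amz, runif(na, 1, 100), prec_a)
    b <- make_spec(bmz, runif(nb, 1, 100), prec_b)
    got <- modified_cosine(a, b)
    want <- oracle_modified_cosine(a, b)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$n_matched, want$n_matched)
    sym <- modified_cosine(b, a)
    expect_equal(sym$score, got$score, tolerance = 1e-12)
  }
})

ten_peaks <- function(prec, shift = 0, id = "X") {
  make_spec(seq(150, 420, length.out = 10) + shift,
            rep(c(30, 50), 5), prec, feature_id = id)
}

test_that("edges require both the cosine and shared-peak conditions", {
  cfg <- network_config()
  a <- ten_peaks(700, id = "A")
  b <- ten_peaks(700, id = "B")
  net <- build_network(list(a, b), cfg)
  expect_equal(nrow(net$edges), 1)
  expect_gt(net$edges$cosine, 0.99)
  # identical 4-peak spectra: cosine 1 but only 4 shared peaks -> no edge
  a4 <- make_spec(c(150, 250, 350, 450), c(10, 20, 30, 40), 700, "A")
  b4 <- make_spec(c(150, 250, 350, 450), c(10, 20, 30, 40), 700, "B")
  expect_equal(nrow(build_network(list(a4, b4), cfg)$edges), 0)
  # dissimilar spectra: no edges
  set.seed(3)
  singles <- lapply(1:5, function(i) {
    make_spec(sort(runif(8, 100, 600)), runif(8, 1, 100),
              650 + 40 * i, paste0("S", i))
  })
  expect_equal(nrow(build_network(singles, cfg)$edges), 0)
  # deterministic under input order
  net_rev <- build_network(list(b, a), cfg)
  expect_identical(net$edges, net_rev$edges)
  expect_identical(net$nodes, net_rev$nodes)
})

chain_net <- function(ids, mzs) {
  n <- length(ids)
  structure(list(
    nodes = data.frame(feature_id = ids, mz = mzs),
    edges = data.frame(from = ids[-n], to = ids[-1],
                       cosine = 0.9, matched_peaks = 6L, delta_mz = 0)),
    class = "mol_network")
}

test_that("network filtration removes blanks, low m/z, then small components", {
  cfg <- network_config()
  net <- chain_net(paste0("N", 1:3), rep(600, 3))
  expect_equal(nrow(filter_network(net, character(0), cfg)$nodes), 0)
  net4 <- chain_net(paste0("N", 1:4), c(499.9, 500.0, 600, 700))
  f4 <- filter_network(net4, character(0), cfg)
  expect_false("N1" %in% f4$nodes$feature_id)   # 499.9 removed
  # remaining component has 3 nodes -> removed entirely
  expect_equal(nrow(f4$nodes), 0)
  net5 <- chain_net(paste0("N", 1:5), rep(600, 5))
  f5 <- filter_network(net5, blank_ids = c("N1", "N5"), cfg)
  expect_equal(nrow(f5$nodes), 0)   # 5 - 2 blanks = 3 < 4
  net6 <- chain_net(paste0("N", 1:6), rep(600, 6))
  f6 <- filter_network(net6, blank_ids = c("N5", "N6"), cfg)
  expect_equal(nrow(f6$nodes), 4)   # boundary component size 4 is kept
})

test_that("components are categorised by majority class or dominant taxon", {
  net <- chain_net(paste0("N", 1:8), rep(600, 8))
  net$edges <- net$edges[-4, ]   # split into N1-4 and N5-8
  ann <- data.frame(feature_id = c("N1", "N2", "N3"),
                    lipid_class = c("PG", "PG", "DGD"), accepted = TRUE)
  occ <- rbind(
    data.frame(feature_id = paste0("N", 1:4), strain = "S1"),
    data.frame(feature_id = paste0("N", 5:8), strain = c("H1", "H1",
                                                         "H2", "H1")))
  taxa <- data.frame(strain = c("S1", "H1", "H2"),
                     taxon = c("Natrialba", "Haloferax", "Haloferax"))
  cats <- categorize_components(net, ann, occ, taxa)
  expect_setequal(cats$category, c("PG", "Haloferax-dominant unknown"))
  # mixed-strain all-unknown component
  occ2 <- rbind(occ[1:4, ],
                data.frame(feature_id = paste0("N", 5:8),
                           strain = c("S1", "S1", "H1", "H2")))
  taxa2 <- data.frame(strain = c("S1", "H1", "H2"),
                      taxon = c("Natrialba", "Haloferax", "Haloarcula"))
  cats2 <- categorize_components(net, ann[0, ], occ2, taxa2)
  expect_true("unknown" %in% cats2$category)
})

test_that("network summary partitions nodes exactly", {
  net <- chain_net(paste0("N", 1:9), rep(600, 9))
  net$edges <- net$edges[-c(4, 6), ]  # components {1-4}, {5-6}, {7-9}
  s <- network_summary(net, identified_ids = c("N1", "N5"))
  expect_equal(s$n_nodes, 9)
  expect_equal(s$n_identified, 2)
  expect_equal(s$n_analogs, 4)   # N2-4 with N1; N6 with N5
  expect_equal(s$n_new, 3)       # N7-9 all-unknown
  expect_equal(s$n_identified + s$n_analogs + s$n_new, s$n_nodes)
  empty <- structure(list(nodes = data.frame(feature_id = character(0),
                                             mz = numeric(0)),
                          edges = net$edges[0, ]), class = "mol_network")
  expect_equal(network_summary(empty, character(0))$n_nodes, 0)
})
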