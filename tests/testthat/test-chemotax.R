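test_that("matrix preparation scales samples and normalises for ordination", {
  set.seed(5)
  m <- matrix(rlnorm(60, 3, 1), nrow = 10,
              dimnames = list(paste0("L", 1:10), paste0("S", 1:6)))
  m[2, 3] <- 0
  cl <- prepare_matrix(m, "cluster")
  expect_true(all(abs(colMeans(cl)) < 1e-9))
  expect_true(all(abs(apply(cl, 2, sd) - 1) < 1e-9))
  ord <- prepare_matrix(m, "ordination")
  expect_true(all(abs(colSums(10^ord) - 1) < 1e-9))
  # doubling one sample's raw intensities leaves its ordination values alone
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(prepare_matrix(m2, "ordination")[, 1], ord[, 1])
  expect_error(prepare_matrix(cbind(m, 0), "cluster"), "all-zero")
  expect_warning(prepare_matrix(matrix(c(1, 1, 2, 3), 2), "cluster"),
                 "constant")
})

test_that("linkages agree on simple geometries", {
  # two identical columns merge at height zero
  m <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(9, 9, 9))
  hc <- hcluster(m, "complete")
  expect_equal(min(hc$height), 0)
  # three points on a line (0, 1, 10): closest pair joins first everywhere
  line <- rbind(c(A = 0, B = 1, C = 10))
  for (lk in c("complete", "single", "ward", "average")) {
    h <- hcluster(line, lk)
    first <- h$labels[-h$merge[1, ]]
    expect_setequal(first, c("A", "B"))
  }
  expect_error(hcluster(cbind(A = c(1, NA), B = c(1, 2)), "single"),
               "NaN")
  nwk <- dendrogram_newick(hcluster(m, "average"))
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("PCA reconstructs the data and separates orthogonal groups", {
  set.seed(9)
  m <- matrix(rnorm(48), nrow = 8,
              dimnames = list(paste0("L", 1:8), paste0("S", 1:6)))
  p <- pca_lipidome(m, n_components = 5)
  recon <- p$scores %*% t(p$loadings)
  centered <- t(m) - rep(colMeans(t(m)), each = 6)
  expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
  # two orthogonal blocks separate by PC1 sign
  toy <- cbind(matrix(rep(c(5, 0), c(4, 4)), 8, 3) + rnorm(24, 0, 0.1),
               matrix(rep(c(0, 5), c(4, 4)), 8, 3) + rnorm(24, 0, 0.1))
  colnames(toy) <- paste0("S", 1:6); rownames(toy) <- paste0("L", 1:8)
  sc <- pca_lipidome(toy, 2)$scores[, 1]
  expect_true(all(sign(sc[1:3]) == sign(sc[1])))
  expect_true(all(sign(sc[4:6]) == -sign(sc[1])))
  expect_error(pca_lipidome(m, 10), "rank")
})

test_that("VIP scores satisfy their identity and rank discriminants first", {
  set.seed(13)
  n_per <- 6
  classes <- rep(c("a", "b"), each = n_per)
  mat <- matrix(rnorm(20 * 2 * n_per), nrow = 20,
                dimnames = list(paste0("L", 1:20), NULL))
  mat[7, ] <- ifelse(classes == "a", 5, -5) + rnorm(2 * n_per, 0, 0.1)
  mat[1, ] <- 3            # constant across classes
  vip <- plsda_vip(mat, classes)
  expect_equal(mean(vip$vip^2), 1, tolerance = 1e-6)
  expect_identical(vip$feature[1], "L7")
  expect_lt(vip$vip[vip$feature == "L1"], 0.5)
  expect_error(plsda_vip(mat, rep("a", 2 * n_per)), "two classes")
  expect_error(plsda_vip(mat[, 1:3], c("a", "a", "b")), "two samples")
})

test_that("p-distance and NJ recover additive trees exactly", {
  aln <- c(A = "acgtacgtac", B = "acgtacgtac", C = "ttttacgtac")
  d <- p_distance(aln)
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 0.3)
  expect_error(p_distance(c(A = "acgt", B = "acg")), "ragged")
  # 4-taxon additive matrix: NJ against the least-squares topology oracle
  tr <- ape::read.tree(text = "((A:2,B:3):1.5,(C:1,D:4):1.5);")
  D <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  fit <- oracle_nj4(D)
  expect_setequal(fit$sister, c("A", "B"))
  expect_lt(fit$resid, 1e-18)
  njt <- nj_tree(D)
  expect_equal(phangorn::RF.dist(ape::unroot(njt), ape::unroot(tr)), 0)
  expect_equal(ape::cophenetic.phylo(njt)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-8)
  # random additive matrices on 5 and 6 taxa
  set.seed(2)
  for (n in c(5, 6)) {
    rt <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    rt <- ape::unroot(rt)
    D2 <- ape::cophenetic.phylo(rt)
    nj2 <- nj_tree(D2)
    expect_equal(phangorn::RF.dist(ape::unroot(nj2), rt), 0)
    expect_equal(ape::cophenetic.phylo(nj2)[rownames(D2), colnames(D2)],
                 D2, tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("bootstrap gives full support for clean clades, order-invariant", {
  # two clean clades, each backed by 8 congruent sites, no conflicts
  anc <- rep("a", 32)
  put <- function(s, idx, b) { s[idx] <- b; paste(s, collapse = "") }
  aln <- c(t1 = put(anc, 1:8, "c"),
           t2 = put(strsplit(put(anc, 1:8, "c"), "")[[1]], 32, "g"),
           t3 = put(anc, 9:16, "g"),
           t4 = put(anc, 17:24, "t"),
           t5 = put(strsplit(put(anc, 17:24, "t"), "")[[1]], 31, "c"))
  bs <- nj_bootstrap(aln, n = 100, seed = 4)
  expect_true(all(bs$support >= 0.99, na.rm = TRUE))
  bs2 <- nj_bootstrap(aln[c(3, 1, 5, 2, 4)], n = 100, seed = 4)
  expect_equal(bs$support, bs2$support)
})

test_that("concordance agrees with the direct ARI formula", {
  m <- cbind(A = c(0, 0), B = c(0.1, 0), C = c(5, 5), D = c(5.1, 5),
             E = c(10, 0), F = c(10, 0.1), G = c(10.2, 0))
  hc <- hcluster(m, "complete")
  labels <- c(A = "g1", B = "g1", C = "g2", D = "g2", E = "g3", F = "g3",
              G = "g3")
  cc <- concordance(hc, labels, k = 3)
  expect_equal(cc$ari, 1)
  expect_equal(concordance(hc, labels, k = 1)$ari, 0)
  # one strain moved between groups: matches the closed-form ARI
  wrong <- labels; wrong["G"] <- "g2"
  cc2 <- concordance(hc, wrong, k = 3)
  expect_lt(cc2$ari, 1)
  expect_equal(cc2$ari, oracle_ari(cc2$clusters[names(wrong)], wrong))
  # RF distance zero against the matching topology
  ref <- ape::read.tree(text = "((A:1,B:1):1,((C:1,D:1):1,((E:1,F:1):0.5,G:1):1):1);")
  expect_equal(concordance(hc, labels, k = 3, ref_tree = ref)$rf, 0)
  expect_error(concordance(hc, labels[1:5], k = 3), "mismatch")
})
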