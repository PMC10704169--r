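#' Prepare a lipidome matrix for clustering or ordination
#'
#' Zeros are replaced by half the smallest positive value in the matrix
#' before the log. In `cluster` mode, values are log10-transformed and then
#' z-scored within each sample column (constant columns fall back to sd = 1
#' with a warning). In `ordination` mode, each column is divided by its sum
#' (total-abundance normalisation) and then log10-transformed.
#'
#' @param abund numeric matrix, lipids (rows) x samples/strains (columns);
#'   non-negative.
#' @param mode `"cluster"` or `"ordination"`.
#' @return transformed matrix with attributes `mode` recorded.
#' @export
prepare_matrix <- function(abund, mode = c("cluster", "ordination")) {
  mode <- match.arg(mode)
  abund <- as.matrix(abund)
  if (any(abund < 0)) stop("abundances must be non-negative")
  if (any(colSums(abund) == 0)) stop("all-zero sample column")
  pos <- abund[abund > 0]
  if (length(pos) == 0) stop("matrix has no positive values")
  abund[abund == 0] <- min(pos) / 2
  if (mode == "cluster") {
    x <- log10(abund)
    out <- apply(x, 2, function(col) {
      s <- stats::sd(col)
      if (s == 0) {
        warning("constant sample column under scaling; sd fallback to 1")
        s <- 1
      }
      (col - mean(col)) / s
    })
    rownames(out) <- rownames(abund)
  } else {
    out <- log10(sweep(abund, 2, colSums(abund), "/"))
  }
  attr(out, "mode") <- mode
  out
}

.linkage_methods <- c(complete = "complete", single = "single",
                      ward = "ward.D", average = "average")

#' Hierarchical clustering of strains by lipidome
#'
#' Agglomerative clustering of the matrix columns (strains) on Euclidean
#' distances. `"ward"` maps to the classical Ward criterion on Euclidean
#' distances (`hclust` method `ward.D`).
#'
#' @param mat prepared matrix (lipids x strains), see [prepare_matrix()].
#' @param linkage one of `"complete"`, `"single"`, `"ward"`, `"average"`.
#' @return an `hclust` object.
#' @export
hcluster <- function(mat, linkage = c("complete", "single", "ward",
                                      "average")) {
  linkage <- match.arg(linkage)
  if (anyNA(mat)) stop("NaN/NA in matrix")
  stopifnot(ncol(mat) >= 2)
  d <- stats::dist(t(mat), method = "euclidean")
  stats::hclust(d, method = .linkage_methods[[linkage]])
}

#' Newick string for a dendrogram
#'
#' @param hc an `hclust` object.
#' @return single Newick string with merge heights as branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Principal component analysis of a lipidome matrix
#'
#' Column-centred PCA of the strains-as-observations matrix.
#'
#' @param mat prepared matrix (lipids x strains).
#' @param n_components number of components to return.
#' @return list with `scores` (strains x components), `loadings`,
#'   `explained` (variance fractions, non-increasing).
#' @export
pca_lipidome <- function(mat, n_components = 2) {
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  p <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  r <- sum(p$sdev > 1e-12)
  if (n_components > r) {
    stop("n_components exceeds matrix rank (", r, ")")
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       loadings = p$rotation[, seq_len(n_components), drop = FALSE],
       explained = ev[seq_len(n_components)])
}

#' PLS-DA variable importance in projection
#'
#' Two-component PLS-DA fitted by NIPALS on per-feature autoscaled data
#' against a centred class-indicator matrix, with deflation between
#' components. VIP for feature j is
#' sqrt(p * sum_a(w_ja^2 * SSY_a) / sum_a(SSY_a)) where SSY_a is the
#' Y-variance explained by component a; mean(VIP^2) = 1 by construction.
#'
#' @param mat matrix, features (rows) x samples (columns).
#' @param classes class label per sample column (>= 2 classes, each with
#'   >= 2 samples).
#' @param n_components number of latent variables.
#' @return data frame `feature`, `vip`, sorted by decreasing VIP.
#' @export
plsda_vip <- function(mat, classes, n_components = 2) {
  classes <- as.factor(classes)
  if (nlevels(classes) < 2) stop("PLS-DA needs at least two classes")
  if (any(table(classes) < 2)) {
    stop("every class needs at least two samples")
  }
  X <- t(as.matrix(mat))                      # samples x features
  X <- scale(X)                               # autoscale per feature
  X[, attr(X, "scaled:scale") == 0] <- 0
  Y <- stats::model.matrix(~ classes - 1)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  Xa <- X; Ya <- Y
  for (a in seq_len(n_components)) {
    u <- Ya[, which.max(colSums(Ya^2))]
    for (it in 1:500) {
      w <- crossprod(Xa, u); w <- w / sqrt(sum(w^2))
      tt <- Xa %*% w
      q <- crossprod(Ya, tt) / sum(tt^2)
      u_new <- Ya %*% q / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u^2)) { u <- u_new; break }
      u <- u_new
    }
    p_load <- crossprod(Xa, tt) / sum(tt^2)
    ssy[a] <- sum((tt %*% t(q))^2)
    W[, a] <- w; Tm[, a] <- tt
    Xa <- Xa - tt %*% t(p_load)
    Ya <- Ya - tt %*% t(q)
  }
  vip2 <- p * (W^2 %*% ssy) / sum(ssy)
  res <- data.frame(feature = colnames(X), vip = sqrt(as.numeric(vip2)))
  res[order(-res$vip), , drop = FALSE]
}

#' p-distance matrix from an aligned FASTA
#'
#' Proportion of differing sites with pairwise deletion of gaps/ambiguities.
#'
#' @param alignment path to an aligned FASTA, a `DNAbin` alignment, or a
#'   named character vector of equal-length sequences.
#' @return symmetric distance matrix (class `dist` converted to matrix).
#' @export
p_distance <- function(alignment) {
  aln <- .as_dnabin(alignment)
  d <- ape::dist.dna(aln, model = "raw", pairwise.deletion = TRUE)
  as.matrix(d)
}

.as_dnabin <- function(alignment) {
  if (inherits(alignment, "DNAbin")) {
    aln <- alignment
  } else if (is.character(alignment) && length(alignment) == 1 &&
             file.exists(alignment)) {
    aln <- ape::read.FASTA(alignment)
    aln <- as.matrix(aln)
  } else if (is.character(alignment)) {
    if (length(unique(nchar(alignment))) != 1) {
      stop("ragged alignment: sequences differ in length")
    }
    aln <- ape::as.DNAbin(t(sapply(alignment,
                                   function(s) strsplit(s, "")[[1]])))
  } else {
    stop("unsupported alignment input")
  }
  if (is.list(aln)) {
    if (length(unique(lengths(aln))) != 1) {
      stop("ragged alignment: sequences differ in length")
    }
    aln <- as.matrix(aln)
  }
  aln
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining; negative branch lengths are clamped to 0.
#'
#' @param d symmetric distance matrix (zero diagonal), >= 3 taxa.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(diag(d) == 0))
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree on
#' p-distances for each replicate, and reports for each internal edge of
#' the original tree the fraction of replicates containing the same
#' bipartition. The seed fixes the resampling, and taxa are sorted by label
#' first so support is invariant to input order.
#'
#' @param alignment as in [p_distance()].
#' @param n number of bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `tree` (the NJ tree on the full alignment) and
#'   `support` (fraction per internal node, as `ape::boot.phylo`).
#' @export
nj_bootstrap <- function(alignment, n = 1000, seed = 1L) {
  aln <- .as_dnabin(alignment)
  aln <- aln[order(rownames(aln)), , drop = FALSE]
  build <- function(x) nj_tree(ape::dist.dna(x, model = "raw",
                                             pairwise.deletion = TRUE))
  tree <- build(aln)
  set.seed(seed)
  bp <- ape::boot.phylo(tree, aln, build, B = n, quiet = TRUE)
  list(tree = tree, support = bp / n)
}

#' Concordance between a dendrogram and a reference phylogeny
#'
#' The adjusted Rand index compares the `k`-cut cluster assignment of the
#' dendrogram with reference group labels (k = 1 gives ARI 0 by
#' convention). When a reference tree is supplied, the Robinson-Foulds
#' distance between the unrooted dendrogram topology and the reference is
#' also reported.
#'
#' @param hc `hclust` object over the strains.
#' @param ref_labels named vector of reference group labels (names = strain
#'   labels, must match the dendrogram leaves).
#' @param k number of clusters to cut.
#' @param ref_tree optional reference `phylo` tree with the same leaf set.
#' @return list with `ari`, `clusters` and (if `ref_tree` given) `rf`.
#' @export
concordance <- function(hc, ref_labels, k, ref_tree = NULL) {
  leaves <- hc$labels
  if (!setequal(leaves, names(ref_labels))) {
    stop("leaf set mismatch between dendrogram and reference labels")
  }
  cl <- stats::cutree(hc, k = k)
  ari <- if (k <= 1) 0 else
    mclust::adjustedRandIndex(cl[leaves], ref_labels[leaves])
  out <- list(ari = ari, clusters = cl)
  if (!is.null(ref_tree)) {
    dtree <- ape::as.phylo(hc)
    if (!setequal(dtree$tip.label, ref_tree$tip.label)) {
      stop("leaf set mismatch between dendrogram and reference tree")
    }
    out$rf <- phangorn::RF.dist(ape::unroot(dtree), ape::unroot(ref_tree))
  }
  out
}
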