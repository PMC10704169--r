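# Independent element-mass table (NIST/CODATA values, entered separately
# from the package's table) for brute-force mass summation oracles.
oracle_masses <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, P = 30.97376163, S = 31.97207100,
                   Na = 22.9897692809)

oracle_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  total <- 0
  for (tok in tokens) {
    sym <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (n == "") 1 else as.numeric(n)
    total <- total + n * oracle_masses[[sym]]
  }
  total
}

make_spec <- function(mz, intensity, precursor_mz, feature_id = "X") {
  list(feature_id = feature_id, precursor_mz = precursor_mz,
       peaks = data.frame(mz = mz, intensity = intensity))
}

# Exhaustive modified-cosine oracle: recursion over peaks of A, assigning
# each to any unused compatible peak of B or to nothing. Independent of the
# package's branch-and-bound assignment.
oracle_modified_cosine <- function(a, b, tol = 0.05) {
  shift <- a$precursor_mz - b$precursor_mz
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  ia <- sqrt(a$peaks$intensity); ib <- sqrt(b$peaks$intensity)
  best <- 0; best_n <- 0L
  rec <- function(i, used, acc, n) {
    if (acc > best || (acc == best && n > best_n)) {
      best <<- acc; best_n <<- n
    }
    if (i > na) return()
    rec(i + 1L, used, acc, n)
    for (j in seq_len(nb)) {
      if (used[j]) next
      d1 <- abs(a$peaks$mz[i] - b$peaks$mz[j])
      d2 <- abs(a$peaks$mz[i] - b$peaks$mz[j] - shift)
      if (d1 <= tol || d2 <= tol) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + ia[i] * ib[j], n + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0, 0L)
  list(score = min(best / (sqrt(sum(ia^2)) * sqrt(sum(ib^2))), 1),
       n_matched = best_n)
}

# Direct adjusted-Rand-index computation from the contingency table.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  exp_ <- a * b / choose(n, 2)
  (sum_ij - exp_) / ((a + b) / 2 - exp_)
}

# Least-squares fit of a 4-taxon unrooted topology to a distance matrix.
# Topologies encoded by the sister pair of taxon 1.
oracle_nj4 <- function(d) {
  taxa <- rownames(d)
  fits <- lapply(2:4, function(s) {
    pair1 <- c(1, s); pair2 <- setdiff(1:4, pair1)
    # branch lengths: e1..e4 terminal, e5 internal
    A <- matrix(0, 6, 5); y <- numeric(6); r <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      r <- r + 1
      A[r, i] <- 1; A[r, j] <- 1
      same <- (i %in% pair1 && j %in% pair1) ||
        (i %in% pair2 && j %in% pair2)
      if (!same) A[r, 5] <- 1
      y[r] <- d[i, j]
    }
    est <- qr.solve(A, y)
    list(sister = taxa[pair1], resid = sum((A %*% est - y)^2), est = est)
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "resid"))]]
}
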