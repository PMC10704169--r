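#' Molecular-networking parameters
#'
#' Defaults follow standard feature-based molecular networking practice:
#' 0.05 Da tolerances, top-6 peaks per 50 Da window with a 17 Da precursor
#' exclusion, edges requiring cosine > 0.7 and at least 6 matched peaks,
#' nodes below m/z 500 and components below 4 nodes removed.
#'
#' @param frag_mz_tol,precursor_mz_tol fragment / precursor tolerances (Da).
#' @param topk peaks kept per window.
#' @param window window width (Da); applied as +/- `window`/2 around each
#'   peak.
#' @param precursor_exclusion fragments within this many Da of the precursor
#'   are discarded.
#' @param min_cosine minimum modified-cosine score (strict inequality).
#' @param min_matched_peaks minimum shared peaks per edge.
#' @param min_component_size components smaller than this are removed
#'   (exactly this size is kept).
#' @param min_node_mz nodes below this precursor m/z are removed (exactly
#'   this m/z is kept).
#' @return a `network_config` list.
#' @export
network_config <- function(frag_mz_tol = 0.05, precursor_mz_tol = 0.05,
                           topk = 6L, window = 50, precursor_exclusion = 17,
                           min_cosine = 0.7, min_matched_peaks = 6L,
                           min_component_size = 4L, min_node_mz = 500) {
  stopifnot(frag_mz_tol > 0, topk > 0, window > 0,
            precursor_exclusion > 0, min_cosine > 0, min_cosine <= 1,
            min_matched_peaks > 0, min_component_size > 0, min_node_mz > 0)
  structure(list(frag_mz_tol = frag_mz_tol,
                 precursor_mz_tol = precursor_mz_tol, topk = topk,
                 window = window, precursor_exclusion = precursor_exclusion,
                 min_cosine = min_cosine,
                 min_matched_peaks = min_matched_peaks,
                 min_component_size = min_component_size,
                 min_node_mz = min_node_mz),
            class = "network_config")
}

#' Filter an MS2 spectrum for networking
#'
#' Removes fragments within `precursor_exclusion` Da of the precursor, then
#' keeps a peak only if it ranks among the `topk` most intense peaks within
#' +/- `window`/2 Da of itself (a sliding window centred on each peak).
#' The operation is idempotent.
#'
#' @param peaks peak data frame (`mz`, `intensity`).
#' @param precursor_mz precursor m/z.
#' @param config a [network_config()].
#' @return filtered peak data frame (possibly empty).
#' @export
filter_spectrum <- function(peaks, precursor_mz,
                            config = network_config()) {
  stopifnot(nrow(peaks) >= 1)
  peaks <- peaks[abs(peaks$mz - precursor_mz) >=
                   config$precursor_exclusion, , drop = FALSE]
  if (nrow(peaks) == 0) return(peaks)
  half <- config$window / 2
  # deterministic intensity ranking: ties broken by lower m/z
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    win <- which(abs(peaks$mz - peaks$mz[i]) <= half)
    ord <- win[order(-peaks$intensity[win], peaks$mz[win])]
    i %in% ord[seq_len(min(config$topk, length(ord)))]
  }, logical(1))
  out <- peaks[keep, , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact maximum-weight one-to-one assignment over candidate peak pairs
# (branch and bound; candidate lists are small for filtered spectra).
.best_assignment <- function(pa, pb, w) {
  n <- length(w)
  ord <- order(-w)
  pa <- pa[ord]; pb <- pb[ord]; w <- w[ord]
  suffix <- rev(cumsum(rev(w)))
  best_w <- 0; best_n <- 0L
  usedA <- logical(max(pa)); usedB <- logical(max(pb))
  rec <- function(idx, acc, nm) {
    if (acc > best_w || (acc == best_w && nm > best_n)) {
      best_w <<- acc; best_n <<- nm
    }
    if (idx > n) return()
    if (acc + suffix[idx] < best_w) return()
    i <- pa[idx]; j <- pb[idx]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <<- TRUE; usedB[j] <<- TRUE
      rec(idx + 1L, acc + w[idx], nm + 1L)
      usedA[i] <<- FALSE; usedB[j] <<- FALSE
    }
    rec(idx + 1L, acc, nm)
  }
  rec(1L, 0, 0L)
  list(weight = best_w, n = best_n)
}

#' Modified cosine similarity between two MS2 spectra
#'
#' Peaks match directly (|dm/z| <= `frag_tol`) or shifted by the signed
#' precursor mass difference (spectrum A minus spectrum B); direct and
#' shifted candidates compete in one optimal one-to-one assignment
#' maximising the sum of products of square-root intensities. The score is
#' normalised by the two spectral norms, so it is symmetric and lies in
#' [0, 1].
#'
#' @param a,b spectra: lists with `precursor_mz` and `peaks`.
#' @param frag_tol fragment tolerance (Da).
#' @return list with `score` and `n_matched`.
#' @export
modified_cosine <- function(a, b, frag_tol = 0.05) {
  pa <- a$peaks; pb <- b$peaks
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    return(list(score = 0, n_matched = 0L))
  }
  stopifnot(all(pa$intensity > 0), all(pb$intensity > 0))
  shift <- a$precursor_mz - b$precursor_mz
  ia <- sqrt(pa$intensity); ib <- sqrt(pb$intensity)
  ii <- jj <- integer(0); ww <- numeric(0)
  for (i in seq_len(nrow(pa))) {
    d_direct <- abs(pa$mz[i] - pb$mz)
    d_shift <- abs(pa$mz[i] - pb$mz - shift)
    for (j in which(d_direct <= frag_tol | d_shift <= frag_tol)) {
      ii <- c(ii, i); jj <- c(jj, j); ww <- c(ww, ia[i] * ib[j])
    }
  }
  if (length(ww) == 0) return(list(score = 0, n_matched = 0L))
  asg <- .best_assignment(ii, jj, ww)
  score <- asg$weight / (sqrt(sum(ia^2)) * sqrt(sum(ib^2)))
  list(score = min(score, 1), n_matched = asg$n)
}

#' Build a molecular network from MS2 spectra
#'
#' Spectra are filtered with [filter_spectrum()], every pair is scored with
#' [modified_cosine()], and an edge is created when the score exceeds
#' `min_cosine` and at least `min_matched_peaks` peaks are shared. Nodes are
#' ordered by feature id so the result is independent of input order.
#'
#' @param spectra list of spectra (`feature_id`, `precursor_mz`, `peaks`).
#' @param config a [network_config()].
#' @return a `mol_network`: list with `nodes` (feature_id, mz) and `edges`
#'   (from, to, cosine, matched_peaks, delta_mz).
#' @export
build_network <- function(spectra, config = network_config()) {
  stopifnot(length(spectra) >= 2)
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  spectra <- spectra[order(ids)]
  ids <- sort(ids)
  filt <- lapply(spectra, function(s) {
    s$peaks <- filter_spectrum(s$peaks, s$precursor_mz, config)
    s
  })
  nodes <- data.frame(feature_id = ids,
                      mz = vapply(filt, function(s) s$precursor_mz,
                                  numeric(1)))
  from <- to <- character(0)
  cosine <- dmz <- numeric(0)
  nmatch <- integer(0)
  n <- length(filt)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      mc <- modified_cosine(filt[[i]], filt[[j]], config$frag_mz_tol)
      if (mc$score > config$min_cosine &&
          mc$n_matched >= config$min_matched_peaks) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        cosine <- c(cosine, mc$score)
        nmatch <- c(nmatch, mc$n_matched)
        dmz <- c(dmz, filt[[i]]$precursor_mz - filt[[j]]$precursor_mz)
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, cosine = cosine,
                                    matched_peaks = nmatch,
                                    delta_mz = dmz)),
            class = "mol_network")
}

.net_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Connected components of a molecular network
#'
#' @param net a `mol_network`.
#' @return named integer vector: component id per feature id (singletons
#'   included).
#' @export
network_components <- function(net) {
  if (nrow(net$nodes) == 0) return(stats::setNames(integer(0), character(0)))
  g <- .net_graph(net)
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), names(comp))
}

#' Filter a molecular network
#'
#' Node filters run first (blank-involved nodes, nodes below
#' `min_node_mz`), then components smaller than `min_component_size` are
#' removed entirely. Singleton nodes (degree 0) count as components of
#' size 1 and are therefore dropped under the default configuration.
#'
#' @param net a `mol_network`.
#' @param blank_ids feature ids observed in blank samples.
#' @param config a [network_config()].
#' @return filtered `mol_network`.
#' @export
filter_network <- function(net, blank_ids = character(0),
                           config = network_config()) {
  keep <- !(net$nodes$feature_id %in% blank_ids) &
    net$nodes$mz >= config$min_node_mz
  nodes <- net$nodes[keep, , drop = FALSE]
  edges <- net$edges[net$edges$from %in% nodes$feature_id &
                       net$edges$to %in% nodes$feature_id, , drop = FALSE]
  net2 <- structure(list(nodes = nodes, edges = edges),
                    class = "mol_network")
  comp <- network_components(net2)
  sizes <- table(comp)
  big <- names(sizes)[sizes >= config$min_component_size]
  keep_ids <- names(comp)[comp %in% as.integer(big)]
  nodes <- nodes[nodes$feature_id %in% keep_ids, , drop = FALSE]
  edges <- edges[edges$from %in% keep_ids & edges$to %in% keep_ids, ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "mol_network")
}

#' Categorise network components
#'
#' A component containing at least one annotated node is labelled by the
#' majority lipid class among its annotated nodes (alphabetical tie-break).
#' An all-unknown component whose nodes' strain occurrences are contributed
#' more than 50% by one taxon is labelled "<taxon>-dominant unknown";
#' otherwise "unknown".
#'
#' @param net filtered `mol_network`.
#' @param annotations annotation table (accepted rows used).
#' @param occurrence data frame `feature_id`, `strain` (one row per
#'   feature-strain occurrence).
#' @param strain_taxa data frame `strain`, `taxon` (e.g. genus or order).
#' @return data frame `component`, `n_nodes`, `category`.
#' @export
categorize_components <- function(net, annotations, occurrence,
                                  strain_taxa) {
  comp <- network_components(net)
  acc <- annotations[annotations$accepted, , drop = FALSE]
  cls <- stats::setNames(acc$lipid_class, acc$feature_id)
  occurrence$taxon <- strain_taxa$taxon[match(occurrence$strain,
                                              strain_taxa$strain)]
  out <- list()
  for (k in sort(unique(comp))) {
    ids <- names(comp)[comp == k]
    ann <- cls[intersect(ids, names(cls))]
    if (length(ann) > 0) {
      tab <- sort(table(ann), decreasing = TRUE)
      label <- names(tab)[1]
    } else {
      occ <- occurrence[occurrence$feature_id %in% ids, , drop = FALSE]
      tab <- table(occ$taxon)
      if (length(tab) > 0 && max(tab) > 0.5 * sum(tab)) {
        label <- paste0(names(tab)[which.max(tab)], "-dominant unknown")
      } else {
        label <- "unknown"
      }
    }
    out[[length(out) + 1L]] <- data.frame(component = k,
                                          n_nodes = length(ids),
                                          category = label)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Network composition summary
#'
#' Partitions the nodes of a filtered network into identified features,
#' unknown analogs (unknown nodes sharing a component with at least one
#' identified node) and new structures (nodes of all-unknown components),
#' so that `n_identified + n_analogs + n_new = n_nodes`.
#'
#' @param net filtered `mol_network`.
#' @param identified_ids feature ids annotated against the library.
#' @return list of counts `n_nodes`, `n_identified`, `n_unknown`,
#'   `n_analogs`, `n_new`.
#' @export
network_summary <- function(net, identified_ids) {
  if (nrow(net$nodes) == 0) {
    return(list(n_nodes = 0L, n_identified = 0L, n_unknown = 0L,
                n_analogs = 0L, n_new = 0L))
  }
  comp <- network_components(net)
  ids <- net$nodes$feature_id
  known <- ids %in% identified_ids
  comp_has_known <- tapply(known, comp[ids], any)
  analog <- !known & comp_has_known[as.character(comp[ids])]
  list(n_nodes = length(ids),
       n_identified = sum(known),
       n_unknown = sum(!known),
       n_analogs = sum(analog),
       n_new = sum(!known & !analog))
}

#' Export a molecular network as GraphML
#'
#' Node attributes: precursor m/z, annotation, component category,
#' per-strain occurrence; edge attributes: cosine, matched peaks, precursor
#' mass difference.
#'
#' @param net a `mol_network`.
#' @param path output file.
#' @param annotations optional annotation table.
#' @param categories optional output of [categorize_components()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, annotations = NULL,
                          categories = NULL) {
  nodes <- net$nodes
  if (!is.null(annotations)) {
    acc <- annotations[annotations$accepted, , drop = FALSE]
    nodes$annotation <- acc$species[match(nodes$feature_id,
                                          acc$feature_id)]
    nodes$annotation[is.na(nodes$annotation)] <- ""
  }
  if (!is.null(categories)) {
    comp <- network_components(net)
    nodes$category <- categories$category[
      match(comp[nodes$feature_id], categories$component)]
  }
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
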