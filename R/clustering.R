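#' Principal component embedding of spots
#'
#' Genes are centered and unit-scaled across the in-tissue spots before the
#' decomposition (constant genes are dropped). Components are ordered by
#' decreasing explained variance with a fixed sign convention: the
#' largest-magnitude gene loading of each component is positive.
#'
#' @param norm a `normalized_matrix`, or a plain spots x genes matrix.
#' @param n_components number of components to keep (default 20).
#' @param scale. unit-scale genes before the decomposition.
#' @return a `pc_embedding`: list with `scores` (spots x k), `loadings`,
#'   `sdev`, and `spot_ids`.
#' @export
run_pca <- function(norm, n_components = 20, scale. = TRUE) {
  if (inherits(norm, "normalized_matrix")) {
    x <- as.matrix(norm$values[norm$in_tissue, , drop = FALSE])
  } else x <- as.matrix(norm)
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  x <- scale(x, center = TRUE, scale = scale.)
  k <- min(n_components, nrow(x) - 1, ncol(x))
  if (k < n_components)
    warning(sprintf("rank limits components to %d (requested %d)", k, n_components))
  sv <- svd(x, nu = k, nv = k)
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = sv$v,
                 sdev = sv$d[seq_len(k)] / sqrt(nrow(x) - 1),
                 spot_ids = rownames(x)),
            class = "pc_embedding")
}

#' Joint embedding of several sections
#'
#' Each section's genes are centered and unit-scaled within the section
#' (removing per-section global offsets), the rows are concatenated, and a
#' joint PCA is run. The originating section of every spot is retained so
#' residual section separation stays reportable.
#'
#' @param norms list of `normalized_matrix` objects over an identical gene
#'   universe.
#' @param n_components number of joint components.
#' @return a `pc_embedding` with an extra `section` factor per spot.
#' @export
integrate_sections <- function(norms, n_components = 20) {
  universes <- lapply(norms, function(n) colnames(n$values))
  ref <- universes[[1]]
  for (u in universes[-1]) {
    if (!setequal(u, ref))
      stop("gene universes differ; symmetric difference: ",
           paste(utils::head(c(setdiff(u, ref), setdiff(ref, u)), 10),
                 collapse = ", "), call. = FALSE)
  }
  blocks <- lapply(norms, function(nrm) {
    x <- as.matrix(nrm$values[nrm$in_tissue, ref, drop = FALSE])
    sds <- apply(x, 2, stats::sd)
    x <- scale(x, center = TRUE, scale = FALSE)
    x[, sds > 0] <- sweep(x[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
    rownames(x) <- paste(nrm$section_id, rownames(x), sep = ":")
    x
  })
  joint <- do.call(rbind, blocks)
  emb <- run_pca(joint, n_components = n_components, scale. = FALSE)
  emb$section <- factor(rep(vapply(norms, function(n) n$section_id, ""),
                            vapply(blocks, nrow, 1L)))
  emb
}

#' Graph-based clustering of a PC embedding
#'
#' Builds a symmetric k-nearest-neighbor graph on Euclidean distances in PC
#' space and partitions it with Leiden community detection (modularity
#' objective) at the given resolution. Deterministic given `seed`.
#'
#' @param embedding a `pc_embedding`.
#' @param k_neighbors neighbors per spot.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed.
#' @return a `cluster_assignment`: list with `cluster` (integer labels from
#'   0, named by spot), `resolution`, `modularity`, `section` (if present).
#' @export
cluster_graph <- function(embedding, k_neighbors = 15, resolution = 1.0,
                          seed = 1) {
  x <- embedding$scores
  n <- nrow(x)
  stopifnot(k_neighbors < n)
  # canonical vertex order (by spot id) so the result is exactly invariant
  # to the order spots are supplied in
  ord <- if (!is.null(rownames(x))) order(rownames(x)) else seq_len(n)
  x <- x[ord, , drop = FALSE]
  nn <- knn_indices(x, k_neighbors)
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- withr_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5)
  })
  labels <- igraph::membership(memb)
  # relabel contiguously from 0, largest cluster first
  sz <- sort(table(labels), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sz) - 1L, names(sz))
  cl <- unname(remap[as.character(labels)])
  mod <- igraph::modularity(g, labels)
  cl <- cl[order(ord)]                         # back to the input order
  structure(list(cluster = stats::setNames(cl, rownames(embedding$scores)),
                 resolution = resolution, modularity = mod,
                 section = embedding$section),
            class = "cluster_assignment")
}

# brute-force kNN in embedding space; adequate at the spot counts used here
knn_indices <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' Deterministic 2D embedding of spots for visualization
#'
#' Classical multidimensional scaling (principal coordinates) of the
#' Euclidean distances in PC space. Chosen over a stochastic
#' neighbor-embedding because it is exactly reproducible and preserves the
#' blob-level separations the downstream checks rely on.
#'
#' @param embedding a `pc_embedding`.
#' @param seed accepted for interface compatibility; the layout is
#'   deterministic and ignores it.
#' @return spots x 2 coordinate matrix.
#' @export
embed_2d <- function(embedding, seed = 1) {
  xy <- stats::cmdscale(stats::dist(embedding$scores), k = 2)
  # fix reflections: largest-|value| coordinate positive per axis
  for (j in 1:2) {
    i <- which.max(abs(xy[, j]))
    if (xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  colnames(xy) <- c("dim1", "dim2")
  rownames(xy) <- rownames(embedding$scores)
  xy
}

#' One-vs-rest cluster marker detection
#'
#' For each cluster and gene, a two-sided Wilcoxon rank-sum test of the
#' normalized values in the cluster against all other spots, with
#' Benjamini-Hochberg correction across every (cluster, gene) test.
#' log-FC is the difference of means on the log scale.
#'
#' @param norm a `normalized_matrix` (or plain matrix of in-tissue spots).
#' @param clusters a `cluster_assignment` or an integer vector aligned with
#'   the in-tissue spots.
#' @return a `marker_table` data.frame: cluster, gene, logfc, stat
#'   (rank-sum z), p, q.
#' @export
find_markers <- function(norm, clusters) {
  x <- if (inherits(norm, "normalized_matrix"))
    as.matrix(norm$values[norm$in_tissue, , drop = FALSE]) else as.matrix(norm)
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster else clusters
  stopifnot(length(cl) == nrow(x))
  if (is.null(colnames(x))) colnames(x) <- sprintf("gene%d", seq_len(ncol(x)))
  ids <- sort(unique(cl))
  if (length(ids) < 2) stop("need at least 2 clusters", call. = FALSE)
  n <- nrow(x)
  # rank once per gene; per-cluster rank-sums give every one-vs-rest z
  rk <- apply(x, 2, rank)
  tie_term <- apply(x, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    inC <- cl == ids[i]
    n1 <- sum(inC); n2 <- n - n1
    if (n1 < 2) warning("cluster ", ids[i], " has fewer than 2 spots")
    rsum <- colSums(rk[inC, , drop = FALSE])
    u <- rsum - n1 * (n1 + 1) / 2
    mu_u <- n1 * n2 / 2
    sd_u <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    z <- ifelse(sd_u > 0, (u - mu_u) / sd_u, 0)
    p <- 2 * stats::pnorm(-abs(z))
    lfc <- colMeans(x[inC, , drop = FALSE]) -
      colMeans(x[!inC, , drop = FALSE])
    res[[i]] <- data.frame(cluster = ids[i], gene = colnames(x),
                           logfc = lfc, stat = z, p = p,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("marker_table", "data.frame")
  out
}
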