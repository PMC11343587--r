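#' Minimum-spanning-tree trajectory with rooted pseudotime
#'
#' Runs PCA on the top `hvg_n` variance genes restricted to the trajectory
#' clusters, computes cluster centroids in PC space, joins them by a
#' minimum spanning tree (Euclidean edge weights; ties broken by node-id
#' order), projects every spot onto its nearest point of the tree, and
#' defines pseudotime as the geodesic tree distance from the root terminus,
#' min-max scaled to `[0, 1]`.
#'
#' @param norm a `normalized_matrix`.
#' @param clusters per-in-tissue-spot cluster labels (vector or
#'   `cluster_assignment`).
#' @param root_cluster label of the root (progenitor) cluster.
#' @param hvg_n number of high-variance genes for the PCA.
#' @param n_pcs PCs used for centroid geometry.
#' @param use_clusters optional subset of cluster labels forming the
#'   trajectory; default all.
#' @return a `trajectory`: list with `pseudotime` (named, `[0,1]`),
#'   `edge`/`offset` per spot, `centroids`, `mst_edges`, `root`.
#' @export
infer_trajectory <- function(norm, clusters, root_cluster, hvg_n = 2000,
                             n_pcs = 10, use_clusters = NULL) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster else clusters
  x_ids <- rownames(norm$values)[norm$in_tissue]
  stopifnot(length(cl) == length(x_ids))
  if (is.null(use_clusters)) use_clusters <- sort(unique(cl))
  if (!root_cluster %in% use_clusters)
    stop("root_cluster '", root_cluster, "' not present", call. = FALSE)
  if (length(use_clusters) < 2) stop("need at least 2 clusters", call. = FALSE)
  keep <- cl %in% use_clusters
  hvg <- select_hvg(norm, min(hvg_n, ncol(norm$values)))
  x <- as.matrix(norm$values[norm$in_tissue, hvg, drop = FALSE])[keep, , drop = FALSE]
  cl <- cl[keep]
  emb <- run_pca(x, n_components = min(n_pcs, ncol(x), nrow(x) - 1))
  sc <- emb$scores
  nodes <- sort(unique(cl))
  cent <- do.call(rbind, lapply(nodes, function(g)
    colMeans(sc[cl == g, , drop = FALSE])))
  rownames(cent) <- as.character(nodes)
  # MST over centroids; igraph breaks weight ties by edge insertion order,
  # which follows node-id order here
  dmat <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst)
  ew <- igraph::E(mst)$weight
  # project spots onto tree edges
  n <- nrow(sc)
  best <- list(dist = rep(Inf, n), edge = integer(n), t = numeric(n))
  for (e in seq_len(nrow(el))) {
    a <- cent[el[e, 1], ]; b <- cent[el[e, 2], ]
    ab <- b - a; len2 <- sum(ab^2)
    t <- pmin(1, pmax(0, (sc %*% ab - sum(a * ab))[, 1] / len2))
    proj <- matrix(a, n, length(a), byrow = TRUE) + outer(t, ab)
    d <- sqrt(rowSums((sc - proj)^2))
    upd <- d < best$dist
    best$dist[upd] <- d[upd]; best$edge[upd] <- e; best$t[upd] <- t[upd]
  }
  # geodesic distance from the root node to each projection
  node_dist <- igraph::distances(mst, v = as.character(root_cluster))[1, ]
  pt <- numeric(n)
  for (i in seq_len(n)) {
    e <- best$edge[i]
    da <- node_dist[el[e, 1]] + best$t[i] * ew[e]
    db <- node_dist[el[e, 2]] + (1 - best$t[i]) * ew[e]
    pt[i] <- min(da, db)
  }
  rng <- range(pt)
  pt <- if (diff(rng) == 0) rep(0, n) else (pt - rng[1]) / diff(rng)
  names(pt) <- x_ids[keep]
  structure(list(pseudotime = pt,
                 edge = stats::setNames(best$edge, x_ids[keep]),
                 offset = stats::setNames(best$t, x_ids[keep]),
                 centroids = cent,
                 mst_edges = data.frame(from = el[, 1], to = el[, 2],
                                        weight = ew),
                 root = root_cluster, cluster = stats::setNames(cl, x_ids[keep])),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d spots on %d-node MST, root '%s'\n",
              length(x$pseudotime), nrow(x$centroids), x$root))
  invisible(x)
}

# one EM run for a k-component 1D Gaussian mixture
gmm_em_1d <- function(x, k, mu0, max_iter = 200, tol = 1e-8, var_floor = NULL) {
  n <- length(x)
  if (is.null(var_floor)) var_floor <- max(1e-6 * stats::var(x), 1e-12)
  mu <- mu0
  sigma2 <- rep(max(stats::var(x) / k, var_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(sigma2[j])), numeric(n))
    dens <- matrix(dens, n, k)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma2 <- pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, var_floor)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma2 = sigma2, w = w, loglik = ll, resp = r)
}

#' Detect bimodality of a value distribution by Gaussian-mixture BIC
#'
#' Fits 1- and 2-component Gaussian mixtures by EM (10 random restarts,
#' seeded) and selects the model with the lower BIC. For a 2-component
#' selection the low-mean component is labeled `"pseudotime-low"` and the
#' high-mean one `"pseudotime-high"`. Degenerate variances are floored and
#' noted.
#'
#' @param values numeric vector (>= 20 values).
#' @param seed RNG seed for the EM restarts.
#' @param n_restarts EM restarts for the 2-component fit.
#' @return a `mixture_fit`: list with `n_components`, `mu`, `sigma2`,
#'   `weights`, `assignment` (factor per value), `bic` (both models),
#'   `delta_bic`.
#' @export
detect_bimodality <- function(values, seed = 1, n_restarts = 10) {
  x <- as.numeric(values)
  if (length(x) < 20) stop("need at least 20 values", call. = FALSE)
  n <- length(x)
  if (stats::sd(x) == 0) {
    assignment <- factor(rep("pseudotime-low", n),
                         levels = c("pseudotime-low", "pseudotime-high"))
    return(structure(list(n_components = 1L, mu = mean(x), sigma2 = 0,
                          weights = 1, assignment = assignment,
                          bic = c(k1 = -Inf, k2 = Inf), delta_bic = Inf,
                          floored = TRUE),
                     class = "mixture_fit"))
  }
  # k = 1 closed form
  mu1 <- mean(x); v1 <- stats::var(x) * (n - 1) / n
  ll1 <- sum(stats::dnorm(x, mu1, sqrt(v1), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  fit2 <- withr_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      mu0 <- sort(sample(x, 2))
      f <- gmm_em_1d(x, 2, mu0)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    best
  })
  bic2 <- -2 * fit2$loglik + 5 * log(n)
  if (bic2 < bic1) {
    ord <- order(fit2$mu)
    lab <- c("pseudotime-low", "pseudotime-high")[order(ord)]
    comp <- max.col(fit2$resp)
    assignment <- factor(lab[comp], levels = c("pseudotime-low", "pseudotime-high"))
    structure(list(n_components = 2L, mu = fit2$mu[ord],
                   sigma2 = fit2$sigma2[ord], weights = fit2$w[ord],
                   assignment = assignment,
                   bic = c(k1 = bic1, k2 = bic2), delta_bic = bic1 - bic2),
              class = "mixture_fit")
  } else {
    assignment <- factor(rep("pseudotime-low", n),
                         levels = c("pseudotime-low", "pseudotime-high"))
    structure(list(n_components = 1L, mu = mu1, sigma2 = v1, weights = 1,
                   assignment = assignment,
                   bic = c(k1 = bic1, k2 = bic2), delta_bic = bic1 - bic2),
              class = "mixture_fit")
  }
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %d component(s), delta BIC (k1 - k2) = %.2f\n",
              x$n_components, x$delta_bic))
  invisible(x)
}

#' Compare the SpatialTime of two pseudotime components
#'
#' Two-sided Wilcoxon rank-sum test of SpatialTime `s` between the
#' `pseudotime-low` and `pseudotime-high` components of a 2-component
#' mixture fit, reporting which component sits at greater median `s`
#' (farther from the fracture plane).
#'
#' @param fit a 2-component `mixture_fit` whose `assignment` is named by
#'   barcode (or aligned with `barcodes`).
#' @param st a `spatialtime_values`.
#' @param barcodes barcodes aligned with `fit$assignment` when the
#'   assignment itself is unnamed.
#' @return list with `stat` (W), `p`, `direction`, and the two medians.
#' @export
compare_groups_spatialtime <- function(fit, st, barcodes = NULL) {
  if (fit$n_components != 2)
    stop("mixture fit has 1 component; bimodality split requires 2 ",
         "(rerun detect_bimodality or inspect delta_bic)", call. = FALSE)
  bc <- if (!is.null(barcodes)) barcodes else names(fit$assignment)
  if (is.null(bc)) stop("assignment is unnamed; supply barcodes", call. = FALSE)
  s <- st$s[match(bc, st$barcode)]
  ok <- !is.na(s)
  lo <- s[ok & fit$assignment == "pseudotime-low"]
  hi <- s[ok & fit$assignment == "pseudotime-high"]
  wt <- stats::wilcox.test(lo, hi, exact = FALSE)
  dir <- if (stats::median(lo) > stats::median(hi))
    "pseudotime-low higher s" else "pseudotime-high higher s"
  list(stat = unname(wt$statistic), p = wt$p.value, direction = dir,
       median_low = stats::median(lo), median_high = stats::median(hi))
}
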