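#' Define a fracture plane as a polyline
#'
#' @param points numeric matrix or data.frame with two columns (x, y) and at
#'   least two rows, ordered along the plane.
#' @return an object of class `fracture_plane`.
#' @export
fracture_plane <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2) stop("a fracture plane needs at least 2 points", call. = FALSE)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive plane points must be distinct", call. = FALSE)
  structure(list(points = pts), class = "fracture_plane")
}

#' Read a plane polyline from a CSV of x,y rows
#' @param path CSV file with columns x, y (header optional).
#' @return a [fracture_plane()].
#' @export
read_plane <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  fracture_plane(utils::read.csv(path, header = header))
}

# Euclidean distance from each point (rows of xy) to the nearest point on
# the polyline: per segment the point-to-segment distance, then the minimum.
polyline_distance <- function(xy, plane) {
  pts <- plane$points
  d <- rep(Inf, nrow(xy))
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- xy[, 1] - (a[1] + t * ab[1])
    dy <- xy[, 2] - (a[2] + t * ab[2])
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' Assign SpatialTime to spots
#'
#' SpatialTime is the per-spot distance from the fracture plane, min-max
#' normalized over the included spots so that the nearest included spot is
#' exactly 0 and the farthest exactly 1. Distance is Euclidean from the spot
#' center to the nearest point of the polyline (point-to-segment).
#'
#' @param section a `spatial_section`.
#' @param plane a [fracture_plane()].
#' @param include_clusters clusters (values of `metadata$cluster`) whose
#'   spots participate; `NULL` includes every in-tissue spot.
#' @return a `spatialtime_values` object: data.frame with `barcode`,
#'   raw distance `d`, normalized `s`, and logical `included`.
#' @export
assign_spatialtime <- function(section, plane, include_clusters = NULL) {
  idx <- in_tissue_idx(section)
  included <- rep(FALSE, length(section$spot_ids))
  included[idx] <- TRUE
  if (!is.null(include_clusters)) {
    if (is.null(section$metadata$cluster))
      stop("section has no cluster metadata; run clustering first", call. = FALSE)
    included <- included & section$metadata$cluster %in% include_clusters
  }
  if (!any(included)) stop("no included spots for SpatialTime", call. = FALSE)
  rng <- apply(section$coords, 2, range)
  if (any(plane$points[, 1] < rng[1, 1] | plane$points[, 1] > rng[2, 1] |
          plane$points[, 2] < rng[1, 2] | plane$points[, 2] > rng[2, 2]))
    warning("plane extends outside the spot bounding box")
  d <- polyline_distance(section$coords, plane)
  s <- rep(NA_real_, length(d))
  di <- d[included]
  s[included] <- if (diff(range(di)) == 0) 0 else (di - min(di)) / (max(di) - min(di))
  structure(data.frame(barcode = section$spot_ids, d = d, s = s,
                       included = included, stringsAsFactors = FALSE),
            class = c("spatialtime_values", "data.frame"))
}

#' Test genes for expression trends along SpatialTime
#'
#' Per gene, regresses normalized expression of the included spots on a
#' natural cubic spline basis of SpatialTime (`df` degrees of freedom) and
#' compares it against an intercept-only null with a Gaussian
#' likelihood-ratio test (`n * log(RSS0/RSS1)` on a chi-square with `df`
#' degrees of freedom). P values are BH-adjusted across genes, and the
#' fitted curve is evaluated on a fixed grid of `grid_n` SpatialTime points.
#'
#' @param norm a `normalized_matrix`.
#' @param st a `spatialtime_values` for the same section.
#' @param df spline degrees of freedom.
#' @param q_threshold BH q-value below which a gene is called dynamic.
#' @param grid_n number of grid points for the fitted curves.
#' @return a `gene_trends` object: list with `table` (gene, stat, p, q,
#'   significant), `curves` (genes x grid matrix of fitted values),
#'   `grid` (SpatialTime grid), `df`, `q_threshold`. Class labels are added
#'   by [classify_trends()].
#' @export
fit_gene_trends <- function(norm, st, df = 3, q_threshold = 0.05, grid_n = 100) {
  keep <- st$included
  s <- st$s[keep]
  n <- length(s)
  if (n < df + 2) stop("need at least df + 2 included spots", call. = FALSE)
  y <- as.matrix(norm$values[keep, , drop = FALSE])
  basis <- splines::ns(s, df = df)
  X <- cbind(1, basis)
  qrX <- qr(X)
  # RSS for full model, all genes at once via QR projection
  resid_full <- qr.resid(qrX, y)
  rss1 <- colSums(resid_full^2)
  mu <- colMeans(y)
  rss0 <- colSums(y^2) - n * mu^2
  stat <- ifelse(rss1 > 0, n * log(rss0 / rss1), Inf)
  # constant gene: rss0 == 0 -> no information, p = 1 by convention
  const <- rss0 <= .Machine$double.eps * n
  stat[const] <- 0
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  p[const] <- 1
  q <- stats::p.adjust(p, method = "BH")
  grid <- seq(0, 1, length.out = grid_n)
  Xg <- cbind(1, stats::predict(basis, grid))
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0
  curves <- t(Xg %*% beta)
  rownames(curves) <- colnames(y)
  structure(list(table = data.frame(gene = colnames(y), stat = stat, p = p,
                                    q = q, significant = q < q_threshold,
                                    class = NA_character_,
                                    stringsAsFactors = FALSE),
                 curves = curves, grid = grid, df = df,
                 q_threshold = q_threshold),
            class = "gene_trends")
}

#' @export
print.gene_trends <- function(x, ...) {
  cat(sprintf("gene_trends: %d genes tested, %d significant at q < %g\n",
              nrow(x$table), sum(x$table$significant), x$q_threshold))
  invisible(x)
}

# canonical class names for k = 4, ordered along SpatialTime
.canonical_classes <- c("early", "midearly", "midlate", "late")
.canonical_peaks <- c(0.05, 0.30, 0.60, 0.95)

#' Group dynamic genes into SpatialTime classes
#'
#' Z-standardizes each significant gene's fitted curve, clusters the curves
#' hierarchically (Ward linkage on Euclidean distance) and cuts at `k`
#' groups. Groups are named by the SpatialTime position of their mean
#' curve's maximum, ordered early to late; with the default `k = 4` the
#' names are `early`, `midearly`, `midlate`, `late`.
#'
#' @param trends a `gene_trends` from [fit_gene_trends()].
#' @param k number of classes.
#' @return the `gene_trends` with the `class` column filled for significant
#'   genes (`"none"` for non-significant genes) and a `class_curves`
#'   element of per-class mean standardized curves.
#' @export
classify_trends <- function(trends, k = 4) {
  sig <- which(trends$table$significant)
  trends$table$class <- "none"
  if (length(sig) == 0) {
    warning("no significant genes to classify")
    return(trends)
  }
  z <- trends$curves[sig, , drop = FALSE]
  sds <- apply(z, 1, stats::sd)
  sds[sds == 0] <- 1
  z <- (z - rowMeans(z)) / sds
  if (length(sig) < k) {
    warning("fewer significant genes than classes; labeling by nearest canonical peak")
    peak_pos <- trends$grid[apply(z, 1, which.max)]
    nearest <- vapply(peak_pos, function(p) which.min(abs(.canonical_peaks - p)), 1L)
    trends$table$class[sig] <- class_names(k)[pmin(nearest, k)]
    return(trends)
  }
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(z[grp == g, , drop = FALSE])))
  peak <- trends$grid[apply(centers, 1, which.max)]
  ord <- order(peak)                       # early -> late
  nm <- class_names(k)
  label_of <- character(k); label_of[ord] <- nm
  trends$table$class[sig] <- label_of[grp]
  rownames(centers) <- label_of
  trends$class_curves <- centers[nm, , drop = FALSE]
  trends
}

class_names <- function(k) {
  if (k == 4) .canonical_classes
  else if (k == 1) "early..late"
  else sprintf("class%d", seq_len(k))
}

#' Summarize a per-spot value over SpatialTime bins
#'
#' @param values numeric vector, one value per spot of the section.
#' @param st a `spatialtime_values`; only included spots are used.
#' @param n_bins number of equal-width bins on `[0, 1]`.
#' @return data.frame with one row per bin: `bin`, bin `center`, `n`,
#'   `mean`, `lo`/`hi` (t-based 95% CI; NA for empty bins), plus a
#'   `"peak"` attribute giving the center of the highest-mean bin.
#' @export
summarize_over_spatialtime <- function(values, st, n_bins = 20) {
  keep <- st$included
  s <- st$s[keep]; v <- values[keep]
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    n = 0L, mean = NA_real_, lo = NA_real_, hi = NA_real_)
  for (b in seq_len(n_bins)) {
    x <- v[bin == b]
    out$n[b] <- length(x)
    if (length(x)) {
      out$mean[b] <- mean(x)
      if (length(x) > 1) {
        half <- stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
        out$lo[b] <- out$mean[b] - half
        out$hi[b] <- out$mean[b] + half
      }
    }
  }
  attr(out, "peak") <- out$center[which.max(out$mean)]
  out
}

#' Compare a module's SpatialTime gradient between two genotypes
#'
#' Quantifies the contrast between two binned curves as
#' `delta_auc = area(A) - area(B)` (trapezoid rule over bin means) and a
#' peak shift, with a two-sided permutation p value obtained by permuting
#' the genotype labels of spots within each SpatialTime bin.
#'
#' @param values_a,values_b per-spot scores for genotypes A and B.
#' @param st_a,st_b matching `spatialtime_values`.
#' @param n_bins bins shared by the two curves.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `delta_auc`, `peak_shift`, `p`, and the two binned
#'   curves.
#' @export
compare_genotypes <- function(values_a, st_a, values_b, st_b,
                              n_bins = 20, n_perm = 1000, seed = 1) {
  sa <- st_a$s[st_a$included]; va <- values_a[st_a$included]
  sb <- st_b$s[st_b$included]; vb <- values_b[st_b$included]
  edges <- seq(0, 1, length.out = n_bins + 1)
  bins <- function(s) pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), n_bins)
  ba <- bins(sa); bb <- bins(sb)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  curve_of <- function(v, b) vapply(seq_len(n_bins), function(k) {
    x <- v[b == k]; if (length(x)) mean(x) else NA_real_
  }, 0)
  auc <- function(cv) {
    ok <- !is.na(cv)
    if (sum(ok) < 2) return(0)
    x <- centers[ok]; y <- cv[ok]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  ca <- curve_of(va, ba); cb <- curve_of(vb, bb)
  delta <- auc(ca) - auc(cb)
  peak_shift <- centers[which.max(ca)] - centers[which.max(cb)]
  v <- c(va, vb); b <- c(ba, bb)
  is_a <- c(rep(TRUE, length(va)), rep(FALSE, length(vb)))
  null <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- is_a
      for (k in unique(b)) {
        at <- which(b == k)
        perm[at] <- sample(perm[at])
      }
      auc(curve_of(v[perm], b[perm])) - auc(curve_of(v[!perm], b[!perm]))
    }, 0)
  })
  p <- (1 + sum(abs(null) >= abs(delta))) / (n_perm + 1)
  list(delta_auc = delta, peak_shift = peak_shift, p = p,
       curve_a = data.frame(center = centers, mean = ca),
       curve_b = data.frame(center = centers, mean = cb))
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
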