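#' Build a strictly one-to-one ortholog map
#'
#' Rows whose symbol appears more than once in either column (one-to-many
#' or many-to-one orthology) are dropped, with the count reported.
#'
#' @param table data.frame whose first two columns are symbols of species A
#'   and B.
#' @param strict error (rather than drop) on duplicated symbols.
#' @return an `ortholog_map` data.frame with columns `symbol_a`, `symbol_b`
#'   and an attribute `n_dropped`.
#' @export
ortholog_map <- function(table, strict = FALSE) {
  tab <- data.frame(symbol_a = as.character(table[[1]]),
                    symbol_b = as.character(table[[2]]),
                    stringsAsFactors = FALSE)
  dup <- duplicated(tab$symbol_a) | duplicated(tab$symbol_a, fromLast = TRUE) |
    duplicated(tab$symbol_b) | duplicated(tab$symbol_b, fromLast = TRUE)
  if (any(dup) && strict)
    stop("duplicated symbol(s) in ortholog table: ",
         paste(utils::head(unique(c(tab$symbol_a[dup], tab$symbol_b[dup])), 5),
               collapse = ", "), call. = FALSE)
  out <- tab[!dup, ]
  if (any(dup))
    message(sum(dup), " multi-mapping ortholog row(s) dropped")
  attr(out, "n_dropped") <- sum(dup)
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Align two marker tables on shared one-to-one orthologs
#'
#' Restricts both species' marker log-FC vectors to genes linked by the
#' ortholog map and present in both tables, returning per-cluster log-FC
#' matrices over a shared gene index.
#'
#' @param markers_a,markers_b `marker_table` data.frames from
#'   [find_markers()].
#' @param map an [ortholog_map()] (or two-column table passed through it).
#' @param min_shared minimum shared orthologs required.
#' @return list with `logfc_a`, `logfc_b` (clusters x shared genes, columns
#'   aligned so column j of both refers to the same ortholog pair) and
#'   `shared` (the ortholog rows used).
#' @export
harmonize_orthologs <- function(markers_a, markers_b, map, min_shared = 50) {
  if (!inherits(map, "ortholog_map")) map <- ortholog_map(map)
  genes_a <- unique(markers_a$gene); genes_b <- unique(markers_b$gene)
  shared <- map[map$symbol_a %in% genes_a & map$symbol_b %in% genes_b, ]
  if (nrow(shared) < min_shared)
    stop(sprintf("only %d shared orthologs (< %d); insufficient signal",
                 nrow(shared), min_shared), call. = FALSE)
  fc_mat <- function(mk, genes) {
    cl <- sort(unique(mk$cluster))
    m <- matrix(NA_real_, length(cl), length(genes),
                dimnames = list(as.character(cl), genes))
    m[cbind(match(mk$cluster, cl), match(mk$gene, genes))] <- mk$logfc
    m[, colSums(is.na(m)) == 0, drop = FALSE]
  }
  a <- fc_mat(markers_a, shared$symbol_a)
  b <- fc_mat(markers_b, shared$symbol_b)
  keep <- intersect(colnames(a), shared$symbol_a[shared$symbol_b %in% colnames(b)])
  shared <- shared[match(keep, shared$symbol_a), ]
  list(logfc_a = a[, shared$symbol_a, drop = FALSE],
       logfc_b = b[, shared$symbol_b, drop = FALSE],
       shared = shared)
}

#' Cross-species cluster correspondence
#'
#' Similarity between cluster `i` of species A and cluster `j` of species B
#' is the Spearman correlation of their marker log-FC vectors over the
#' shared ortholog index; significance per cell comes from permuting the
#' gene index. Best matches are reported in both directions.
#'
#' @param paired output of [harmonize_orthologs()].
#' @param n_perm gene-index permutations.
#' @param seed RNG seed.
#' @return a `correspondence`: list with `similarity` (A-clusters x
#'   B-clusters), `p` (same shape), `best_a_to_b`, `best_b_to_a`.
#' @export
cluster_correspondence <- function(paired, n_perm = 1000, seed = 1) {
  a <- paired$logfc_a; b <- paired$logfc_b
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 clusters on each side", call. = FALSE)
  # Spearman = Pearson on ranks; precompute rank matrices
  ra <- t(apply(a, 1, rank)); rb <- t(apply(b, 1, rank))
  sim <- stats::cor(t(ra), t(rb))
  pmat <- withr_seed(seed, {
    exceed <- matrix(0, nrow(a), nrow(b))
    for (k in seq_len(n_perm)) {
      perm <- sample(ncol(ra))
      nullsim <- stats::cor(t(ra[, perm, drop = FALSE]), t(rb))
      exceed <- exceed + (abs(nullsim) >= abs(sim))
    }
    (exceed + 1) / (n_perm + 1)
  })
  dimnames(sim) <- dimnames(pmat) <- list(rownames(a), rownames(b))
  structure(list(similarity = sim, p = pmat,
                 best_a_to_b = stats::setNames(
                   colnames(sim)[max.col(sim)], rownames(sim)),
                 best_b_to_a = stats::setNames(
                   rownames(sim)[max.col(t(sim))], colnames(sim))),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat("cluster correspondence (Spearman on marker log-FC):\n")
  print(round(x$similarity, 3))
  invisible(x)
}
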