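#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' symbols within a set are collapsed with a warning; empty sets are
#' rejected. An empty file yields an empty list.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene symbols.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("malformed GMT line %d: need name, description and >=1 gene", i),
           call. = FALSE)
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("malformed GMT line %d: empty gene set '%s'", i, parts[1]),
           call. = FALSE)
    ndup <- sum(duplicated(genes))
    if (ndup > 0)
      warning(sprintf("set '%s': %d duplicated symbol(s) collapsed", parts[1], ndup))
    sets[[parts[1]]] <- unique(genes)
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Expression-bin-matched module score
#'
#' Implements the standard bin-matched control scheme: all genes are ranked
#' by mean normalized expression over in-tissue spots and cut into `n_bins`
#' equal-size bins; for each set gene, `n_ctrl` control genes are sampled
#' without replacement from its bin (set genes excluded); the per-spot score
#' is the mean over set genes minus the mean over the pooled controls.
#'
#' @param norm a `normalized_matrix`.
#' @param gene_set character vector of gene symbols (or one element of
#'   [load_gene_sets()] output).
#' @param n_bins number of expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed RNG seed for control sampling.
#' @param name set name carried into the result.
#' @return a `module_score` object: list with `score` (named per in-tissue
#'   spot), `genes_used`, `genes_missing`, and `params`.
#' @export
score_module <- function(norm, gene_set, n_bins = 24, n_ctrl = 100, seed = 1,
                         name = "module") {
  all_genes <- colnames(norm$values)
  genes_used <- intersect(gene_set, all_genes)
  genes_missing <- setdiff(gene_set, all_genes)
  if (!length(genes_used))
    stop("no gene of the set is present in the matrix", call. = FALSE)
  x <- norm$values[norm$in_tissue, , drop = FALSE]
  avg <- Matrix::colMeans(x)
  # equal-size expression bins by rank of mean expression
  bin <- ceiling(rank(avg, ties.method = "first") / (length(avg) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  n_short <- 0L
  ctrl <- withr_seed(seed, {
    unlist(lapply(genes_used, function(g) {
      pool <- all_genes[bin == bin[match(g, all_genes)]]
      pool <- setdiff(pool, genes_used)
      if (!length(pool)) return(character(0))
      if (length(pool) < n_ctrl) {
        n_short <<- n_short + 1L
        pool
      } else sample(pool, n_ctrl)
    }))
  })
  if (n_short > 0)
    warning(sprintf(
      "%d of %d set genes had control pools smaller than n_ctrl = %d; whole bins used",
      n_short, length(genes_used), n_ctrl))
  set_mean <- Matrix::rowMeans(x[, genes_used, drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    Matrix::rowMeans(x[, ctrl, drop = FALSE]) else 0
  structure(list(score = set_mean - ctrl_mean, name = name,
                 genes_used = genes_used, genes_missing = genes_missing,
                 params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)),
            class = "module_score")
}

#' Per-spot score vector aligned to a section's spots
#'
#' Helper to expand a `module_score` (defined on in-tissue spots) to the
#' full spot vector with NA elsewhere.
#'
#' @param ms a `module_score`.
#' @param section the originating `spatial_section`.
#' @return numeric vector of length `nrow(section)`.
#' @export
score_by_spot <- function(ms, section) {
  v <- rep(NA_real_, length(section$spot_ids))
  v[match(names(ms$score), section$spot_ids)] <- ms$score
  v
}
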