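#' Read a 10x-style spatial dataset from a directory
#'
#' Expects the conventional layout: `matrix.mtx` (MatrixMarket integer
#' matrix), `barcodes.tsv` (one barcode per line), `features.tsv` (id and
#' symbol columns), and `tissue_positions.csv` with columns
#' `barcode, in_tissue, array_row, array_col, pxl_row, pxl_col`. The matrix
#' may be stored either spots x genes or genes x spots; orientation is
#' resolved against the id-list lengths.
#'
#' @param path directory containing the four files.
#' @param section_id section identifier; defaults to the directory name.
#' @return a [spatial_section()].
#' @export
read_spatial_dataset <- function(path, section_id = basename(normalizePath(path))) {
  need <- c("matrix.mtx", "barcodes.tsv", "features.tsv", "tissue_positions.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("missing file in spatial dataset directory: ", f, call. = FALSE)
  }
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))
  if (length(m@x) && any(m@x != round(m@x)))
    stop("matrix.mtx contains non-integer entries", call. = FALSE)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  feats <- utils::read.delim(file.path(path, "features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  genes <- feats[[min(2L, ncol(feats))]]
  nb <- length(barcodes); ng <- length(genes)
  if (nrow(m) == nb && ncol(m) == ng) {
    # stored spots x genes
  } else if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf("matrix dims %dx%d match neither %d barcodes x %d features orientation",
                 nrow(m), ncol(m), nb, ng), call. = FALSE)
  }
  pos <- utils::read.csv(file.path(path, "tissue_positions.csv"),
                         stringsAsFactors = FALSE)
  names(pos)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                       "pxl_row", "pxl_col")
  missing_bc <- setdiff(barcodes, pos$barcode)
  if (length(missing_bc))
    stop("barcodes absent from tissue_positions.csv: ",
         paste(utils::head(missing_bc, 5), collapse = ", "), call. = FALSE)
  pos <- pos[match(barcodes, pos$barcode), ]
  spatial_section(counts = m,
                  coords = cbind(pos$pxl_col, pos$pxl_row),
                  spot_ids = barcodes, gene_ids = genes,
                  array_pos = cbind(pos$array_row, pos$array_col),
                  metadata = data.frame(in_tissue = pos$in_tissue == 1),
                  section_id = section_id)
}

#' Write a section in the 10x-style layout read by [read_spatial_dataset()]
#'
#' @param section a `spatial_section`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_spatial_dataset <- function(section, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(section$counts, file.path(path, "matrix.mtx"))
  writeLines(section$spot_ids, file.path(path, "barcodes.tsv"))
  utils::write.table(data.frame(id = section$gene_ids, symbol = section$gene_ids),
                     file.path(path, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pos <- data.frame(barcode = section$spot_ids,
                    in_tissue = as.integer(section$metadata$in_tissue),
                    array_row = section$array_pos[, 1],
                    array_col = section$array_pos[, 2],
                    pxl_row = section$coords[, 2],
                    pxl_col = section$coords[, 1])
  utils::write.csv(pos, file.path(path, "tissue_positions.csv"),
                   quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes expressed in too few spots
#'
#' A gene is kept iff it has a non-zero count in strictly more than
#' `min_fraction` of the in-tissue spots; at the default 0.003 a gene seen
#' in exactly 0.3% of spots is excluded. Gene order is preserved.
#'
#' @param section a `spatial_section`.
#' @param min_fraction prevalence threshold in `[0, 1]`.
#' @return the filtered `spatial_section`.
#' @export
filter_genes <- function(section, min_fraction = 0.003) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  idx <- in_tissue_idx(section)
  nnz <- Matrix::colSums(section$counts[idx, , drop = FALSE] > 0)
  keep <- nnz > min_fraction * length(idx)
  section$counts <- section$counts[, keep, drop = FALSE]
  section$gene_ids <- section$gene_ids[keep]
  section
}

#' Log2 counts-per-million normalization
#'
#' Computes `log2(1 + 1e6 * c_ig / sum_g c_ig)` per spot. Zero counts map
#' to zero, so sparsity is preserved.
#'
#' @param section a `spatial_section`.
#' @return a `normalized_matrix`: list with `values` (sparse spots x genes
#'   matrix on the log2(CPM+1) scale), `section_id`, `in_tissue`, `coords`,
#'   and `metadata` carried over from the section.
#' @export
normalize_log_cpm <- function(section) {
  totals <- Matrix::rowSums(section$counts)
  bad <- which(section$metadata$in_tissue & totals == 0)
  if (length(bad))
    stop("in-tissue spots with zero total count: ",
         paste(utils::head(section$spot_ids[bad], 5), collapse = ", "),
         call. = FALSE)
  sf <- ifelse(totals > 0, 1e6 / totals, 0)
  v <- Matrix::Diagonal(x = sf) %*% section$counts
  v@x <- log2(1 + v@x)
  dimnames(v) <- dimnames(section$counts)
  structure(list(values = v, section_id = section$section_id,
                 in_tissue = section$metadata$in_tissue,
                 coords = section$coords, metadata = section$metadata,
                 params = list(scheme = "log2cpm1")),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix '%s': %d spots x %d genes, log2(CPM+1)\n",
              x$section_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Row-bind two normalized matrices over their shared gene universe
#'
#' Used to score paired (e.g. control/mutant) sections jointly so that a
#' module score is computed against one common expression ranking; barcodes
#' are prefixed with each section id to stay unique.
#'
#' @param a,b `normalized_matrix` objects.
#' @return a `normalized_matrix` over the shared genes with an extra
#'   `section` column in its metadata.
#' @export
bind_normalized <- function(a, b) {
  shared <- intersect(colnames(a$values), colnames(b$values))
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  va <- a$values[, shared, drop = FALSE]
  vb <- b$values[, shared, drop = FALSE]
  rownames(va) <- paste(a$section_id, rownames(va), sep = ":")
  rownames(vb) <- paste(b$section_id, rownames(vb), sep = ":")
  structure(list(values = rbind(va, vb),
                 section_id = paste(a$section_id, b$section_id, sep = "+"),
                 in_tissue = c(a$in_tissue, b$in_tissue),
                 coords = rbind(a$coords, b$coords),
                 metadata = data.frame(
                   in_tissue = c(a$in_tissue, b$in_tissue),
                   section = rep(c(a$section_id, b$section_id),
                                 c(nrow(va), nrow(vb)))),
                 params = list(scheme = "bind")),
            class = "normalized_matrix")
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their normalized values across in-tissue
#' spots and returns the top `n` symbols. Ties are broken by lexical order
#' of the symbol (smaller symbol ranks first).
#'
#' @param norm a `normalized_matrix`.
#' @param n number of genes to return.
#' @return character vector of `n` gene symbols.
#' @export
select_hvg <- function(norm, n = 2000) {
  genes <- colnames(norm$values)
  stopifnot(n <= length(genes))
  v <- col_vars_sparse(norm$values[norm$in_tissue, , drop = FALSE])
  ord <- order(-v, genes)
  genes[ord[seq_len(n)]]
}

# column variances of a sparse matrix without densifying
col_vars_sparse <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colSums(m) / n
  (Matrix::colSums(m^2) - n * mu^2) / (n - 1)
}
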