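#' Construct a spatial section
#'
#' A `spatial_section` holds one tissue section captured on a spot array:
#' sparse non-negative integer counts (spots x genes), continuous 2D spot
#' coordinates in pixel units, integer array positions, and per-spot
#' metadata (at minimum an `in_tissue` flag; clustering and genotype labels
#' are added by downstream steps).
#'
#' @param counts sparse or dense non-negative integer matrix, spots x genes.
#' @param coords numeric matrix (spots x 2) of pixel coordinates.
#' @param spot_ids character vector of unique barcodes, one per spot.
#' @param gene_ids character vector of unique gene symbols.
#' @param array_pos integer matrix (spots x 2) of array (row, col); optional.
#' @param metadata data.frame of per-spot columns; an `in_tissue` logical
#'   column is added (all `TRUE`) when absent.
#' @param section_id single string identifying the section.
#' @return An object of class `spatial_section`.
#' @export
spatial_section <- function(counts, coords, spot_ids, gene_ids,
                            array_pos = NULL, metadata = NULL,
                            section_id = "section") {
  counts <- as_sparse_counts(counts)
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers", call. = FALSE)
  n_spot <- nrow(counts); n_gene <- ncol(counts)
  if (length(spot_ids) != n_spot || length(gene_ids) != n_gene)
    stop("id lists inconsistent with count matrix dimensions", call. = FALSE)
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  coords <- as.matrix(coords)
  if (nrow(coords) != n_spot || ncol(coords) != 2)
    stop("coords must be a spots x 2 matrix", call. = FALSE)
  if (is.null(array_pos)) array_pos <- matrix(NA_integer_, n_spot, 2)
  array_pos <- as.matrix(array_pos)
  if (is.null(metadata)) metadata <- data.frame(row.names = spot_ids)
  if (is.null(metadata$in_tissue)) metadata$in_tissue <- rep(TRUE, n_spot)
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  dimnames(coords) <- list(spot_ids, c("x", "y"))
  dimnames(array_pos) <- list(spot_ids, c("row", "col"))
  rownames(metadata) <- spot_ids
  structure(list(counts = counts, coords = coords, spot_ids = spot_ids,
                 gene_ids = gene_ids, array_pos = array_pos,
                 metadata = metadata, section_id = section_id),
            class = "spatial_section")
}

# coerce any numeric matrix-like input to a dgCMatrix
as_sparse_counts <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  m
}

#' @export
print.spatial_section <- function(x, ...) {
  cat(sprintf("spatial_section '%s': %d spots x %d genes (%d in tissue)\n",
              x$section_id, length(x$spot_ids), length(x$gene_ids),
              sum(x$metadata$in_tissue)))
  invisible(x)
}

#' @export
dim.spatial_section <- function(x) dim(x$counts)

#' Indices of in-tissue spots
#' @param section a `spatial_section`.
#' @return integer vector of row indices with `in_tissue == TRUE`.
#' @export
in_tissue_idx <- function(section) which(section$metadata$in_tissue)
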