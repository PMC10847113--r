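#' Construct a CountMatrix
#'
#' A `CountMatrix` bundles a genes x cells matrix of non-negative integer
#' counts with per-cell and per-gene annotations. It is the entry container
#' for all single-cell operations in the package.
#'
#' @param counts genes x cells matrix (base matrix or [Matrix::dgCMatrix-class])
#'   of non-negative integral counts, with unique rownames (gene ids) and
#'   colnames (cell ids).
#' @param cell_meta data.frame keyed by `cell_id` (one row per cell, same
#'   order-free key as `colnames(counts)`). Recognised columns: `line_id`,
#'   `group_label` (e.g. `"SR101high"` / `"SR101low"`), `cluster_id`,
#'   `true_state`. Missing annotations are allowed.
#' @param gene_meta optional data.frame keyed by `gene_id`; a logical `mito`
#'   column flags mitochondrial genes. When absent, mitochondrial genes are
#'   flagged by the `mito_prefix` on the gene id.
#' @param mito_prefix gene-id prefix used to flag mitochondrial genes when
#'   `gene_meta` has no `mito` column. Default `"MT-"`.
#'
#' @return an object of class `CountMatrix`: a list with elements `counts`,
#'   `cell_meta`, `gene_meta`.
#' @export
CountMatrix <- function(counts, cell_meta = NULL, gene_meta = NULL,
                        mito_prefix = "MT-") {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene ids as rownames and cell ids as colnames")
  }
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else counts
  if (any(vals < 0)) stop("counts must be non-negative")
  if (any(vals != round(vals))) stop("counts must be integral")

  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta)) {
    stop("`cell_meta` must have a `cell_id` column")
  }
  if (!setequal(cell_meta$cell_id, cell_ids) ||
      nrow(cell_meta) != length(cell_ids)) {
    stop("`cell_meta` must be keyed 1:1 to the cell ids of `counts`")
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL

  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  }
  if (!"gene_id" %in% names(gene_meta)) {
    stop("`gene_meta` must have a `gene_id` column")
  }
  if (!setequal(gene_meta$gene_id, gene_ids) ||
      nrow(gene_meta) != length(gene_ids)) {
    stop("`gene_meta` must be keyed 1:1 to the gene ids of `counts`")
  }
  gene_meta <- gene_meta[match(gene_ids, gene_meta$gene_id), , drop = FALSE]
  rownames(gene_meta) <- NULL
  if (!"mito" %in% names(gene_meta)) {
    gene_meta$mito <- startsWith(gene_meta$gene_id, mito_prefix)
  }

  structure(
    list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
    class = "CountMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf(
    "CountMatrix: %d genes x %d cells (%d mitochondrial genes flagged)\n",
    nrow(x$counts), ncol(x$counts), sum(x$gene_meta$mito)
  ))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra)) cat("cell annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Number of genes / cells in a CountMatrix or NormalizedMatrix
#' @param x a `CountMatrix` or `NormalizedMatrix`
#' @return integer count
#' @export
n_genes <- function(x) nrow(if (inherits(x, "CountMatrix")) x$counts else x$values)

#' @rdname n_genes
#' @export
n_cells <- function(x) ncol(if (inherits(x, "CountMatrix")) x$counts else x$values)

#' Subset a CountMatrix by gene and/or cell ids
#'
#' @param cm a `CountMatrix`
#' @param genes,cells character vectors of ids to keep (NULL keeps all)
#' @return a `CountMatrix`
#' @export
subset_cm <- function(cm, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- rownames(cm$counts)
  if (is.null(cells)) cells <- colnames(cm$counts)
  CountMatrix(
    cm$counts[genes, cells, drop = FALSE],
    cell_meta = cm$cell_meta[cm$cell_meta$cell_id %in% cells, , drop = FALSE],
    gene_meta = cm$gene_meta[cm$gene_meta$gene_id %in% genes, , drop = FALSE]
  )
}

new_normalized_matrix <- function(values, cell_meta, gene_meta, scale_factor,
                                  source = "CountMatrix") {
  structure(
    list(values = values, cell_meta = cell_meta, gene_meta = gene_meta,
         scale_factor = scale_factor, source = source),
    class = "NormalizedMatrix"
  )
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf(
    "NormalizedMatrix: %d genes x %d cells, ln(1 + %g * count / total)\n",
    nrow(x$values), ncol(x$values), x$scale_factor
  ))
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)
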