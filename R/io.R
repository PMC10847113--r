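#' Write / read a CountMatrix as a MatrixMarket triple
#'
#' The on-disk layout follows the common single-cell exchange convention:
#' `matrix.mtx` (genes x cells, 1-based coordinates), `genes.tsv` (gene_id,
#' mito), `barcodes.tsv` (cell ids) and `cell_meta.tsv` (all cell
#' annotations, keyed by cell_id).
#'
#' @param cm a [CountMatrix()]
#' @param dir output directory (created if missing)
#' @return `write_count_mtx`: the directory, invisibly.
#' @export
write_count_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(cm$counts, "dMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(cm$gene_meta[, c("gene_id", "mito")],
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_count_mtx
#' @return `read_count_mtx`: the reconstructed `CountMatrix`.
#' @export
read_count_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes$gene_id, barcodes)
  meta_path <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  CountMatrix(m, cell_meta = cell_meta, gene_meta = genes)
}

#' Write / read a CountMatrix as a dense TSV
#'
#' Genes in rows, cells in columns, gene ids in the first column
#' (`gene_id`). Cell annotations are not serialized by this format.
#'
#' @param cm a [CountMatrix()]
#' @param path TSV file path
#' @export
write_count_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "CountMatrix"))
  df <- data.frame(gene_id = rownames(cm$counts),
                   as.matrix(cm$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @param path TSV file path
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  CountMatrix(m)
}

#' Write / read a gene signature as a two-column TSV
#'
#' The exchange format consumed by the scoring stage: header `gene_id`,
#' `direction` with direction in `{"up", "down"}`.
#'
#' @param sig a [gene_signature()]
#' @param path TSV file path
#' @export
write_signature_tsv <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  df <- data.frame(
    gene_id = c(sig$up, sig$down),
    direction = rep(c("up", "down"), c(length(sig$up), length(sig$down))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @param name signature name given to the reconstructed object
#' @export
read_signature_tsv <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction") %in% names(df))) {
    stop("signature TSV must have columns gene_id, direction")
  }
  if (!all(df$direction %in% c("up", "down"))) {
    stop("signature direction must be 'up' or 'down'")
  }
  gene_signature(name,
                 up = df$gene_id[df$direction == "up"],
                 down = df$gene_id[df$direction == "down"])
}

#' Write / read calcium traces and cell positions as CSV
#'
#' Traces: rows = frames, columns = cells (header = cell ids). Positions:
#' columns `cell_id`, `x_um`, `y_um`.
#'
#' @param rec a `CalciumRecording` (see [simulate_calcium_recording()])
#' @param traces_path,positions_path CSV file paths
#' @export
write_calcium_csv <- function(rec, traces_path, positions_path) {
  stopifnot(inherits(rec, "CalciumRecording"))
  utils::write.csv(as.data.frame(t(rec$traces), check.names = FALSE),
                   traces_path, row.names = FALSE)
  utils::write.csv(rec$positions, positions_path, row.names = FALSE)
  invisible(traces_path)
}

#' @rdname write_calcium_csv
#' @param frame_interval_s frame interval in seconds (not stored in the CSV)
#' @export
read_calcium_csv <- function(traces_path, positions_path,
                             frame_interval_s = 1.52) {
  tr <- utils::read.csv(traces_path, check.names = FALSE)
  pos <- utils::read.csv(positions_path, stringsAsFactors = FALSE)
  calcium_recording(t(as.matrix(tr)), positions = pos,
                    frame_interval_s = frame_interval_s)
}
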