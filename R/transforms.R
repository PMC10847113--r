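#' Library-size log-normalization
#'
#' Scales each cell to a common library size and applies the natural-log
#' transform: `value(g, c) = ln(1 + scale_factor * count(g, c) / total(c))`.
#' Zero counts stay exactly zero, so sparsity is preserved.
#'
#' @param cm a [CountMatrix()]
#' @param scale_factor positive library-size target, default 10,000
#' @return a `NormalizedMatrix` with the same gene/cell order and annotations
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"), scale_factor > 0)
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0)) {
    bad <- colnames(cm$counts)[totals == 0][1]
    stop(sprintf("cell '%s' has zero total count; cannot normalize", bad))
  }
  if (methods::is(cm$counts, "sparseMatrix")) {
    vals <- methods::as(cm$counts, "CsparseMatrix") %*%
      Matrix::Diagonal(x = scale_factor / totals)
    vals <- methods::as(vals, "CsparseMatrix")
    vals@x <- log1p(vals@x)
    dimnames(vals) <- dimnames(cm$counts)
  } else {
    vals <- log1p(sweep(cm$counts, 2, scale_factor / totals, `*`))
  }
  new_normalized_matrix(vals, cm$cell_meta, cm$gene_meta, scale_factor)
}

#' Winsorized z-scaling
#'
#' Centers and scales a score vector (mean 0, sample sd with the n-1
#' denominator) and clips the result to `[-3, 3]`. A zero-variance input
#' yields all zeros with a warning.
#'
#' @param v numeric vector (length >= 2), optionally named by unit id
#' @param limit clip bound, default 3
#' @return numeric vector with attribute `scaling_state = "z_winsorized"`
#' @export
z_winsorize <- function(v, limit = 3) {
  if (length(v) < 2) stop("z_winsorize needs at least 2 values")
  if (identical(attr(v, "scaling_state"), "z_winsorized")) {
    stop("input is already z-winsorized")
  }
  s <- stats::sd(v)
  if (s == 0 || !is.finite(s)) {
    warning("zero variance: z_winsorize returns all zeros")
    z <- rep(0, length(v))
  } else {
    z <- pmin(pmax((v - mean(v)) / s, -limit), limit)
  }
  names(z) <- names(v)
  attr(z, "scaling_state") <- "z_winsorized"
  z
}

#' Quality-control thresholds for single-cell filtering
#'
#' Fixed per-cell cutoffs for detected genes, total counts and the
#' mitochondrial count fraction, plus the MAD multiplier for the
#' sample-wise outlier rule.
#'
#' @param min_genes,max_genes detected-gene bounds (cells outside are removed)
#' @param min_counts,max_counts total-count bounds
#' @param max_mito_frac maximum tolerated mitochondrial count fraction
#' @param n_mads MAD multiplier for [qc_filter_mad()]
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 8000,
                          min_counts = 500, max_counts = 80000,
                          max_mito_frac = 0.10, n_mads = 3) {
  stopifnot(min_genes < max_genes, min_counts < max_counts,
            max_mito_frac >= 0, max_mito_frac <= 1, n_mads > 0)
  structure(
    list(min_genes = min_genes, max_genes = max_genes,
         min_counts = min_counts, max_counts = max_counts,
         max_mito_frac = max_mito_frac, n_mads = n_mads),
    class = "qc_thresholds"
  )
}

#' Fixed-threshold cell quality filter
#'
#' Removes cells with a detected-gene number outside `[min_genes, max_genes]`,
#' a total count outside `[min_counts, max_counts]`, or a mitochondrial count
#' fraction above `max_mito_frac`. When no gene is flagged mitochondrial the
#' mito rule is skipped with a warning.
#'
#' @param cm a [CountMatrix()] whose `gene_meta$mito` flags mitochondrial genes
#' @param thr a [qc_thresholds()] object
#' @return the filtered `CountMatrix`; attribute `qc_summary` reports the
#'   number of cells failing each rule and the number removed overall
#' @export
qc_filter_fixed <- function(cm, thr = qc_thresholds()) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(thr, "qc_thresholds"))
  detected <- Matrix::colSums(cm$counts > 0)
  totals <- Matrix::colSums(cm$counts)
  fail_genes <- detected < thr$min_genes | detected > thr$max_genes
  fail_counts <- totals < thr$min_counts | totals > thr$max_counts
  if (!any(cm$gene_meta$mito)) {
    warning("no mitochondrial genes flagged; mito-fraction rule skipped")
    fail_mito <- rep(FALSE, n_cells(cm))
  } else {
    mito_frac <- Matrix::colSums(cm$counts[cm$gene_meta$mito, , drop = FALSE]) /
      totals
    fail_mito <- mito_frac > thr$max_mito_frac
  }
  keep <- !(fail_genes | fail_counts | fail_mito)
  out <- subset_cm(cm, cells = colnames(cm$counts)[keep])
  attr(out, "qc_summary") <- list(
    n_in = n_cells(cm), n_kept = sum(keep),
    fail_genes = sum(fail_genes), fail_counts = sum(fail_counts),
    fail_mito = sum(fail_mito)
  )
  out
}

#' One-sided MAD outlier rule
#'
#' Flags cells whose per-cell statistic (e.g. detected genes or total counts)
#' exceeds `median + n_mads * MAD`, using the scaled MAD
#' (1.4826 x median absolute deviation). Only the high tail is removed. When
#' the MAD is zero the rule degenerates to "strictly above the median"
#' (within 1e-12), so for constant input nothing is removed.
#'
#' @param values numeric per-cell statistic (length >= 3)
#' @param n_mads MAD multiplier, default 3
#' @return logical keep mask, `TRUE` for cells retained
#' @export
qc_filter_mad <- function(values, n_mads = 3) {
  if (length(values) < 3) stop("qc_filter_mad needs at least 3 cells")
  med <- stats::median(values)
  m <- stats::mad(values)  # scaled, constant = 1.4826
  values <= med + n_mads * m + 1e-12
}

#' Remove genes with low total counts from a bulk table
#'
#' Drops genes whose total count across all samples is below `min_total`
#' (the boundary `min_total` itself is kept).
#'
#' @param counts genes x samples matrix of non-negative counts
#' @param min_total threshold, default 10
#' @return the filtered matrix (possibly with zero rows)
#' @export
lowcount_gene_filter <- function(counts, min_total = 10) {
  stopifnot(all(counts >= 0))
  counts[Matrix::rowSums(counts) >= min_total, , drop = FALSE]
}
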