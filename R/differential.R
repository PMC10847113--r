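# Differential expression tests and the signature-construction cascades.

# Two-sided Wilcoxon rank-sum p-value for one gene, mirroring
# stats::wilcox.test defaults: exact when both groups < 50 and no ties,
# otherwise normal approximation with continuity and ties correction.
rank_sum_p <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  r <- rank(c(xa, xb))
  W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  nties <- table(r)
  if (na < 50 && nb < 50 && !any(nties > 1)) {
    if (W > na * nb / 2) {
      min(1, 2 * stats::pwilcox(W - 1, na, nb, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::pwilcox(W, na, nb))
    }
  } else {
    z <- W - na * nb / 2
    n <- na + nb
    sigma <- sqrt((na * nb / 12) *
                    ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
    if (!is.finite(sigma) || sigma == 0) return(1)  # constant gene
    z <- (z - sign(z) * 0.5) / sigma
    2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  }
}

resolve_group <- function(nm, group) {
  cells <- colnames(nm$values)
  if (length(group) == 1 && !(group %in% cells) &&
      "group_label" %in% names(nm$cell_meta)) {
    group <- nm$cell_meta$cell_id[nm$cell_meta$group_label == group]
  }
  if (!length(group)) stop("empty group")
  if (!all(group %in% cells)) stop("unknown cell ids in group")
  group
}

#' Wilcoxon rank-sum marker test between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log-normalized values, with
#' the detection-fraction and fold-change prefilters of standard single-cell
#' marker detection. The log fold change is the natural-log difference of
#' group means on the de-logged scale:
#' `ln(mean(expm1(a)) + 1) - ln(mean(expm1(b)) + 1)`.
#' P-values are Bonferroni-adjusted over the tested genes.
#'
#' @param nm a [lognormalize()]d matrix
#' @param group_a,group_b character vectors of cell ids, or a single
#'   `group_label` value from the cell metadata; the groups must not overlap
#' @param min_pct minimum detection fraction in at least one group
#' @param logfc_min minimum absolute log fold change to test
#' @param base `"ln"` (default) or `"log2"` for the reported fold change;
#'   `logfc_min` is applied on the chosen scale
#' @return a data.frame (one row per tested gene) with columns `gene_id`,
#'   `logfc`, `p`, `p_adj`, `pct_a`, `pct_b`; attributes `logfc_base` and
#'   `comparison`
#' @export
rank_sum_markers <- function(nm, group_a, group_b, min_pct = 0.1,
                             logfc_min = 0.25, base = c("ln", "log2")) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  base <- match.arg(base)
  a <- resolve_group(nm, group_a)
  b <- resolve_group(nm, group_b)
  if (length(intersect(a, b))) stop("groups overlap")
  va <- as.matrix(nm$values[, a, drop = FALSE])
  vb <- as.matrix(nm$values[, b, drop = FALSE])
  pct_a <- rowMeans(va > 0)
  pct_b <- rowMeans(vb > 0)
  logfc <- log(rowMeans(expm1(va)) + 1) - log(rowMeans(expm1(vb)) + 1)
  if (base == "log2") logfc <- logfc / log(2)
  tested <- (pct_a >= min_pct | pct_b >= min_pct) & abs(logfc) >= logfc_min
  idx <- which(tested)
  p <- vapply(idx, function(g) rank_sum_p(va[g, ], vb[g, ]), numeric(1))
  out <- data.frame(
    gene_id = rownames(va)[idx],
    logfc = logfc[idx],
    p = p,
    p_adj = stats::p.adjust(p, method = "bonferroni"),
    pct_a = pct_a[idx], pct_b = pct_b[idx],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "logfc_base") <- base
  attr(out, "comparison") <- paste(group_a[1], "vs", group_b[1])
  out
}

#' Aggregate per-line marker tables into a connectivity signature
#'
#' Pools the significant genes (`p_adj < padj_max`) of three per-line DEG
#' tables and keeps a gene if it is significant with the same sign in all
#' three lines, or significant with the same sign and
#' `|logfc| >= lfc_two_line` in exactly two lines (both lines must clear the
#' fold-change bar). Genes significant with conflicting signs are dropped.
#'
#' @param tables list of exactly 3 DEG tables from [rank_sum_markers()]
#' @param padj_max significance cutoff on the adjusted p-value
#' @param lfc_two_line absolute log-fold-change bar for the two-line rule,
#'   applied on the tables' own log scale (natural log by default)
#' @param name signature name
#' @return a [gene_signature()]
#' @export
aggregate_sc_signature <- function(tables, padj_max = 0.05,
                                   lfc_two_line = 0.4,
                                   name = "connectivity") {
  if (length(tables) != 3) stop("exactly 3 per-line tables are required")
  sig_rows <- lapply(tables, function(t) t[t$p_adj < padj_max, , drop = FALSE])
  genes <- unique(unlist(lapply(sig_rows, `[[`, "gene_id")))
  up <- character(); down <- character()
  for (g in genes) {
    hits <- do.call(rbind, lapply(sig_rows, function(t) {
      t[t$gene_id == g, c("gene_id", "logfc"), drop = FALSE]
    }))
    signs <- sign(hits$logfc)
    if (any(signs == 0) || length(unique(signs)) > 1) next  # sign conflict
    keep <- nrow(hits) == 3 ||
      (nrow(hits) == 2 && all(abs(hits$logfc) >= lfc_two_line))
    if (!keep) next
    if (signs[1] > 0) up <- c(up, g) else down <- c(down, g)
  }
  gene_signature(name, up = up, down = down,
                 provenance = list(rule = "3-line-consensus-or-2-line-lfc",
                                   padj_max = padj_max,
                                   lfc_two_line = lfc_two_line))
}

#' Negative-binomial group test on bulk counts with a line covariate
#'
#' Fits per-gene negative-binomial regressions with `~ line + group`
#' (DESeq2) and reports the Wald test on the group coefficient with
#' Benjamini-Hochberg adjustment. The log2 fold change is high over low,
#' unshrunk by default.
#'
#' @param counts genes x samples matrix of non-negative integer counts
#'   (low-count genes should already be filtered, see
#'   [lowcount_gene_filter()])
#' @param sample_meta data.frame with `sample_id`, `line_id`, `group_label`
#'   matching the columns of `counts`
#' @param high,low `group_label` values of the numerator and denominator
#'   group
#' @param shrink apply DESeq2's built-in normal-prior shrinkage to the
#'   reported log2 fold change (default off; thresholds downstream are meant
#'   for unshrunk estimates)
#' @return a DEG table as in [rank_sum_markers()], with `logfc` on the log2
#'   scale and `p_adj` from Benjamini-Hochberg
#' @export
nb_group_test <- function(counts, sample_meta, high = "SR101high",
                          low = "SR101low", shrink = FALSE) {
  stopifnot(all(colnames(counts) == sample_meta$sample_id))
  if (sum(sample_meta$group_label == high) < 2 ||
      sum(sample_meta$group_label == low) < 2) {
    stop("need at least 2 samples per group")
  }
  col_data <- data.frame(
    line = factor(sample_meta$line_id),
    group = factor(sample_meta$group_label, levels = c(low, high))
  )
  design <- if (nlevels(col_data$line) > 1) ~ line + group else ~ group
  mm <- stats::model.matrix(design, col_data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("singular design; confounded terms: ", paste(bad, collapse = ", "))
  }
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = counts, colData = col_data, design = design
  )
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  coef_name <- paste0("group_", make.names(high), "_vs_", make.names(low))
  res <- DESeq2::results(dds, name = coef_name,
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  if (shrink) {
    res_shr <- DESeq2::lfcShrink(dds, coef = coef_name, type = "normal",
                                 quiet = TRUE)
    res$log2FoldChange <- res_shr$log2FoldChange
  }
  in_high <- sample_meta$group_label == high
  out <- data.frame(
    gene_id = rownames(res),
    logfc = ifelse(is.na(res$log2FoldChange), 0, res$log2FoldChange),
    p = ifelse(is.na(res$pvalue), 1, res$pvalue),
    p_adj = ifelse(is.na(res$padj), 1, res$padj),
    pct_a = rowMeans(counts[, in_high, drop = FALSE] > 0),
    pct_b = rowMeans(counts[, !in_high, drop = FALSE] > 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "logfc_base") <- "log2"
  attr(out, "comparison") <- paste(high, "vs", low)
  out
}

#' Threshold filter turning a bulk DEG table into a signature
#'
#' Keeps significant genes (`p_adj < padj_max`) with
#' `|log2 fold change| >= abs_log2fc_min` (boundary inclusive) and assigns
#' up/down by sign.
#'
#' @param tab DEG table from [nb_group_test()] (log2 fold changes)
#' @param padj_max,abs_log2fc_min thresholds
#' @param name signature name
#' @return a [gene_signature()]
#' @export
aggregate_bulk_signature <- function(tab, padj_max = 0.05,
                                     abs_log2fc_min = 1,
                                     name = "connectivity_bulk") {
  keep <- tab$p_adj < padj_max & abs(tab$logfc) >= abs_log2fc_min
  gene_signature(name,
                 up = tab$gene_id[keep & tab$logfc > 0],
                 down = tab$gene_id[keep & tab$logfc < 0],
                 provenance = list(padj_max = padj_max,
                                   abs_log2fc_min = abs_log2fc_min))
}

#' Five-filter cascade for calcium-history labeling signatures
#'
#' Merges the DEG records of three pairwise intensity comparisons
#' (high-vs-medium, medium-vs-low, high-vs-low) and applies, in order:
#' 1. records with FDR > `fdr_max` are removed;
#' 2. genes detected in only one comparison are removed;
#' 3. genes without a consistent direction of regulation are removed;
#' 4. low-expression genes (mean logCPM across remaining records
#'    < `min_logcpm`) are removed;
#' 5. genes not ranking in the top `top_n` or bottom `top_n` by fold change
#'    in every comparison in which they remain are removed (set
#'    `top_rule = "any"` to require one comparison only).
#'
#' @param tables named list of exactly 3 DEG tables with columns `gene_id`,
#'   `logfc`, `p_adj`, `logcpm`
#' @param fdr_max,min_logcpm,top_n filter parameters
#' @param top_rule `"every"` (default) or `"any"`
#' @param name signature name
#' @return a [gene_signature()]
#' @export
caprola_cascade <- function(tables, fdr_max = 0.05, min_logcpm = 2,
                            top_n = 50, top_rule = c("every", "any"),
                            name = "caprola") {
  top_rule <- match.arg(top_rule)
  if (length(tables) != 3) stop("exactly 3 comparison tables are required")
  if (is.null(names(tables))) names(tables) <- paste0("cmp", 1:3)
  for (nmx in names(tables)) {
    if (!"logcpm" %in% names(tables[[nmx]])) {
      stop("table '", nmx, "' is missing the logcpm column")
    }
  }
  rec <- do.call(rbind, lapply(names(tables), function(cmp) {
    t <- tables[[cmp]]
    data.frame(gene_id = t$gene_id, logfc = t$logfc, p_adj = t$p_adj,
               logcpm = t$logcpm, comparison = cmp,
               stringsAsFactors = FALSE)
  }))

  empty <- function() gene_signature(name, provenance = list(empty = TRUE))
  rec <- rec[rec$p_adj <= fdr_max, , drop = FALSE]               # filter 1
  if (!nrow(rec)) return(empty())
  n_cmp <- table(rec$gene_id)
  rec <- rec[n_cmp[rec$gene_id] >= 2, , drop = FALSE]            # filter 2
  if (!nrow(rec)) return(empty())
  consistent <- tapply(sign(rec$logfc), rec$gene_id,
                       function(s) length(unique(s)) == 1 && all(s != 0))
  rec <- rec[consistent[rec$gene_id], , drop = FALSE]            # filter 3
  if (!nrow(rec)) return(empty())
  mean_cpm <- tapply(rec$logcpm, rec$gene_id, mean)
  rec <- rec[mean_cpm[rec$gene_id] >= min_logcpm, , drop = FALSE] # filter 4
  if (!nrow(rec)) return(empty())

  # filter 5: top/bottom-n by fold change within each comparison
  in_extreme <- rep(FALSE, nrow(rec))
  for (cmp in unique(rec$comparison)) {
    i <- which(rec$comparison == cmp)
    ord <- i[order(rec$logfc[i], rec$gene_id[i])]  # ties: gene-id order
    k <- length(ord)
    extreme <- c(utils::head(ord, min(top_n, k)),
                 utils::tail(ord, min(top_n, k)))
    in_extreme[unique(extreme)] <- TRUE
  }
  ok_gene <- tapply(in_extreme, rec$gene_id,
                    if (top_rule == "every") all else any)
  rec <- rec[ok_gene[rec$gene_id], , drop = FALSE]

  dirs <- tapply(sign(rec$logfc), rec$gene_id, function(s) s[1])
  gene_signature(name,
                 up = names(dirs)[dirs > 0],
                 down = names(dirs)[dirs < 0],
                 provenance = list(fdr_max = fdr_max, min_logcpm = min_logcpm,
                                   top_n = top_n, top_rule = top_rule))
}
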