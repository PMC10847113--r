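#' Parameters for binned-control module scoring
#'
#' @param n_bins number of equal-frequency expression bins, default 24
#' @param n_ctrl control genes drawn per signature gene, default 100
#' @param seed RNG seed for the control draws (scores are reproducible for a
#'   fixed seed)
#' @return a `module_score_params` list
#' @export
module_score_params <- function(n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(n_bins >= 1, n_ctrl >= 1)
  structure(list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
            class = "module_score_params")
}

#' Module score of a gene set with expression-binned controls
#'
#' The score of a cell is the mean normalized expression of the gene set
#' minus the mean over a pooled control set: all genes are binned into
#' `n_bins` equal-frequency bins by their average expression across cells
#' (ties broken by gene-id order), and for each signature gene `n_ctrl`
#' control genes are drawn from its bin without replacement; a bin with at
#' most `n_ctrl` genes contributes whole (each gene once, no sampling). The
#' control pool keeps duplicate contributions across signature genes, so
#' each signature gene carries equal control weight.
#' A positive score means the set is expressed above its expression-matched
#' background in that cell.
#'
#' @param nm a [lognormalize()]d matrix
#' @param genes character vector of signature gene ids; genes absent from
#'   the matrix are dropped with a warning
#' @param params a [module_score_params()]
#' @return named numeric vector of per-cell scores
#' @export
module_score <- function(nm, genes, params = module_score_params()) {
  stopifnot(inherits(nm, "NormalizedMatrix"),
            inherits(params, "module_score_params"))
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(nm$values))
  if (length(missing) == length(genes)) stop("empty gene set after matching")
  if (length(missing)) {
    warning(length(missing), " signature gene(s) not in matrix; dropped")
    genes <- setdiff(genes, missing)
  }
  vals <- nm$values
  avg <- Matrix::rowMeans(vals)
  gene_ids <- rownames(vals)
  # equal-frequency bins on average expression, ties by gene-id order
  ord <- order(avg, gene_ids)
  bin_of <- integer(length(avg))
  bin_of[ord] <- if (params$n_bins == 1) 1L else {
    as.integer(cut(seq_along(ord), breaks = params$n_bins, labels = FALSE))
  }
  names(bin_of) <- gene_ids

  ctrl <- with_seed(params$seed, {
    unlist(lapply(genes, function(g) {
      pool <- gene_ids[bin_of == bin_of[g]]
      if (length(pool) <= params$n_ctrl) pool
      else sample(pool, params$n_ctrl)
    }), use.names = FALSE)
  })
  set_mean <- Matrix::colMeans(vals[genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(vals[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(set_mean - ctrl_mean), colnames(vals))
}

#' Connectivity signature score
#'
#' The per-cell (or per-sample) connectivity signature score is the module
#' score of the signature's up-regulated gene set minus the module score of
#' its down-regulated set. Both sets are required.
#'
#' @param nm a [lognormalize()]d matrix
#' @param sig a [gene_signature()] with non-empty up and down sets
#' @param params a [module_score_params()]
#' @param zwinsorize also report the z-scored, winsorized score (for
#'   plotting and cross-sample comparison); the raw difference is always kept
#' @return data.frame of class `connectivity_scores` with columns `cell_id`,
#'   `up_score`, `down_score`, `connectivity_score` (and
#'   `connectivity_score_z` when `zwinsorize = TRUE`)
#' @export
connectivity_score <- function(nm, sig, params = module_score_params(),
                               zwinsorize = FALSE) {
  stopifnot(inherits(sig, "gene_signature"))
  if (!length(sig$up) || !length(sig$down)) {
    stop("signature must have both an up and a down gene set")
  }
  up <- module_score(nm, sig$up, params)
  down <- module_score(nm, sig$down, params)
  out <- data.frame(cell_id = names(up), up_score = as.numeric(up),
                    down_score = as.numeric(down),
                    connectivity_score = as.numeric(up - down),
                    stringsAsFactors = FALSE)
  if (zwinsorize) {
    out$connectivity_score_z <- as.numeric(z_winsorize(out$connectivity_score))
  }
  class(out) <- c("connectivity_scores", class(out))
  out
}

#' Classify cells as highly or lowly connected from their scores
#'
#' A cell is predicted `"high"` when its up-signature score is strictly
#' higher than its down-signature score; ties go to `"low"`.
#'
#' @param cs a [connectivity_score()] result
#' @return named character vector of `"high"` / `"low"` labels
#' @export
predict_connectivity <- function(cs) {
  stopifnot(all(c("up_score", "down_score") %in% names(cs)))
  stats::setNames(ifelse(cs$up_score > cs$down_score, "high", "low"),
                  cs$cell_id)
}

#' Confusion matrix and prediction metrics
#'
#' @param pred,truth vectors of class labels, aligned by position (or by
#'   name when both are named)
#' @param positive label treated as the positive class, default `"high"`
#' @return list with the 2x2 `table` (prediction x truth) and `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`. Metrics whose denominator
#'   is empty are `NaN` with a warning.
#' @export
confusion_metrics <- function(pred, truth, positive = "high") {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    truth <- truth[names(pred)]
  }
  stopifnot(length(pred) == length(truth))
  pos <- positive
  tp <- sum(pred == pos & truth == pos)
  fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos)
  tn <- sum(pred != pos & truth != pos)
  tab <- matrix(c(tp, fn, fp, tn), 2, 2,
                dimnames = list(pred = c(pos, paste0("not_", pos)),
                                truth = c(pos, paste0("not_", pos))))
  div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (empty denominator); reported as NaN")
      return(NaN)
    }
    num / den
  }
  list(table = tab,
       accuracy = div(tp + tn, tp + tn + fp + fn, "accuracy"),
       sensitivity = div(tp, tp + fn, "sensitivity"),
       specificity = div(tn, tn + fp, "specificity"),
       ppv = div(tp, tp + fp, "ppv"),
       npv = div(tn, tn + fn, "npv"))
}

#' Average prediction metrics of random signatures (negative control)
#'
#' Draws `n_sets` random signatures of the given up/down sizes from the
#' matrix's gene universe, scores and classifies each, and averages the
#' prediction metrics. Mirrors the chance-level control used to benchmark a
#' derived signature: with no planted signal the mean accuracy sits at
#' chance.
#'
#' @param nm a [lognormalize()]d matrix
#' @param truth per-cell `"high"`/`"low"` truth labels (named by cell id or
#'   aligned with the matrix columns)
#' @param sizes lengths of the random up and down sets, default `c(40, 31)`
#' @param n_sets number of random signatures, default 100
#' @param seed RNG seed
#' @param params a [module_score_params()] (its seed is re-derived per set)
#' @return list of mean `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, plus `n_sets`
#' @export
random_control_metrics <- function(nm, truth, sizes = c(40, 31),
                                   n_sets = 100, seed = 1L,
                                   params = module_score_params()) {
  universe <- rownames(nm$values)
  if (sum(sizes) > length(universe)) {
    stop("requested signature sizes exceed the gene universe")
  }
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  draws <- with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      g <- sample(universe, sum(sizes))
      list(sig = gene_signature(sprintf("random%03d", i),
                                up = g[seq_len(sizes[1])],
                                down = g[sizes[1] + seq_len(sizes[2])]),
           score_seed = sample.int(.Machine$integer.max, 1))
    })
  })
  mats <- vapply(draws, function(d) {
    p <- module_score_params(params$n_bins, params$n_ctrl, d$score_seed)
    cs <- connectivity_score(nm, d$sig, p)
    m <- confusion_metrics(predict_connectivity(cs), truth)
    unlist(m[metric_names])
  }, numeric(length(metric_names)))
  out <- as.list(rowMeans(mats))
  out$n_sets <- n_sets
  out
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap of at least `k` genes between a set
#' of size `m` and a set of size `n` drawn from a universe of `N` genes.
#'
#' @param k observed overlap
#' @param m,n sizes of the two sets
#' @param N universe size
#' @return `P(X >= k)`
#' @export
hypergeom_overlap <- function(k, m, n, N) {
  stopifnot(k >= 0, k <= min(m, n), m <= N, n <= N)
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Stratify scores into quartile-based groups
#'
#' Cuts a score vector at its 25th and 75th percentiles (linear
#' interpolation, quantile type 7) into the three groups `Q1`
#' (lowest quartile), `Q2-Q3`, `Q4` (highest quartile); with
#' `four_level = TRUE` the median also splits the middle into `Q2` and `Q3`.
#'
#' @param v numeric score vector (optionally named)
#' @param four_level return four labels instead of three
#' @return factor of group labels in increasing score order
#' @export
quartile_groups <- function(v, four_level = FALSE) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (q[1] == q[3]) {
    warning("degenerate score distribution: all values in one group")
    return(factor(stats::setNames(rep("Q1", length(v)), names(v)),
                  levels = "Q1"))
  }
  if (four_level) {
    lab <- ifelse(v <= q[1], "Q1",
                  ifelse(v <= q[2], "Q2", ifelse(v <= q[3], "Q3", "Q4")))
    lev <- c("Q1", "Q2", "Q3", "Q4")
  } else {
    lab <- ifelse(v <= q[1], "Q1", ifelse(v >= q[3], "Q4", "Q2-Q3"))
    lev <- c("Q1", "Q2-Q3", "Q4")
  }
  factor(stats::setNames(lab, names(v)), levels = lev)
}
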