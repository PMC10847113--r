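# Cell-state scoring/assignment, 2D state projection, and the cluster-level
# malignant / non-malignant typing rule.

#' Canonical order of malignant cell states
#'
#' Used for column ordering and deterministic tie-breaking of the argmax
#' state assignment.
#' @export
CANONICAL_STATES <- c("AC", "MES1", "MES2", "OPC", "NPC1", "NPC2",
                      "G1_S", "G2_M")

#' Score cells against cell-state marker sets and assign states
#'
#' One binned-control [module_score()] per state; each cell is assigned the
#' state with the highest score. Exact ties are broken by the order of
#' `markers` (first state wins) with a warning.
#'
#' @param nm a [lognormalize()]d matrix
#' @param markers named list of marker gene sets, one per state; the list
#'   order is the tie-breaking order
#' @param params a [module_score_params()]
#' @return data.frame of class `state_scores`: `cell_id`, one score column
#'   per state, and `assigned_state`
#' @export
score_states <- function(nm, markers, params = module_score_params()) {
  stopifnot(is.list(markers), length(markers) >= 2,
            !is.null(names(markers)))
  scores <- vapply(seq_along(markers), function(i) {
    p <- module_score_params(params$n_bins, params$n_ctrl,
                             derive_seed(params$seed, i))
    module_score(nm, markers[[i]], p)
  }, numeric(ncol(nm$values)))
  colnames(scores) <- names(markers)
  best <- max.col(scores, ties.method = "first")
  n_ties <- sum(vapply(seq_len(nrow(scores)), function(i) {
    sum(scores[i, ] == scores[i, best[i]]) > 1
  }, logical(1)))
  if (n_ties > 0) {
    warning(n_ties, " cell(s) had tied state scores; first state in list ",
            "order assigned")
  }
  out <- data.frame(cell_id = colnames(nm$values), scores,
                    assigned_state = names(markers)[best],
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("state_scores", class(out))
  out
}

#' Two-dimensional projection of cells by cell-state scores
#'
#' The vertical axis contrasts the astrocyte/mesenchymal-like programs with
#' the progenitor-like programs; the horizontal axis resolves the dominant
#' pair:
#' `Y = max(S_AC, S_MES1, S_MES2) - max(S_OPC, S_NPC1, S_NPC2)`;
#' if `Y > 0`, `X = S_AC - max(S_MES1, S_MES2)`, otherwise
#' `X = S_OPC - max(S_NPC1, S_NPC2)`. Cycling scores do not enter the
#' projection.
#'
#' @param ss a [score_states()] result containing columns `AC`, `MES1`,
#'   `MES2`, `OPC`, `NPC1`, `NPC2`
#' @return data.frame `cell_id`, `X`, `Y`
#' @export
project_states_2d <- function(ss) {
  need <- c("AC", "MES1", "MES2", "OPC", "NPC1", "NPC2")
  if (!all(need %in% names(ss))) {
    stop("state scores must include: ", paste(need, collapse = ", "))
  }
  y <- pmax(ss$AC, ss$MES1, ss$MES2) - pmax(ss$OPC, ss$NPC1, ss$NPC2)
  x <- ifelse(y > 0,
              ss$AC - pmax(ss$MES1, ss$MES2),
              ss$OPC - pmax(ss$NPC1, ss$NPC2))
  data.frame(cell_id = ss$cell_id, X = x, Y = y, stringsAsFactors = FALSE)
}

#' Median cell-type score per cluster
#'
#' @param scores cells x types matrix (or data.frame) of per-cell type
#'   scores
#' @param clusters per-cell cluster labels aligned with the rows of
#'   `scores`
#' @return types x clusters matrix of medians
#' @export
cluster_median_scores <- function(scores, clusters) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(clusters))
  cl <- sort(unique(as.character(clusters)))
  out <- sapply(cl, function(j) {
    apply(scores[as.character(clusters) == j, , drop = FALSE], 2,
          stats::median)
  })
  out <- matrix(out, nrow = ncol(scores),
                dimnames = list(colnames(scores), cl))
  out
}

#' Assign clusters to malignant or non-malignant cell types
#'
#' For every non-malignant type `i` and cluster `j` the non-malignant score
#' is `NMS_ij = S_ij - S_mj` (the type's median score minus the malignant
#' median score in that cluster). A cluster is assigned to its best
#' non-malignant type (largest NMS) when that NMS exceeds
#' `median(NMS) + MAD(NMS)` over all type/cluster combinations (scaled MAD,
#' constant 1.4826); otherwise the cluster is malignant. When several types
#' clear the threshold the largest NMS wins. An `override` map can force
#' labels for specific clusters (e.g. after an orthogonal copy-number
#' check).
#'
#' @param S types x clusters matrix of median scores
#'   ([cluster_median_scores()]) including the malignant row
#' @param malignant rowname of the malignant type, default `"malignant"`
#' @param override optional named character vector `cluster -> type` applied
#'   after the rule
#' @return named character vector mapping cluster to assigned type;
#'   attribute `nms` carries the NMS matrix and `threshold` the cutoff
#' @export
assign_cluster_types <- function(S, malignant = "malignant",
                                 override = NULL) {
  stopifnot(malignant %in% rownames(S))
  if (ncol(S) < 2) {
    warning("fewer than 2 clusters: MAD threshold is degenerate")
  }
  nms <- sweep(S[setdiff(rownames(S), malignant), , drop = FALSE], 2,
               S[malignant, ], `-`)
  thr <- stats::median(nms) + stats::mad(nms)
  best <- apply(nms, 2, which.max)
  assigned <- ifelse(nms[cbind(best, seq_len(ncol(nms)))] > thr,
                     rownames(nms)[best], malignant)
  names(assigned) <- colnames(S)
  if (!is.null(override)) {
    assigned[names(override)] <- override
  }
  attr(assigned, "nms") <- nms
  attr(assigned, "threshold") <- thr
  assigned
}
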