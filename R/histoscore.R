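#' Weighted immunohistochemistry histoscore
#'
#' Staining intensity of each cell is rated 0 (negative), 1 (low),
#' 2 (moderate) or 3 (high); the weighted histoscore of a specimen is the
#' rating-weighted sum of the percentage of cells at each rating,
#' `sum(r * P_r)`, ranging from 0 (no cell stains) to 300 (all cells rate
#' 3).
#'
#' @param p percentages of cells at ratings 0, 1, 2, 3 (length 4,
#'   non-negative, summing to 100 within 1e-9). With `fractions = TRUE`,
#'   fractions summing to 1 are accepted and rescaled.
#' @param fractions interpret `p` as fractions instead of percentages
#' @return the histoscore in `[0, 300]`
#' @export
weighted_histoscore <- function(p, fractions = FALSE) {
  if (length(p) != 4) stop("need percentages for ratings 0, 1, 2, 3")
  if (any(p < 0)) stop("rating percentages must be non-negative")
  if (fractions) p <- p * 100
  if (abs(sum(p) - 100) > 1e-9) {
    stop(sprintf("rating percentages must sum to 100 (got %.6g)", sum(p)))
  }
  sum((0:3) * p)
}

#' Histoscore from per-cell staining ratings
#'
#' Tabulates integer ratings 0-3 into a rating distribution and applies
#' [weighted_histoscore()].
#'
#' @param ratings integer vector of per-cell ratings in `0:3`
#' @return the histoscore in `[0, 300]`
#' @export
histoscore_from_cells <- function(ratings) {
  if (!length(ratings)) stop("no ratings given")
  if (any(!ratings %in% 0:3)) stop("ratings must be integers 0-3")
  p <- as.numeric(table(factor(ratings, levels = 0:3))) / length(ratings)
  weighted_histoscore(p, fractions = TRUE)
}
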