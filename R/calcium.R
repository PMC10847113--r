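# Functional coactivity from calcium fluorescence traces: smoothing, peak
# detection, distance/speed-constrained lagged correlation, linear-shift
# null, threshold calibration, coactivity graph.

#' Parameters for the calcium coactivity analysis
#'
#' @param sigma_smooth_s Gaussian smoothing sd in seconds (peak detection
#'   only; correlations run on raw traces)
#' @param min_peaks minimum peak count for a cell to be "active"
#' @param max_dist_um maximum cell-pair distance considered (um)
#' @param speed_min,speed_max admissible signal propagation speeds (um/s);
#'   together with the distance they bound the admissible lag range
#'   (`|tau|` between `d/speed_max` and `d/speed_min`; at most
#'   `max_dist_um / speed_min` seconds)
#' @param segment_s correlation segment length in seconds (default 600 =
#'   10 min)
#' @param stride_s stride of the sliding segment start (s)
#' @param null_min_shift_s minimum linear time shift of the null control (s)
#' @param threshold_percentile percentile of the null correlations used as
#'   the coactivity threshold
#' @param n_null_draws null draws per eligible pair
#' @param peak_sel peak prominence threshold; `NULL` (default) uses a
#'   quarter of the smoothed trace's range
#' @param seed RNG seed for the null draws
#' @return a `coactivity_params` list
#' @export
coactivity_params <- function(sigma_smooth_s = 10, min_peaks = 4,
                              max_dist_um = 100, speed_min = 4,
                              speed_max = 25, segment_s = 600,
                              stride_s = 30, null_min_shift_s = 300,
                              threshold_percentile = 95, n_null_draws = 1,
                              peak_sel = NULL, seed = 1L) {
  stopifnot(speed_min < speed_max, segment_s > 0, stride_s > 0,
            threshold_percentile > 0, threshold_percentile <= 100,
            n_null_draws >= 1)
  structure(as.list(environment()), class = "coactivity_params")
}

#' Maximum admissible lag implied by the distance and speed cutoffs
#'
#' @param params a [coactivity_params()]
#' @return `max_dist_um / speed_min` in seconds (25 s at the defaults)
#' @export
max_admissible_lag_s <- function(params = coactivity_params()) {
  params$max_dist_um / params$speed_min
}

# Gaussian smoothing with truncated, renormalized kernel (radius 4 sd).
gaussian_smooth <- function(x, sigma_frames) {
  if (sigma_frames <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma_frames))
  k <- stats::dnorm(seq(-r, r), sd = sigma_frames)
  n <- length(x)
  num <- stats::filter(c(rep(0, r), x, rep(0, r)), k, sides = 2)
  den <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k, sides = 2)
  as.numeric(num)[r + seq_len(n)] / as.numeric(den)[r + seq_len(n)]
}

# Local maxima with prominence >= sel. Prominence of a peak: height above
# the higher of the two lowest points separating it from higher terrain
# (or the trace edge).
find_peaks <- function(x, sel) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  keep <- vapply(cand, function(p) {
    left <- if (p > 1) rev(x[1:(p - 1)]) else numeric(0)
    right <- if (p < n) x[(p + 1):n] else numeric(0)
    base <- function(side) {
      if (!length(side)) return(x[p])
      higher <- which(side > x[p])
      if (length(higher)) min(side[1:higher[1]]) else min(side)
    }
    prom <- x[p] - max(base(left), base(right))
    prom >= sel
  }, logical(1))
  cand[keep]
}

#' Smooth traces and detect calcium peaks
#'
#' Smooths each trace with a Gaussian filter (sd `sigma_smooth_s`,
#' converted to frames) and detects local maxima whose prominence is at
#' least `peak_sel` (default: a quarter of the smoothed trace's range). A
#' cell is active when it has at least `min_peaks` peaks.
#'
#' @param rec a `CalciumRecording`
#' @param params a [coactivity_params()]
#' @return list with `cells` (data.frame `cell_id`, `n_peaks`, `active`),
#'   `peak_times` (list of peak times in seconds per cell) and `smoothed`
#'   (cells x frames matrix)
#' @export
smooth_and_detect_peaks <- function(rec, params = coactivity_params()) {
  stopifnot(inherits(rec, "CalciumRecording"))
  dt <- rec$frame_interval_s
  bad <- rownames(rec$traces)[apply(rec$traces, 1, function(x) any(!is.finite(x)))]
  if (length(bad)) {
    stop("trace of cell '", bad[1], "' contains non-finite values")
  }
  sigma_frames <- params$sigma_smooth_s / dt
  sm <- t(apply(rec$traces, 1, gaussian_smooth, sigma_frames = sigma_frames))
  dimnames(sm) <- dimnames(rec$traces)
  peak_times <- lapply(rownames(sm), function(id) {
    x <- sm[id, ]
    sel <- params$peak_sel %||% ((max(x) - min(x)) / 4)
    if (sel <= 0) return(numeric(0))  # flat trace
    (find_peaks(x, sel) - 1) * dt
  })
  names(peak_times) <- rownames(sm)
  n_peaks <- lengths(peak_times)
  list(
    cells = data.frame(cell_id = rownames(sm), n_peaks = as.integer(n_peaks),
                       active = n_peaks >= params$min_peaks,
                       stringsAsFactors = FALSE, row.names = NULL),
    peak_times = peak_times,
    smoothed = sm
  )
}

#' Admissible lags for a cell pair at a given distance
#'
#' The speed window `[speed_min, speed_max]` translates a pair distance `d`
#' into admissible absolute lags `|tau|` in `[d / speed_max, d / speed_min]`
#' seconds, discretized to whole frames with the bounds rounded inward.
#' Lag 0 is excluded (it would imply infinite propagation speed). Pairs
#' farther apart than `max_dist_um` get an empty set.
#'
#' @param distance_um pair distance (> 0)
#' @param params a [coactivity_params()]
#' @param frame_interval_s seconds per frame
#' @return numeric vector of admissible lags in seconds (both signs,
#'   increasing); attribute `frames` carries the integer frame shifts
#' @export
admissible_lags <- function(distance_um, params = coactivity_params(),
                            frame_interval_s = 1.52) {
  if (distance_um <= 0) stop("distance must be positive")
  empty <- structure(numeric(0), frames = integer(0))
  if (distance_um > params$max_dist_um) return(empty)
  dt <- frame_interval_s
  lo <- ceiling(distance_um / params$speed_max / dt - 1e-9)
  hi <- floor(distance_um / params$speed_min / dt + 1e-9)
  lo <- max(lo, 1)
  if (lo > hi) return(empty)
  frames <- c(-(hi:lo), lo:hi)
  structure(frames * dt, frames = as.integer(frames))
}

#' Best lagged Pearson correlation between two traces
#'
#' Shifts trace `a` forwards and backwards by each admissible lag, slides a
#' segment of `segment_s` seconds over the recording in `stride_s` strides,
#' and returns the maximum Pearson correlation over all (lag, segment)
#' combinations together with its lag and segment start. Zero-variance
#' segments are skipped; if every combination is skipped the result is
#' flagged `undefined`.
#'
#' @param a,b numeric traces of equal length
#' @param lags admissible lag set from [admissible_lags()]
#' @param params a [coactivity_params()]
#' @param frame_interval_s seconds per frame
#' @param b_offset_frames internal: circular shift applied to `b` before
#'   correlating (used by the null control)
#' @return list `rho_max`, `tau_star_s`, `segment_start_s`, `undefined`
#' @export
best_lagged_correlation <- function(a, b, lags,
                                    params = coactivity_params(),
                                    frame_interval_s = 1.52,
                                    b_offset_frames = 0L) {
  stopifnot(length(a) == length(b))
  if (!length(lags)) stop("empty lag set")
  dt <- frame_interval_s
  n <- length(a)
  if (b_offset_frames != 0) {
    shift <- ((seq_len(n) - 1 + b_offset_frames) %% n) + 1
    b <- b[shift]
  }
  L <- floor(params$segment_s / dt)
  if (L > n) stop("recording shorter than the correlation segment")
  stride <- max(1L, as.integer(round(params$stride_s / dt)))
  starts <- seq(1L, n - L + 1L, by = stride)
  frames <- attr(lags, "frames") %||% as.integer(round(lags / dt))

  best <- list(rho_max = -Inf, tau_star_s = NA_real_,
               segment_start_s = NA_real_, undefined = TRUE)
  for (tau in frames) {
    for (s in starts) {
      i <- s:(s + L - 1L)
      ia <- i - tau
      if (ia[1] < 1 || ia[L] > n) next
      xa <- a[ia]; xb <- b[i]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
      r <- stats::cor(xa, xb)
      if (r > best$rho_max) {
        best <- list(rho_max = r, tau_star_s = tau * dt,
                     segment_start_s = (s - 1) * dt, undefined = FALSE)
      }
    }
  }
  if (best$undefined) best$rho_max <- NA_real_
  best
}

eligible_pairs <- function(rec, active_ids, params) {
  pos <- rec$positions
  d <- as.matrix(stats::dist(pos[, c("x_um", "y_um")]))
  dimnames(d) <- list(pos$cell_id, pos$cell_id)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(a = pos$cell_id[idx[, 1]], b = pos$cell_id[idx[, 2]],
                    distance_um = d[idx], stringsAsFactors = FALSE)
  out <- out[out$a %in% active_ids & out$b %in% active_ids &
               out$distance_um <= params$max_dist_um &
               out$distance_um > 0, , drop = FALSE]
  keep <- vapply(out$distance_um, function(dd) {
    length(admissible_lags(dd, params, rec$frame_interval_s)) > 0
  }, logical(1))
  out[keep, , drop = FALSE]
}

#' Null correlation sample by the linear-shift method
#'
#' Repeats the best-lagged-correlation pipeline for every eligible pair,
#' but with trace `b` circularly shifted by a random offset larger than
#' `null_min_shift_s`, so that true propagated coactivity cannot align
#' while each trace's autocorrelation is preserved.
#'
#' @param rec a `CalciumRecording`
#' @param active_ids cell ids that passed the activity filter
#' @param params a [coactivity_params()] (seed controls the draws)
#' @return numeric vector of null `rho_max` values (one per pair per draw);
#'   attribute `shifts_s` records the shifts used
#' @export
null_correlations <- function(rec, active_ids,
                              params = coactivity_params()) {
  pairs <- eligible_pairs(rec, active_ids, params)
  dt <- rec$frame_interval_s
  n <- ncol(rec$traces)
  min_shift <- ceiling(params$null_min_shift_s / dt)
  if (min_shift >= n) stop("recording too short for the null shift")
  with_seed(params$seed, {
    rhos <- numeric(0)
    shifts <- numeric(0)
    for (k in seq_len(params$n_null_draws)) {
      for (i in seq_len(nrow(pairs))) {
        off <- sample(min_shift:(n - 1), 1) * sample(c(-1L, 1L), 1)
        lags <- admissible_lags(pairs$distance_um[i], params, dt)
        r <- best_lagged_correlation(
          rec$traces[pairs$a[i], ], rec$traces[pairs$b[i], ], lags,
          params, dt, b_offset_frames = off
        )
        rhos <- c(rhos, r$rho_max)
        shifts <- c(shifts, off * dt)
      }
    }
    structure(rhos[!is.na(rhos)], shifts_s = shifts)
  })
}

#' Coactivity threshold from the null sample
#'
#' @param null_rhos null correlations from [null_correlations()]
#' @param percentile percentile (0-100], default 95
#' @return the linear-interpolation (type 7) percentile of the null sample
#' @export
coactivity_threshold <- function(null_rhos, percentile = 95) {
  if (!length(null_rhos)) stop("empty null sample")
  stats::quantile(null_rhos, percentile / 100, type = 7, names = FALSE)
}

#' Build the coactivity graph of a recording
#'
#' Runs the full pipeline: peak detection and activity filter, pair
#' eligibility (distance and speed exclusions), best lagged correlation per
#' pair, null calibration, thresholding at the null's
#' `threshold_percentile`, and per-cell functional degree.
#'
#' @param rec a `CalciumRecording`
#' @param params a [coactivity_params()]
#' @return a `CoactivityResult`: list with `pairs` (data.frame `a`, `b`,
#'   `distance_um`, `rho_max`, `tau_star_s`, `coactive`), `threshold`,
#'   `null_rhos`, `cells` (`cell_id`, `n_peaks`, `active`, `degree`), and
#'   the `params` used
#' @export
build_coactivity_graph <- function(rec, params = coactivity_params()) {
  pk <- smooth_and_detect_peaks(rec, params)
  active_ids <- pk$cells$cell_id[pk$cells$active]
  pairs <- eligible_pairs(rec, active_ids, params)
  dt <- rec$frame_interval_s
  if (nrow(pairs)) {
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      lags <- admissible_lags(pairs$distance_um[i], params, dt)
      best_lagged_correlation(rec$traces[pairs$a[i], ],
                              rec$traces[pairs$b[i], ], lags, params, dt)
    })
    pairs$rho_max <- vapply(res, `[[`, numeric(1), "rho_max")
    pairs$tau_star_s <- vapply(res, `[[`, numeric(1), "tau_star_s")
  } else {
    pairs$rho_max <- numeric(0)
    pairs$tau_star_s <- numeric(0)
  }
  null_rhos <- if (nrow(pairs)) {
    null_correlations(rec, active_ids, params)
  } else numeric(0)
  threshold <- if (length(null_rhos)) {
    coactivity_threshold(null_rhos, params$threshold_percentile)
  } else NA_real_
  pairs$coactive <- !is.na(pairs$rho_max) & !is.na(threshold) &
    pairs$rho_max > threshold
  degree <- table(factor(
    c(pairs$a[pairs$coactive], pairs$b[pairs$coactive]),
    levels = pk$cells$cell_id
  ))
  cells <- pk$cells
  cells$degree <- as.integer(degree[cells$cell_id])
  structure(list(pairs = pairs, threshold = threshold,
                 null_rhos = null_rhos, cells = cells, params = params),
            class = "CoactivityResult")
}

#' @export
print.CoactivityResult <- function(x, ...) {
  cat(sprintf(
    "CoactivityResult: %d/%d cells active, %d eligible pairs, %d coactive (threshold %.3f)\n",
    sum(x$cells$active), nrow(x$cells), nrow(x$pairs),
    sum(x$pairs$coactive), x$threshold
  ))
  invisible(x)
}

#' Group cells by extreme calcium activity
#'
#' Ranks cells by peak count and labels the lowest `ceiling(frac * n)` as
#' `bottom`, the highest as `top`, and a centered window of the same size
#' around the median rank as `middle`; everything else is `none`. Ties at a
#' group boundary expand the group (all cells with the boundary count are
#' included). Groups are disjoint, with priority bottom, top, middle.
#'
#' @param peak_counts named integer vector of per-cell peak counts
#' @param frac group size as a fraction of cells, default 0.05
#' @return named factor with levels `bottom`, `middle`, `top`, `none`
#' @export
activity_percentile_groups <- function(peak_counts, frac = 0.05) {
  stopifnot(frac > 0, frac < 0.5)
  n <- length(peak_counts)
  k <- ceiling(frac * n)
  srt <- sort(peak_counts)
  bottom <- peak_counts <= srt[k]
  top <- peak_counts >= srt[n - k + 1] & !bottom
  mid_start <- floor((n - k) / 2) + 1
  mid_lo <- srt[mid_start]; mid_hi <- srt[mid_start + k - 1]
  middle <- peak_counts >= mid_lo & peak_counts <= mid_hi & !bottom & !top
  lab <- rep("none", n)
  lab[middle] <- "middle"; lab[top] <- "top"; lab[bottom] <- "bottom"
  factor(stats::setNames(lab, names(peak_counts)),
         levels = c("bottom", "middle", "top", "none"))
}
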