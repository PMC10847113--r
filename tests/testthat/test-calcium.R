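test_that("peak detection finds planted transients and applies the activity rule", {
  dt <- 1.52
  # flat trace: no peaks
  flat <- calcium_recording(
    matrix(0, 1, 800, dimnames = list("cellA", NULL)),
    data.frame(cell_id = "cellA", x_um = 0, y_um = 0), dt
  )
  pk <- smooth_and_detect_peaks(flat)
  expect_equal(pk$cells$n_peaks, 0L)
  expect_false(pk$cells$active)

  # well-separated transients at known times; oracle recomputes the
  # systematic peak shift of the asymmetric kernel under smoothing by
  # brute-force argmax of a single numerically smoothed transient
  mk_trace <- function(ev_times, n = 800) {
    t_frames <- (seq_len(n) - 1) * dt
    Reduce(`+`, lapply(ev_times, function(te) {
      glioconnect:::ca_kernel(t_frames - te, amplitude = 5, width_s = 5)
    }))
  }
  single <- glioconnect:::gaussian_smooth(mk_trace(400), 10 / dt)
  shift_s <- (which.max(single) - 1) * dt - 400

  ev5 <- c(120, 300, 500, 700, 950)
  rec5 <- calcium_recording(
    matrix(mk_trace(ev5), 1, 800, dimnames = list("cellA", NULL)),
    data.frame(cell_id = "cellA", x_um = 0, y_um = 0), dt
  )
  pk5 <- smooth_and_detect_peaks(rec5)
  expect_equal(pk5$cells$n_peaks, 5L)
  expect_true(pk5$cells$active)
  expect_true(all(abs(pk5$peak_times[[1]] - (ev5 + shift_s)) <= dt))

  # three transients: below the four-peak activity bar
  rec3 <- calcium_recording(
    matrix(mk_trace(c(200, 500, 800)), 1, 800,
           dimnames = list("cellA", NULL)),
    data.frame(cell_id = "cellA", x_um = 0, y_um = 0), dt
  )
  pk3 <- smooth_and_detect_peaks(rec3)
  expect_equal(pk3$cells$n_peaks, 3L)
  expect_false(pk3$cells$active)

  # NaN traces are rejected with the cell named
  bad <- rec5
  bad$traces[1, 10] <- NaN
  expect_error(smooth_and_detect_peaks(bad), "cellA")
})

test_that("admissible lags respect the distance and speed window", {
  p <- coactivity_params()
  expect_equal(max_admissible_lag_s(p), 25)

  l100 <- admissible_lags(100, p, 1.52)
  expect_true(all(abs(l100) <= 25))
  expect_true(all(abs(l100) >= 100 / 25))
  expect_true(all(attr(l100, "frames") != 0))
  expect_true(setequal(l100, -l100))  # symmetric in sign

  l50 <- admissible_lags(50, p, 1.52)
  expect_true(all(abs(l50) >= 2 & abs(l50) <= 12.5))

  expect_length(admissible_lags(120, p, 1.52), 0)  # beyond 100 um
  expect_error(admissible_lags(0, p, 1.52), "positive")
})

test_that("a delayed copy is recovered at its lag with correlation one", {
  dt <- 1.52
  set.seed(33)
  base <- simulate_calcium_recording(
    ca_sim_config(n_cells = 2, edge_prob = 0, base_rate_hz = 0.02, noise_sd = 0, seed = 3)
  )$traces[1, ]
  p <- coactivity_params()
  for (d_um in c(15, 60, 100)) {
    delay_frames <- round(d_um / 10 / dt)  # speed 10 um/s
    b <- c(rep(0, delay_frames), base)[seq_along(base)]
    lags <- admissible_lags(d_um, p, dt)
    r <- best_lagged_correlation(base, b, lags, p, dt)
    expect_gt(r$rho_max, 0.99)
    expect_lte(abs(r$tau_star_s - delay_frames * dt), dt)
  }
  # diagnostic identity: correlating a trace with itself at lag zero
  self <- best_lagged_correlation(base, base,
                                  structure(0, frames = 0L), p, dt)
  expect_equal(self$rho_max, 1)
  # rho always within [-1, 1]
  expect_true(abs(self$rho_max) <= 1)
})

test_that("zero-variance segments are skipped and can void the result", {
  p <- coactivity_params(segment_s = 100, stride_s = 50)
  a <- rep(1, 200)
  b <- rnorm(200)
  r <- best_lagged_correlation(a, b, structure(1.52, frames = 1L), p, 1.52)
  expect_true(r$undefined)
  expect_true(is.na(r$rho_max))
})

test_that("the null is seeded, shifts exceed five minutes, and matches a null recording", {
  rec <- simulate_calcium_recording(
    ca_sim_config(n_cells = 12, share_prob = 0, seed = 41)
  )
  pk <- smooth_and_detect_peaks(rec)
  act <- pk$cells$cell_id[pk$cells$active]
  p <- coactivity_params(seed = 5)
  n1 <- null_correlations(rec, act, p)
  n2 <- null_correlations(rec, act, p)
  expect_identical(n1, n2)
  expect_true(all(abs(attr(n1, "shifts_s")) > 300))

  # without propagation, empirical and null rho distributions agree
  pairs <- glioconnect:::eligible_pairs(rec, act, p)
  emp <- vapply(seq_len(nrow(pairs)), function(i) {
    lags <- admissible_lags(pairs$distance_um[i], p, rec$frame_interval_s)
    best_lagged_correlation(rec$traces[pairs$a[i], ],
                            rec$traces[pairs$b[i], ], lags, p,
                            rec$frame_interval_s)$rho_max
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(emp, n1)$p.value), 0.01)
})

test_that("the threshold is the type-7 percentile of the null", {
  expect_equal(coactivity_threshold(rep(0.3, 50)), 0.3)
  grid <- seq(0, 0.99, by = 0.01)
  expect_equal(coactivity_threshold(grid, 95), 0.9405)
  expect_equal(coactivity_threshold(grid, 95),
               unname(quantile(grid, 0.95, type = 7)))
  # non-decreasing in the percentile
  thr <- vapply(c(50, 75, 90, 95, 99), coactivity_threshold,
                numeric(1), null_rhos = grid)
  expect_true(all(diff(thr) >= 0))
})

test_that("propagation-free recordings stay near the nominal false-positive rate", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    rec <- simulate_calcium_recording(
      ca_sim_config(share_prob = 0, noise_sd = 0.2, seed = s)
    )
    res <- build_coactivity_graph(rec, coactivity_params(seed = s + 500,
                                                         n_null_draws = 3))
    hits <- hits + sum(res$pairs$coactive)
    total <- total + nrow(res$pairs)
  }
  rate <- hits / total
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("high share probability yields high edge recovery and precision", {
  # recall of direct edges and precision against shared-transient pairs,
  # pooled over recordings (a single sparse recording has too few direct
  # edges for a stable per-recording rate)
  n_rec <- 0; n_vis <- 0; n_prec <- 0; n_found <- 0
  for (s in 1:6) {
    rec <- simulate_calcium_recording(
      ca_sim_config(share_prob = 0.9, noise_sd = 0.05, seed = s)
    )
    res <- build_coactivity_graph(rec, coactivity_params(seed = s + 900))
    found <- edge_key(res$pairs$a, res$pairs$b)[res$pairs$coactive]
    direct <- edge_key(rec$truth$edges_used$a, rec$truth$edges_used$b)
    shared <- edge_key(rec$truth$shared_pairs$a, rec$truth$shared_pairs$b)
    visible_direct <- intersect(direct, edge_key(res$pairs$a, res$pairs$b))
    n_rec <- n_rec + length(intersect(found, visible_direct))
    n_vis <- n_vis + length(visible_direct)
    n_prec <- n_prec + length(intersect(found, shared))
    n_found <- n_found + length(found)
  }
  expect_gte(n_rec / n_vis, 0.8)
  expect_gte(n_prec / n_found, 0.8)
})

test_that("lag recovery stays within one frame across the distance range", {
  dt <- 1.52
  set.seed(12)
  base <- simulate_calcium_recording(
    ca_sim_config(n_cells = 2, edge_prob = 0, base_rate_hz = 0.015, noise_sd = 0, seed = 8)
  )$traces[1, ]
  p <- coactivity_params()
  for (d_um in c(8, 25, 50, 75, 100)) {
    true_delay_s <- d_um / 10
    delay_frames <- round(true_delay_s / dt)
    if (delay_frames == 0) next  # sub-frame delays cannot be represented
    b <- c(rep(0, delay_frames), base)[seq_along(base)]
    lags <- admissible_lags(d_um, p, dt)
    r <- best_lagged_correlation(base, b, lags, p, dt)
    expect_lte(abs(r$tau_star_s - delay_frames * dt), dt)
  }
})

test_that("activity groups take the extreme and middle 5 percent with tie expansion", {
  counts <- setNames(sample(1:100), sprintf("c%03d", 1:100))
  g <- activity_percentile_groups(counts)
  expect_equal(as.integer(table(g)[c("bottom", "middle", "top")]),
               c(5L, 5L, 5L))
  expect_true(all(counts[g == "bottom"] < counts[g == "middle"]))
  expect_true(all(counts[g == "middle"] < counts[g == "top"]))

  # heavy ties at the minimum expand the bottom group
  tied <- setNames(c(rep(0, 12), 13:100), sprintf("c%03d", 1:100))
  g2 <- activity_percentile_groups(tied)
  expect_equal(sum(g2 == "bottom"), 12)
  # groups are disjoint by construction (factor labels are exclusive)
  expect_true(all(table(g2) <= c(100, 100, 100, 100)))
})
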