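#' Configuration for the single-cell experiment simulator
#'
#' Defines a sorted-connectivity single-cell experiment: several "cell lines",
#' each with a highly and a lowly connected sorted group, negative-binomial
#' count background, planted connectivity genes and discrete cell states.
#'
#' The negative binomial is parameterized by mean `m` and dispersion `phi`
#' (variance `m + phi * m^2`, shared across genes).
#'
#' @param n_lines number of cell lines (sorted experiments), default 3
#' @param cells_per_group cells per sorted group per line
#' @param n_genes total genes (includes `n_mito` mitochondrial genes)
#' @param n_up,n_down numbers of planted up-/down-regulated connectivity genes
#' @param effect_size multiplicative mean shift of planted genes in their
#'   favored group (`1` = null, no differential signal)
#' @param lines_with_effect integer vector of lines in which the effect is
#'   planted (default all lines)
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for baseline
#'   gene means
#' @param dispersion NB dispersion `phi`
#' @param state_props named probabilities of the discrete cell states
#' @param markers_per_state planted marker genes per state
#' @param state_boost multiplicative mean boost of a state's markers in cells
#'   of that state
#' @param n_mito number of mitochondrial ("MT-") genes
#' @param mito_fraction expected fraction of counts from mitochondrial genes
#' @param seed RNG seed
#' @return an `sc_sim_config` list
#' @export
sc_sim_config <- function(n_lines = 3, cells_per_group = 300, n_genes = 2000,
                          n_up = 40, n_down = 31, effect_size = 3,
                          lines_with_effect = NULL,
                          baseline_meanlog = 0, baseline_sdlog = 1,
                          dispersion = 0.3,
                          state_props = c(AC = 0.22, MES1 = 0.18, MES2 = 0.10,
                                          OPC = 0.15, NPC1 = 0.15, NPC2 = 0.10,
                                          cycling = 0.10),
                          markers_per_state = 25, state_boost = 4,
                          n_mito = 10, mito_fraction = 0.05, seed = 1L) {
  stopifnot(n_lines >= 1, cells_per_group >= 1, effect_size > 0,
            dispersion > 0, abs(sum(state_props) - 1) < 1e-8)
  lines_with_effect <- lines_with_effect %||% seq_len(n_lines)
  needed <- n_up + n_down + markers_per_state * length(state_props) + n_mito
  if (needed > n_genes) {
    stop(sprintf("planted gene sets need %d genes but n_genes = %d",
                 needed, n_genes))
  }
  cfg <- as.list(environment())
  cfg$needed <- NULL
  structure(cfg, class = "sc_sim_config")
}

#' Simulate a sorted-connectivity single-cell experiment
#'
#' Draws NB counts in which planted up genes have their mean multiplied by
#' `effect_size` in the `"high"` sorted group (in the lines carrying the
#' effect) and planted down genes in the `"low"` group; state marker genes
#' are boosted in cells of their state. The generator is seed-deterministic.
#'
#' @param cfg an [sc_sim_config()]
#' @return list with elements `cm` (a [CountMatrix()] annotated with
#'   `line_id`, `group_label`, `true_state`) and `truth` (planted `up` /
#'   `down` gene sets, `state_markers` named list, per-cell `states`)
#' @export
simulate_sc_experiment <- function(cfg = sc_sim_config()) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  with_seed(cfg$seed, {
    states <- names(cfg$state_props)
    n_plain <- cfg$n_genes - cfg$n_mito
    gene_ids <- c(sprintf("gene%04d", seq_len(n_plain)),
                  sprintf("MT-%d", seq_len(cfg$n_mito)))
    up <- gene_ids[seq_len(cfg$n_up)]
    down <- gene_ids[cfg$n_up + seq_len(cfg$n_down)]
    marker_start <- cfg$n_up + cfg$n_down
    state_markers <- stats::setNames(lapply(seq_along(states), function(i) {
      gene_ids[marker_start + (i - 1) * cfg$markers_per_state +
                 seq_len(cfg$markers_per_state)]
    }), states)

    base_mean <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                               cfg$baseline_sdlog)
    names(base_mean) <- gene_ids
    # scale mito means so their expected count share is ~ mito_fraction
    is_mito <- startsWith(gene_ids, "MT-")
    tot_plain <- sum(base_mean[!is_mito])
    base_mean[is_mito] <- base_mean[is_mito] / sum(base_mean[is_mito]) *
      tot_plain * cfg$mito_fraction / (1 - cfg$mito_fraction)

    n_cells_total <- cfg$n_lines * 2 * cfg$cells_per_group
    line_id <- rep(sprintf("line%d", seq_len(cfg$n_lines)),
                   each = 2 * cfg$cells_per_group)
    group_label <- rep(rep(c("SR101high", "SR101low"),
                           each = cfg$cells_per_group), cfg$n_lines)
    cell_state <- sample(states, n_cells_total, replace = TRUE,
                         prob = cfg$state_props)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells_total))

    mu <- matrix(base_mean, nrow = cfg$n_genes, ncol = n_cells_total,
                 dimnames = list(gene_ids, cell_ids))
    line_num <- rep(seq_len(cfg$n_lines), each = 2 * cfg$cells_per_group)
    eff_line <- line_num %in% cfg$lines_with_effect
    hi <- group_label == "SR101high" & eff_line
    lo <- group_label == "SR101low" & eff_line
    mu[up, hi] <- mu[up, hi] * cfg$effect_size
    mu[down, lo] <- mu[down, lo] * cfg$effect_size
    for (s in states) {
      in_state <- cell_state == s
      if (any(in_state)) {
        mu[state_markers[[s]], in_state] <-
          mu[state_markers[[s]], in_state] * cfg$state_boost
      }
    }

    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$dispersion),
      nrow = cfg$n_genes, dimnames = dimnames(mu)
    )
    cm <- CountMatrix(
      counts,
      cell_meta = data.frame(cell_id = cell_ids, line_id = line_id,
                             group_label = group_label,
                             true_state = cell_state,
                             stringsAsFactors = FALSE)
    )
    list(cm = cm,
         truth = list(up = up, down = down, state_markers = state_markers,
                      states = stats::setNames(cell_state, cell_ids)))
  })
}

#' Configuration for the bulk experiment simulator
#'
#' Two-group bulk RNA-seq with a cell-line covariate: per-line, per-gene
#' baseline offsets create covariate signal that a group-only test would
#' confound; planted genes carry the group effect.
#'
#' @param n_lines number of cell lines, default 2
#' @param reps_per_group replicates per line x group
#' @param n_genes,n_up,n_down,effect_size,dispersion,seed as in
#'   [sc_sim_config()]
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean parameters
#'   (bulk scale)
#' @param line_sd sd (log scale) of the per-line, per-gene baseline offset;
#'   `0` disables the covariate signal
#' @return a `bulk_sim_config` list
#' @export
bulk_sim_config <- function(n_lines = 2, reps_per_group = 3, n_genes = 2000,
                            n_up = 30, n_down = 30, effect_size = 4,
                            baseline_meanlog = 4, baseline_sdlog = 1,
                            dispersion = 0.05, line_sd = 0.3, seed = 1L) {
  stopifnot(n_lines >= 1, reps_per_group >= 2, effect_size > 0,
            n_up + n_down <= n_genes, dispersion > 0, line_sd >= 0)
  structure(as.list(environment()), class = "bulk_sim_config")
}

#' Simulate a two-group bulk RNA-seq experiment with a line covariate
#'
#' @param cfg a [bulk_sim_config()]
#' @return list with `counts` (genes x samples), `sample_meta`
#'   (`sample_id`, `line_id`, `group_label`) and `truth` (`up`, `down`)
#' @export
simulate_bulk_experiment <- function(cfg = bulk_sim_config()) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  with_seed(cfg$seed, {
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    up <- gene_ids[seq_len(cfg$n_up)]
    down <- gene_ids[cfg$n_up + seq_len(cfg$n_down)]
    base_mean <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                               cfg$baseline_sdlog)
    line_factor <- matrix(
      exp(stats::rnorm(cfg$n_genes * cfg$n_lines, 0, cfg$line_sd)),
      nrow = cfg$n_genes
    )

    meta <- expand.grid(rep = seq_len(cfg$reps_per_group),
                        group_label = c("SR101high", "SR101low"),
                        line = seq_len(cfg$n_lines),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$line_id <- sprintf("line%d", meta$line)
    meta$sample_id <- sprintf("%s_%s_r%d", meta$line_id,
                              sub("SR101", "", meta$group_label), meta$rep)

    mu <- sapply(seq_len(nrow(meta)), function(j) {
      m <- base_mean * line_factor[, meta$line[j]]
      if (meta$group_label[j] == "SR101high") {
        m[match(up, gene_ids)] <- m[match(up, gene_ids)] * cfg$effect_size
      } else {
        m[match(down, gene_ids)] <- m[match(down, gene_ids)] * cfg$effect_size
      }
      m
    })
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$dispersion),
      nrow = cfg$n_genes,
      dimnames = list(gene_ids, meta$sample_id)
    )
    list(counts = counts,
         sample_meta = meta[, c("sample_id", "line_id", "group_label")],
         truth = list(up = up, down = down))
  })
}

#' Construct a CalciumRecording
#'
#' @param traces cells x frames matrix of fluorescence values, rownames =
#'   cell ids
#' @param positions data.frame `cell_id`, `x_um`, `y_um` for every cell
#' @param frame_interval_s seconds per frame, default 1.52
#' @param truth optional ground-truth list from the simulator
#' @return a `CalciumRecording`
#' @export
calcium_recording <- function(traces, positions, frame_interval_s = 1.52,
                              truth = NULL) {
  stopifnot(frame_interval_s > 0, is.matrix(traces))
  if (is.null(rownames(traces))) stop("traces must have cell-id rownames")
  if (!all(c("cell_id", "x_um", "y_um") %in% names(positions))) {
    stop("positions needs columns cell_id, x_um, y_um")
  }
  if (!setequal(positions$cell_id, rownames(traces))) {
    stop("positions must cover exactly the cells of `traces`")
  }
  positions <- positions[match(rownames(traces), positions$cell_id), ]
  rownames(positions) <- NULL
  structure(list(traces = traces, positions = positions,
                 frame_interval_s = frame_interval_s, truth = truth),
            class = "CalciumRecording")
}

#' @export
print.CalciumRecording <- function(x, ...) {
  cat(sprintf("CalciumRecording: %d cells x %d frames (%.2f s/frame, %.1f min)\n",
              nrow(x$traces), ncol(x$traces), x$frame_interval_s,
              ncol(x$traces) * x$frame_interval_s / 60))
  invisible(x)
}

#' Configuration for the calcium recording simulator
#'
#' Cells on a 2D field fire calcium transients; a transient propagates across
#' each connection-graph edge with probability `share_prob`, arriving after
#' `distance / speed` seconds. Transients are asymmetric: half-Gaussian rise,
#' exponential decay.
#'
#' @param n_cells number of cells
#' @param field_um side length of the square field (um)
#' @param frame_interval_s seconds per frame (default 1.52)
#' @param duration_s recording length in seconds (default 1800 = 30 min);
#'   must be at least 600 s (the correlation segment length)
#' @param conn_radius_um maximum distance of a graph edge (um)
#' @param edge_prob probability that an eligible pair is connected; the
#'   default yields on the order of two connections per cell, the low
#'   per-cell connection counts typical of in vitro TM networks
#' @param speed_um_s propagation speed, must lie in `[4, 25]` um/s
#' @param amplitude,width_s transient kernel amplitude and width (s); the
#'   rise is half-Gaussian with sd `width_s / 3`, the decay exponential with
#'   time constant `width_s`
#' @param base_rate_hz spontaneous event rate per cell (1/s)
#' @param share_prob probability a transient propagates across an edge
#' @param noise_sd sd of additive Gaussian trace noise
#' @param seed RNG seed
#' @return a `ca_sim_config` list
#' @export
ca_sim_config <- function(n_cells = 30, field_um = 300,
                          frame_interval_s = 1.52, duration_s = 1800,
                          conn_radius_um = 100, edge_prob = 0.25,
                          speed_um_s = 10, amplitude = 5, width_s = 5,
                          base_rate_hz = 0.01, share_prob = 0.7,
                          noise_sd = 0.2, seed = 1L) {
  stopifnot(n_cells >= 2, frame_interval_s > 0,
            speed_um_s >= 4, speed_um_s <= 25,
            share_prob >= 0, share_prob <= 1, noise_sd >= 0)
  if (duration_s < 600) {
    stop("duration_s must be at least 600 s (the 10-min segment length)")
  }
  structure(as.list(environment()), class = "ca_sim_config")
}

# transient kernel evaluated at u = t - event_time (vectorized)
ca_kernel <- function(u, amplitude, width_s) {
  out <- numeric(length(u))
  rise <- u <= 0
  out[rise] <- amplitude * exp(-u[rise]^2 / (2 * (width_s / 3)^2))
  out[!rise] <- amplitude * exp(-u[!rise] / width_s)
  out
}

#' Simulate a calcium-imaging recording with propagating transients
#'
#' @param cfg a [ca_sim_config()]
#' @return a `CalciumRecording` whose `truth` holds per-cell event times
#'   (`events`), the connection graph (`edges`: data.frame `a`, `b`,
#'   `distance_um`), the edges that actually carried a propagated event
#'   (`edges_used`), the pairs that share at least one transient instance
#'   (`shared_pairs`, including common-source pairs two steps apart in the
#'   graph, with the number of shared transients `n_shared`), and the config
#' @export
simulate_calcium_recording <- function(cfg = ca_sim_config()) {
  stopifnot(inherits(cfg, "ca_sim_config"))
  with_seed(cfg$seed, {
    ids <- sprintf("cell%02d", seq_len(cfg$n_cells))
    pos <- data.frame(cell_id = ids,
                      x_um = stats::runif(cfg$n_cells, 0, cfg$field_um),
                      y_um = stats::runif(cfg$n_cells, 0, cfg$field_um),
                      stringsAsFactors = FALSE)
    d <- as.matrix(stats::dist(pos[, c("x_um", "y_um")]))
    pairs <- which(upper.tri(d) & d <= cfg$conn_radius_um, arr.ind = TRUE)
    if (nrow(pairs)) {
      keep <- stats::runif(nrow(pairs)) < cfg$edge_prob
      pairs <- pairs[keep, , drop = FALSE]
    }
    edges <- data.frame(a = ids[pairs[, 1]], b = ids[pairs[, 2]],
                        distance_um = d[pairs], stringsAsFactors = FALSE)

    # spontaneous events; each carries an origin id so that ground truth can
    # record which cell pairs end up sharing the same transient
    events <- lapply(seq_len(cfg$n_cells), function(i) {
      n_ev <- stats::rpois(1, cfg$base_rate_hz * cfg$duration_s)
      stats::runif(n_ev, 0, cfg$duration_s)
    })
    origins <- lapply(seq_len(cfg$n_cells), function(i) {
      if (length(events[[i]])) sprintf("%d.%d", i, seq_along(events[[i]]))
      else character(0)
    })
    names(events) <- names(origins) <- ids

    # one-hop propagation across edges (propagated copies keep their origin)
    edge_used <- rep(FALSE, nrow(edges))
    if (nrow(edges)) {
      prop_t <- lapply(seq_len(cfg$n_cells), function(i) numeric(0))
      prop_o <- lapply(seq_len(cfg$n_cells), function(i) character(0))
      for (e in seq_len(nrow(edges))) {
        i <- pairs[e, 1]; j <- pairs[e, 2]
        delay <- edges$distance_um[e] / cfg$speed_um_s
        for (dir in list(c(i, j), c(j, i))) {
          src <- dir[1]; dst <- dir[2]
          ev <- events[[src]]
          if (length(ev)) {
            go <- stats::runif(length(ev)) < cfg$share_prob
            shared_t <- ev[go] + delay
            ok <- shared_t < cfg$duration_s
            if (any(ok)) {
              prop_t[[dst]] <- c(prop_t[[dst]], shared_t[ok])
              prop_o[[dst]] <- c(prop_o[[dst]], origins[[src]][go][ok])
              edge_used[e] <- TRUE
            }
          }
        }
      }
      for (i in seq_len(cfg$n_cells)) {
        ord <- order(c(events[[i]], prop_t[[i]]))
        origins[[i]] <- c(origins[[i]], prop_o[[i]])[ord]
        events[[i]] <- c(events[[i]], prop_t[[i]])[ord]
      }
    } else {
      events <- lapply(events, sort)
    }

    # pairs that genuinely share transients (same origin event in both)
    shared_pairs <- do.call(rbind, lapply(seq_len(cfg$n_cells - 1), function(i) {
      do.call(rbind, lapply((i + 1):cfg$n_cells, function(j) {
        n_shared <- length(intersect(origins[[i]], origins[[j]]))
        if (n_shared > 0) {
          data.frame(a = ids[i], b = ids[j], n_shared = n_shared,
                     stringsAsFactors = FALSE)
        } else NULL
      }))
    }))
    if (is.null(shared_pairs)) {
      shared_pairs <- data.frame(a = character(), b = character(),
                                 n_shared = integer())
    }

    n_frames <- floor(cfg$duration_s / cfg$frame_interval_s)
    t_frames <- (seq_len(n_frames) - 1) * cfg$frame_interval_s
    traces <- matrix(0, nrow = cfg$n_cells, ncol = n_frames,
                     dimnames = list(ids, NULL))
    for (i in seq_len(cfg$n_cells)) {
      tr <- numeric(n_frames)
      for (te in events[[i]]) {
        tr <- tr + ca_kernel(t_frames - te, cfg$amplitude, cfg$width_s)
      }
      traces[i, ] <- tr
    }
    if (cfg$noise_sd > 0) {
      traces <- traces + matrix(stats::rnorm(length(traces), 0, cfg$noise_sd),
                                nrow = cfg$n_cells)
    }
    calcium_recording(
      traces, pos, cfg$frame_interval_s,
      truth = list(events = events, edges = edges,
                   edges_used = edges[edge_used, , drop = FALSE],
                   shared_pairs = shared_pairs, config = cfg)
    )
  })
}

#' Simulate per-cell immunohistochemistry staining ratings
#'
#' Multinomial draws of staining-intensity ratings 0 (negative) to 3 (high).
#'
#' @param n_cells number of rated cells
#' @param rating_probs probabilities of ratings 0, 1, 2, 3 (length 4,
#'   summing to 1)
#' @param seed RNG seed
#' @return data.frame with `cell_id` and integer `rating`
#' @export
simulate_histology <- function(n_cells, rating_probs = c(.25, .25, .25, .25),
                               seed = 1L) {
  stopifnot(n_cells >= 1, length(rating_probs) == 4,
            all(rating_probs >= 0), abs(sum(rating_probs) - 1) < 1e-8)
  with_seed(seed, {
    data.frame(
      cell_id = sprintf("cell%06d", seq_len(n_cells)),
      rating = sample(0:3, n_cells, replace = TRUE, prob = rating_probs),
      stringsAsFactors = FALSE
    )
  })
}
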