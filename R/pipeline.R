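# End-to-end orchestration: simulate/load -> QC -> normalize -> per-line DEG
# -> signature aggregation -> scoring -> classification -> evaluation, plus
# the calcium coactivity pipeline. Configs are plain lists (optionally from
# YAML); reports are machine-readable JSON.

#' Pipeline configuration
#'
#' Collects stage toggles and per-stage parameter blocks. A single global
#' seed fans out to deterministic per-stage seeds, so toggling one stage
#' does not change another stage's draws.
#'
#' @param seed global seed
#' @param out_dir output directory for reports and tables (`NULL`: nothing
#'   written)
#' @param sc an [sc_sim_config()] (its seed is overridden by the derived
#'   stage seed)
#' @param score a [module_score_params()]
#' @param coactivity a [coactivity_params()]
#' @param ca_sim a [ca_sim_config()]
#' @param stages named logical toggles: `derive`, `calcium`
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            sc = sc_sim_config(),
                            score = module_score_params(),
                            coactivity = coactivity_params(),
                            ca_sim = ca_sim_config(),
                            stages = c(derive = TRUE, calcium = TRUE)) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, sc = sc,
                 score = score, coactivity = coactivity, ca_sim = ca_sim,
                 stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `seed`, `out_dir`, `stages`, and parameter
#' blocks `sc`, `score`, `coactivity`, `ca_sim` whose entries override the
#' corresponding constructor defaults.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path)) {
    stop("config file not found: '", path, "'")
  }
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, block %||% list())
  stages <- c(derive = TRUE, calcium = TRUE)
  if (!is.null(y$stages)) stages[names(y$stages)] <- unlist(y$stages)
  pipeline_config(
    seed = y$seed %||% 1L, out_dir = y$out_dir,
    sc = build(sc_sim_config, y$sc),
    score = build(module_score_params, y$score),
    coactivity = build(coactivity_params, y$coactivity),
    ca_sim = build(ca_sim_config, y$ca_sim),
    stages = stages
  )
}

pipeline_report_skeleton <- function(cfg) {
  hashed <- unclass(cfg)
  hashed$out_dir <- NULL  # analysis identity is independent of output paths
  list(
    tool = "glioconnect",
    version = as.character(utils::packageVersion("glioconnect")),
    seed = cfg$seed,
    config_hash = rlang::hash(hashed)
  )
}

write_report <- function(report, cfg, file) {
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the signature-derivation pipeline on simulated data
#'
#' Simulates a sorted single-cell experiment, applies QC and normalization,
#' runs per-line marker tests, aggregates the connectivity signature,
#' scores and classifies every cell, and evaluates the prediction against
#' the planted sorted labels. Deterministic for a fixed config.
#'
#' @param cfg a [pipeline_config()]
#' @return the report list (also written to
#'   `<out_dir>/derivation_report.json` when `out_dir` is set), with the
#'   derived signature, per-rule QC counts, signature sizes, confusion
#'   metrics and a parameter echo
#' @export
run_derivation_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!isTRUE(cfg$stages[["derive"]])) {
    return(write_report(pipeline_report_skeleton(cfg), cfg,
                        "derivation_report.json"))
  }
  sc_cfg <- cfg$sc
  sc_cfg$seed <- derive_seed(cfg$seed, 1L)
  sim <- run_stage("simulate", simulate_sc_experiment(sc_cfg))

  cm <- run_stage("qc", qc_filter_fixed(sim$cm))
  qc <- attr(cm, "qc_summary")
  nm <- run_stage("normalize", lognormalize(cm))

  lines <- unique(nm$cell_meta$line_id)
  tables <- run_stage("markers", lapply(lines, function(l) {
    in_line <- nm$cell_meta$line_id == l
    a <- nm$cell_meta$cell_id[in_line & nm$cell_meta$group_label == "SR101high"]
    b <- nm$cell_meta$cell_id[in_line & nm$cell_meta$group_label == "SR101low"]
    rank_sum_markers(nm, a, b)
  }))
  sig <- run_stage("aggregate", aggregate_sc_signature(tables))

  score_par <- module_score_params(cfg$score$n_bins, cfg$score$n_ctrl,
                                   derive_seed(cfg$seed, 2L))
  cs <- run_stage("score", connectivity_score(nm, sig, score_par))
  pred <- predict_connectivity(cs)
  truth <- stats::setNames(
    ifelse(nm$cell_meta$group_label == "SR101high", "high", "low"),
    nm$cell_meta$cell_id
  )
  metrics <- run_stage("evaluate", confusion_metrics(pred, truth))

  report <- c(pipeline_report_skeleton(cfg), list(
    qc = qc,
    n_cells = length(pred),
    signature = list(name = sig$name, n_up = length(sig$up),
                     n_down = length(sig$down),
                     jaccard_vs_planted = jaccard(
                       union(sig$up, sig$down),
                       union(sim$truth$up, sim$truth$down)
                     )),
    metrics = metrics[c("accuracy", "sensitivity", "specificity",
                        "ppv", "npv")],
    params = list(sc = unclass(sc_cfg), score = unclass(score_par))
  ))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_signature_tsv(sig, file.path(cfg$out_dir, "signature.tsv"))
    utils::write.table(cbind(cs, predicted = pred[cs$cell_id]),
                       file.path(cfg$out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_report(report, cfg, "derivation_report.json")
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Run the calcium coactivity pipeline on simulated data
#'
#' Simulates a recording with a known connection graph, builds the
#' coactivity graph, and reports edge recovery (precision/recall against
#' the true edges that carried propagated events).
#'
#' @param cfg a [pipeline_config()]
#' @return the report list (also written to
#'   `<out_dir>/calcium_report.json` when `out_dir` is set)
#' @export
run_calcium_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!isTRUE(cfg$stages[["calcium"]])) {
    return(write_report(pipeline_report_skeleton(cfg), cfg,
                        "calcium_report.json"))
  }
  ca_cfg <- cfg$ca_sim
  ca_cfg$seed <- derive_seed(cfg$seed, 3L)
  rec <- run_stage("simulate", simulate_calcium_recording(ca_cfg))
  co_par <- cfg$coactivity
  co_par$seed <- derive_seed(cfg$seed, 4L)
  res <- run_stage("coactivity", build_coactivity_graph(rec, co_par))

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  found <- edge_key(res$pairs$a, res$pairs$b)[res$pairs$coactive]
  true_edges <- edge_key(rec$truth$edges_used$a, rec$truth$edges_used$b)
  # recall judged on direct edges the analysis could see (both active, in
  # range); precision against all pairs that genuinely share transients
  # (direct edges plus common-source pairs)
  visible <- edge_key(res$pairs$a, res$pairs$b)
  true_visible <- intersect(true_edges, visible)
  shared <- edge_key(rec$truth$shared_pairs$a, rec$truth$shared_pairs$b)
  report <- c(pipeline_report_skeleton(cfg), list(
    n_cells = nrow(res$cells),
    n_active = sum(res$cells$active),
    n_pairs = nrow(res$pairs),
    n_coactive = length(found),
    threshold = res$threshold,
    recall = if (length(true_visible)) {
      length(intersect(found, true_visible)) / length(true_visible)
    } else NA_real_,
    precision = if (length(found)) {
      length(intersect(found, shared)) / length(found)
    } else NA_real_,
    params = list(ca_sim = unclass(ca_cfg), coactivity = unclass(co_par))
  ))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$pairs, file.path(cfg$out_dir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$cells, file.path(cfg$out_dir, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_report(report, cfg, "calcium_report.json")
}
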