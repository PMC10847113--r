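test_that("rank-sum p-values match stats::wilcox.test across regimes", {
  set.seed(77)
  cases <- list(
    small_noties = list(a = rnorm(6), b = rnorm(8)),
    small_ties = list(a = c(1, 2, 2, 3), b = c(2, 3, 4, 4)),
    large = list(a = rnorm(120), b = rnorm(150)),
    large_ties = list(a = rpois(80, 3), b = rpois(90, 4)),
    shifted = list(a = rnorm(30), b = rnorm(25, 1))
  )
  for (cs in cases) {
    expected <- suppressWarnings(wilcox.test(cs$a, cs$b)$p.value)
    expect_equal(glioconnect:::rank_sum_p(cs$a, cs$b), expected,
                 tolerance = 1e-12)
  }
  # fully separated small samples: exact enumeration gives 2/C(6,3) = 0.1
  expect_equal(glioconnect:::rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
})

test_that("rank_sum_markers filters, reports fold changes, and adjusts by Bonferroni", {
  vals <- rbind(
    strong  = c(3, 3.2, 3.1, 2.9, 0.2, 0.1, 0.3, 0.2),
    rare    = c(0.4, 0, 0, 0, 0, 0, 0, 0.5),   # detected in 1/4 of each group
    flat    = c(1, 1.1, 0.9, 1, 1, 1.05, 0.95, 1)
  )
  dimnames(vals) <- list(rownames(vals), sprintf("c%d", 1:8))
  nm <- toy_normalized(vals)
  a <- sprintf("c%d", 1:4); b <- sprintf("c%d", 5:8)
  tab <- rank_sum_markers(nm, a, b, min_pct = 0.3, logfc_min = 0.25)
  expect_true("strong" %in% tab$gene_id)
  expect_false("rare" %in% tab$gene_id)   # below min detection fraction
  expect_false("flat" %in% tab$gene_id)   # below fold-change bar
  row <- tab[tab$gene_id == "strong", ]
  expect_equal(row$logfc,
               log(mean(expm1(vals["strong", 1:4])) + 1) -
                 log(mean(expm1(vals["strong", 5:8])) + 1))
  expect_equal(tab$p_adj, pmin(1, tab$p * nrow(tab)))
  expect_error(rank_sum_markers(nm, a, c(b, "c1")), "overlap")
})

test_that("exchangeable groups yield no significant markers", {
  set.seed(9)
  vals <- matrix(rnorm(200 * 40, 1, 0.3), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:40)))
  vals[vals < 0] <- 0
  nm <- toy_normalized(vals)
  tab <- rank_sum_markers(nm, sprintf("c%02d", 1:20), sprintf("c%02d", 21:40),
                          min_pct = 0, logfc_min = 0)
  expect_equal(sum(tab$p_adj < 0.05), 0)
})

test_that("three-line aggregation follows the consensus and two-line rules", {
  mk <- function(genes, lfc, padj) {
    data.frame(gene_id = genes, logfc = lfc, p = padj, p_adj = padj,
               pct_a = rep(1, length(genes)), pct_b = rep(1, length(genes)),
               stringsAsFactors = FALSE)
  }
  t1 <- mk(c("all3", "two_ok", "two_weak", "conflict", "one"),
           c(0.1, 0.50, 0.39, 0.6, 1.0), rep(0.01, 5))
  t2 <- mk(c("all3", "two_ok", "two_weak", "conflict"),
           c(0.1, 0.45, 0.50, -0.6), rep(0.01, 4))
  t3 <- mk(c("all3", "down3"), c(0.1, -0.2), c(0.01, 0.01))
  sig <- aggregate_sc_signature(list(t1, t2, t3))
  # significant, same sign in all 3 lines: kept regardless of |lfc|
  expect_true("all3" %in% sig$up)
  # two lines, both |lfc| >= 0.4: kept
  expect_true("two_ok" %in% sig$up)
  # two lines but one |lfc| = 0.39 < 0.4: dropped
  expect_false("two_weak" %in% union(sig$up, sig$down))
  # significant in opposite directions: dropped
  expect_false("conflict" %in% union(sig$up, sig$down))
  # single line only: dropped
  expect_false("one" %in% union(sig$up, sig$down))
  # a gene significant (down) in one line only is dropped too
  expect_false("down3" %in% union(sig$up, sig$down))

  # invariance to row order and line order
  shuf <- function(t) t[sample(nrow(t)), , drop = FALSE]
  set.seed(4)
  sig2 <- aggregate_sc_signature(list(shuf(t3), shuf(t1), shuf(t2)))
  expect_setequal(sig2$up, sig$up)
  expect_setequal(sig2$down, sig$down)

  empty <- mk(character(0), numeric(0), numeric(0))
  sig0 <- aggregate_sc_signature(list(empty, empty, empty))
  expect_equal(length(sig0), 0)
})

test_that("NB group test recovers a planted fold change with the covariate design", {
  sim <- simulate_bulk_experiment(
    bulk_sim_config(n_genes = 300, n_up = 10, n_down = 10, effect_size = 8,
                    dispersion = 0.05, seed = 12)
  )
  counts <- lowcount_gene_filter(sim$counts)
  # inject a constant gene: logfc 0, p ~ 1
  counts <- rbind(counts, constant = rep(50L, ncol(counts)))
  tab <- nb_group_test(counts, sim$sample_meta)
  up_rows <- tab[tab$gene_id %in% sim$truth$up, ]
  expect_true(all(up_rows$p_adj < 0.05))
  expect_true(all(abs(up_rows$logfc - 3) < 1))
  expect_lt(abs(mean(up_rows$logfc) - 3), 0.3)
  down_rows <- tab[tab$gene_id %in% sim$truth$down, ]
  expect_true(all(abs(down_rows$logfc + 3) < 1))
  expect_lt(abs(mean(down_rows$logfc) + 3), 0.3)
  const <- tab[tab$gene_id == "constant", ]
  expect_lt(abs(const$logfc), 0.1)
  expect_gt(const$p, 0.5)
  expect_identical(attr(tab, "logfc_base"), "log2")
})

test_that("permuted group labels give uniform NB test p-values", {
  sim <- simulate_bulk_experiment(
    bulk_sim_config(n_genes = 500, n_up = 0, n_down = 0, effect_size = 1,
                    seed = 3)
  )
  meta <- sim$sample_meta
  set.seed(5)
  meta$group_label <- sample(meta$group_label)
  # permutation may unbalance groups within line; only proceed when testable
  tab <- nb_group_test(lowcount_gene_filter(sim$counts), meta)
  expect_gt(ks.test(tab$p, "punif")$p.value, 0.01)
})

test_that("a fully confounded design is rejected with the terms named", {
  sim <- simulate_bulk_experiment(bulk_sim_config(n_genes = 200, seed = 2))
  meta <- sim$sample_meta
  meta$line_id <- ifelse(meta$group_label == "SR101high", "lineX", "lineY")
  expect_error(nb_group_test(sim$counts, meta), "confounded")
})

test_that("bulk signature thresholds are boundary-inclusive on |log2 fc| >= 1", {
  tab <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    logfc = c(0.9, -1.0, 1.2, 2.0),
    p = c(0.001, 0.001, 0.001, 0.2),
    p_adj = c(0.04, 0.04, 0.04, 0.6),
    stringsAsFactors = FALSE
  )
  sig <- aggregate_bulk_signature(tab)
  expect_false("a" %in% union(sig$up, sig$down))  # |lfc| below 1
  expect_true("b" %in% sig$down)                  # boundary kept
  expect_true("c" %in% sig$up)
  expect_false("d" %in% union(sig$up, sig$down))  # not significant
  expect_equal(length(aggregate_bulk_signature(tab[integer(0), ])), 0)
})

test_that("caprola cascade filters match a brute-force oracle on constructed tables", {
  mk_tables <- function(seed, n = 120) {
    set.seed(seed)
    genes <- sprintf("g%03d", 1:n)
    mk <- function() {
      present <- sort(sample(n, round(0.8 * n)))
      data.frame(gene_id = genes[present],
                 logfc = round(rnorm(length(present), 0, 2), 2),
                 p_adj = round(runif(length(present), 0, 0.12), 3),
                 logcpm = round(runif(length(present), 0, 6), 2),
                 stringsAsFactors = FALSE)
    }
    list(high_vs_med = mk(), med_vs_low = mk(), high_vs_low = mk())
  }
  for (seed in c(1, 2, 3)) {
    tabs <- mk_tables(seed)
    sig <- caprola_cascade(tabs, top_n = 15)
    oracle <- oracle_caprola(tabs, top_n = 15)
    expect_setequal(sig$up, oracle$up)
    expect_setequal(sig$down, oracle$down)
  }

  # single-filter spot checks
  tabs <- mk_tables(9)
  tabs$high_vs_med$p_adj[] <- 0.06
  tabs$med_vs_low$p_adj[] <- 0.06
  tabs$high_vs_low$p_adj[] <- 0.06
  expect_equal(length(caprola_cascade(tabs)), 0)  # all fail FDR

  one_cmp <- list(
    a = data.frame(gene_id = "g1", logfc = 2, p_adj = 0.01, logcpm = 5),
    b = data.frame(gene_id = "g2", logfc = 2, p_adj = 0.01, logcpm = 5),
    c = data.frame(gene_id = "g3", logfc = 2, p_adj = 0.01, logcpm = 5)
  )
  expect_equal(length(caprola_cascade(one_cmp)), 0)  # one comparison each

  no_cpm <- lapply(one_cmp, function(t) t[, setdiff(names(t), "logcpm")])
  expect_error(caprola_cascade(no_cpm), "logcpm")
})

test_that("diffusion correction removes control genes in either direction", {
  ca <- gene_signature("ca", up = c("a", "b", "c"), down = c("d", "e"))
  ctrl <- gene_signature("ctrl", up = "b", down = "d")
  out <- diffusion_correct(ca, ctrl)
  expect_identical(out$up, c("a", "c"))
  expect_identical(out$down, "e")

  disjoint <- gene_signature("x", up = "q", down = "r")
  out2 <- diffusion_correct(ca, disjoint)
  expect_identical(out2$up, ca$up)

  superset <- gene_signature("all", up = c("a", "b", "c"), down = c("d", "e"))
  expect_equal(length(diffusion_correct(ca, superset)), 0)
})

test_that("signature recovery: derived signature matches planted genes across seeds", {
  ok <- vapply(1:20, function(s) {
    cfg <- sc_sim_config(cells_per_group = 300, n_genes = 800,
                         effect_size = 3, seed = s)
    sim <- simulate_sc_experiment(cfg)
    nm <- lognormalize(sim$cm)
    tabs <- lapply(paste0("line", 1:3), function(l) {
      meta <- nm$cell_meta
      rank_sum_markers(
        nm,
        meta$cell_id[meta$line_id == l & meta$group_label == "SR101high"],
        meta$cell_id[meta$line_id == l & meta$group_label == "SR101low"]
      )
    })
    sig <- aggregate_sc_signature(tabs)
    derived <- union(sig$up, sig$down)
    planted <- union(sim$truth$up, sim$truth$down)
    length(intersect(derived, planted)) / length(union(derived, planted)) >= 0.8
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
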