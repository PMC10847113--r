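# Small fixtures built in code, shared across test files.

# deterministic toy count matrix with annotations
toy_count_matrix <- function(n_genes = 20, n_cells = 12, seed = 42,
                             n_mito = 2) {
  set.seed(seed)
  gene_ids <- c(sprintf("g%03d", seq_len(n_genes - n_mito)),
                sprintf("MT-%d", seq_len(n_mito)))
  cell_ids <- sprintf("c%02d", seq_len(n_cells))
  counts <- matrix(rpois(n_genes * n_cells, 5), nrow = n_genes,
                   dimnames = list(gene_ids, cell_ids))
  meta <- data.frame(
    cell_id = cell_ids,
    line_id = rep(c("lineA", "lineB"), length.out = n_cells),
    group_label = rep(c("SR101high", "SR101low"), each = n_cells / 2),
    stringsAsFactors = FALSE
  )
  CountMatrix(counts, cell_meta = meta)
}

# normalized matrix built directly from given values (for scoring tests)
toy_normalized <- function(values) {
  cm <- CountMatrix(matrix(1L, nrow = nrow(values), ncol = ncol(values),
                           dimnames = dimnames(values)))
  nm <- lognormalize(cm)
  nm$values <- values
  nm
}

# independent brute-force oracle for the five-filter caprola cascade;
# record-by-record loops, no vectorization shared with the implementation
oracle_caprola <- function(tables, fdr_max = 0.05, min_logcpm = 2,
                           top_n = 50) {
  recs <- list()
  for (cmp in names(tables)) {
    t <- tables[[cmp]]
    for (i in seq_len(nrow(t))) {
      if (t$p_adj[i] <= fdr_max) {                     # filter 1
        recs[[length(recs) + 1]] <- list(gene = t$gene_id[i],
                                         lfc = t$logfc[i],
                                         cpm = t$logcpm[i], cmp = cmp)
      }
    }
  }
  genes <- unique(vapply(recs, `[[`, character(1), "gene"))
  surviving <- character(0)
  dir_of <- c()
  for (g in genes) {
    mine <- Filter(function(r) r$gene == g, recs)
    if (length(mine) < 2) next                          # filter 2
    signs <- vapply(mine, function(r) sign(r$lfc), numeric(1))
    if (length(unique(signs)) != 1 || any(signs == 0)) next  # filter 3
    if (mean(vapply(mine, `[[`, numeric(1), "cpm")) < min_logcpm) next # f4
    surviving <- c(surviving, g)
    dir_of[g] <- signs[1]
  }
  # filter 5 on the records of surviving genes
  keep <- character(0)
  for (g in surviving) {
    ok <- TRUE
    for (cmp in names(tables)) {
      rc <- Filter(function(r) r$cmp == cmp & r$gene %in% surviving, recs)
      if (!length(Filter(function(r) r$gene == g, rc))) next
      lfcs <- vapply(rc, `[[`, numeric(1), "lfc")
      gn <- vapply(rc, `[[`, character(1), "gene")
      o <- order(lfcs, gn)
      ranked <- gn[o]
      k <- length(ranked)
      extreme <- union(head(ranked, min(top_n, k)),
                       tail(ranked, min(top_n, k)))
      if (!(g %in% extreme)) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, g)
  }
  list(up = sort(keep[dir_of[keep] > 0]), down = sort(keep[dir_of[keep] < 0]))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
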