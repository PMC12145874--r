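# Shared fixture builders; everything is generated in code, seeded per use.

# A scored_genes table with prescribed DEG labels: "up"/"down" genes get an
# FDR well below .01 with the matching fold-change sign, "none" genes sit
# above the threshold.
make_scored <- function(labels, seed = 1L) {
  set.seed(seed)
  n <- length(labels)
  fdr <- ifelse(labels == "none", runif(n, 0.05, 1), runif(n, 1e-6, 0.005))
  lfc <- ifelse(labels == "down", -1, 1) * runif(n, 0.5, 3)
  call_degs(data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                       log2fc = lfc, fdr = fdr, stringsAsFactors = FALSE))
}

# A small random gene-set collection over a fresh universe.
make_collection <- function(n_genes = 50, n_sets = 8, size = c(3, 10),
                            seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(size[1]:size[2], 1)))
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  gene_set_collection(sets, universe = genes)
}

# Independent BFS ancestor closure over a parent-edge table (queue loop, no
# recursion, no igraph) — the oracle for propagate_ancestors.
bfs_ancestors <- function(terms, edges) {
  out <- character(0)
  queue <- terms
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% out) next
    out <- c(out, t)
    queue <- c(queue, edges$parent[edges$child == t])
  }
  sort(unique(out))
}

# Growth simulation shorthand: one strain, chosen pH set and true rates.
sim_rates <- function(mu, ph = seq_along(mu), n_wells = 12, noise_cv = 0.05,
                      n_periods = 4, seed = 1L) {
  cfg <- growth_sim_config(strains = "S", ph = ph, n_wells = n_wells,
                           n_periods = n_periods, period_length = 3,
                           mu_true = data.frame(strain = "S", ph = ph, mu = mu),
                           noise_cv = noise_cv)
  period_rates(simulate_growth(cfg, seed = seed)$series)
}
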