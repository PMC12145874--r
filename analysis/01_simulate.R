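#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs.
#
# Emulates the common-garden design: 3 strains spanning the three growth
# patterns (an acidophile, a generalist, an acid-intolerant) grown at pH
# 4.7 / 7.0 / 8.2, plus one synthetic DE dataset per strain contrast with
# planted enriched/depleted gene sets, and a toy ontology for ancestor
# propagation. Everything downstream reads from results/.

suppressMessages(library(phresp))

cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "phresp"))
dir.create("results/input", showWarnings = FALSE, recursive = TRUE)

gcfg <- do.call(growth_sim_config, c(
  list(strains = cfg$strains, ph = cfg$ph, mu_true = cfg$mu_true),
  cfg$growth))
growth <- simulate_growth(gcfg, seed = cfg$seed)
write_tsv(growth$series, "results/input/growth_series.tsv")
write_tsv(growth$truth$mu_true, "results/input/mu_true.tsv")
cat("growth: ", nrow(growth$series), " readings over ",
    length(unique(growth$series$well_id)), " wells\n", sep = "")

for (i in seq_len(nrow(cfg$contrasts))) {
  s <- cfg$contrasts$strain[i]
  lo <- cfg$contrasts$low_ph[i]; hi <- cfg$contrasts$high_ph[i]
  dcfg <- do.call(de_sim_config, cfg$de)
  sim <- simulate_de(dcfg, seed = cfg$seed + i, strain = s,
                     contrast = c(lo, hi))
  tag <- sprintf("%s_%dv%d", s, trunc(lo), trunc(hi))
  write_tsv(sim$de, sprintf("results/input/de_%s.tsv", tag))
  write_gmt(sim$sets, sprintf("results/input/sets_%s.gmt", tag))
  truth <- data.frame(set_id = names(sim$truth$planted_sets),
                      planted = unname(sim$truth$planted_sets))
  write_tsv(truth, sprintf("results/input/truth_%s.tsv", tag))
  cat(tag, ": ", sum(truth$planted != "null"), " planted sets of ",
      nrow(truth), "\n", sep = "")
}

ont <- simulate_ontology(n_terms = 40, max_depth = 4, seed = cfg$seed,
                         n_genes = 30)
write_tsv(ont$edges, "results/input/ontology_edges.tsv")
cat("ontology: ", nrow(ont$edges), " parent edges, root ", ont$root, "\n",
    sep = "")
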