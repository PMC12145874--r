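#!/usr/bin/env Rscript
# Stage 5 — strain-pH enrichment groups and response-similarity clustering.
#
# Builds the En/Dp groups per strain x contrast (labels like NPAL-12_7En8),
# computes the square-root-transformed Jaccard dissimilarity on gene-set
# presence/absence, orders the groups by average-linkage clustering, and
# exports the distance heatmap + exact TSV.

suppressMessages(library(phresp))

cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "phresp"))
groups <- list()
for (i in seq_len(nrow(cfg$contrasts))) {
  s <- cfg$contrasts$strain[i]
  lo <- cfg$contrasts$low_ph[i]; hi <- cfg$contrasts$high_ph[i]
  tag <- sprintf("%s_%dv%d", s, trunc(lo), trunc(hi))
  comp <- read_tsv(sprintf("results/composite_%s.tsv", tag))
  gr <- build_groups(comp, s, c(lo, hi))
  groups <- c(groups, gr)
  cat(sprintf("%s: |En| = %d, |Dp| = %d\n",
              tag, length(gr$En$members), length(gr$Dp$members)))
}

d <- suppressMessages(jaccard_sqrt_distance(groups))
ord <- order_groups(d, linkage = "average")
cat("leaf order:", paste(ord$order, collapse = " | "), "\n")
export_heatmap(d, ord$order, "results/response_distance")
cat("mean off-diagonal distance:",
    round(mean(unclass(d)[upper.tri(d)]), 3), "\n")
cat("wrote results/response_distance.{tsv,png}\n")
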