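#!/usr/bin/env Rscript
# Stage 3 — gene-level scoring.
#
# For every strain x contrast DE table: call DEGs at FDR < .01 and attach
# SLFDR scores (signed ln FDR, the printed convention: significant
# upregulation -> strongly negative). Writes one scored table per contrast.

suppressMessages(library(phresp))

de_files <- list.files("results/input", pattern = "^de_.*\\.tsv$",
                       full.names = TRUE)
for (f in de_files) {
  tag <- sub("^de_(.*)\\.tsv$", "\\1", basename(f))
  scored <- call_degs(read_tsv(f), alpha = 0.01)
  write_tsv(scored, sprintf("results/scored_%s.tsv", tag))
  cat(sprintf("%s: %d genes, %d up / %d down DEGs; SLFDR range [%.1f, %.1f]\n",
              tag, nrow(scored),
              sum(scored$deg_label == "up"), sum(scored$deg_label == "down"),
              min(scored$slfdr), max(scored$slfdr)))
}
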