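# phresp

Growth and gene-set transcriptomic response analysis across environmental pH
conditions.

## The problem

Common-garden experiments grow genetically distinct microbial strains (here,
the motivating system is freshwater diatoms) under identical controlled
conditions — e.g. acidic (pH 4.7), neutral (7.0) and alkaline (8.2) media —
so that differences in growth and gene expression reflect genotype rather
than environment. Two questions follow:

1. **Growth**: how fast does each strain grow under each pH, and which
   conditions differ significantly? Strains are then classified as
   *acidophiles*, *generalists*, or *acid-intolerants*.
2. **Transcriptome**: in each pairwise pH contrast, which *gene sets*
   (GO/InterPro/KEGG terms, orthogroups, ...) respond — and do strains that
   grow alike also respond alike at the functional level?

`phresp` implements the full analysis chain for both questions, driven by a
seeded synthetic-data generator with known ground truth so every stage is
testable without any sequencing data.

## The methods

**Growth rate** per well and growth period, from fluorescence (RFU) readings:

```
mu = (ln N1 - ln N0) / (t1 - t0)        [per day]
```

keeping the last two periods (after growth stabilization; one period for
rapidly decaying cultures). Per-strain differences across pH are tested with
Kruskal–Wallis and Dunn's post-hoc z-tests (tie-corrected, BH-adjusted,
FDR .05) summarized as compact letter displays.

**Gene-level scores.** From each differential-expression table (gene,
log2FC, FDR; expression at the lower pH compared to the higher), genes pass
the inclusion filter CPM ≥ 1 in ≥ 2 replicates, DEGs are called at FDR < .01,
and each gene is scored with the signed ln(FDR):

```
SLFDR = ln(FDR) * log2(FC) / |log2(FC)|
```

Note the orientation: a significantly *up*regulated gene gets a strongly
*negative* score.

**Three enrichment methods** per gene set, combined by union:

- **FCS** (functional class scoring): Wilcoxon rank-sum of in-set vs
  out-of-set SLFDR scores, significance from a gene-sampling null
  (equal-size random member sets; exhaustive enumeration on small
  universes), BH-adjusted per direction at FDR .01.
- **ORA** (over-representation): two 2×2 chi-square tests per set — are
  up-(down-)regulated genes over-represented inside the set? — BH-adjusted
  per direction at FDR .01; a set can be enriched, depleted, or both.
- **UGS** (unidirectional gene set): the deterministic criterion flagging
  sets whose DEGs are *exclusively* upregulated (enriched) or downregulated
  (depleted), regardless of proportion, with a minimum of 2 same-direction
  DEGs.

A set is *affected* when at least one method calls it; supporting methods
are recorded per direction.

**Response clustering.** Affected sets are grouped into strain-pH enrichment
groups named `<strain>_<low><En|Dp><high>` with truncated pH digits — e.g.
`NPAL-12_7En8` holds the sets enriched at pH 7.0 vs 8.2 in strain NPAL-12.
Groups are compared by the Euclidean-like, square-root-transformed Jaccard
distance `sqrt(1 - a/(a+b+c))` on gene-set presence/absence and ordered by
average-linkage hierarchical clustering (heatmap + exact TSV output).

## Worked example

The numbered drivers under `analysis/` run the demo study (3 strains, 3
contrasts, synthetic transcriptomes with 12 planted signal sets each) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_growth.R
Rscript analysis/03_score.R
Rscript analysis/04_enrich.R
Rscript analysis/05_cluster.R
```

Stage 2 prints, for the shipped configuration:

```
ACAF-21: KW p = 1.22e-08; medians [4.7:0.30, 7:0.34, 8.2:0.40]; letters [4.7:c, 7:b, 8.2:a] -> generalist
EUNS-26: KW p = 1.07e-09; medians [4.7:0.60, 7:0.24, 8.2:0.20]; letters [4.7:a, 7:b, 8.2:c] -> acidophile
NPAL-12: KW p = 9.32e-09; medians [4.7:-0.31, 7:0.40, 8.2:0.45]; letters [4.7:c, 7:b, 8.2:a] -> acid_intolerant
median |recovery error| = 0.004 /day over 9 strain x pH cells
```

i.e. each strain's pH conditions differ significantly (Kruskal–Wallis p),
the letter displays separate all three conditions, the estimated medians
recover the generating growth rates to ~0.004/day, and the three planted
growth patterns are classified correctly. Stage 4 prints per contrast, e.g.:

```
NPAL-12_7v8: 6 enriched + 10 depleted composite calls; 12/12 planted sets recovered
  method support: FCS=10, ORA=13, UGS=11
```

— all 12 planted signal sets are recovered by at least one method. Stage 5
builds the six strain-pH enrichment groups (`EUNS-26_4En8` ... `NPAL-12_7Dp8`),
clusters them, and writes `results/response_distance.{tsv,png}`.

The same end-to-end run is available programmatically:

```r
library(phresp)
cfg <- read_run_config(system.file("extdata", "demo_config.yaml", package = "phresp"))
res <- run_pipeline(cfg, "results/run")   # writes tables + manifest.json
res$growth$patterns
```

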