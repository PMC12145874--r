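---
title: "Methods: growth and gene-set response analysis across pH conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth and gene-set response analysis across pH conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phresp)
```

# Scope and model

`phresp` analyses common-garden experiments in which microbial strains are
grown under several environmental pH conditions and profiled for (i) growth
and (ii) transcriptomic response per pairwise pH contrast. The package
assumes exponential growth within each growth period, a per-contrast
differential-expression (DE) table as an input contract (the DE model fit
itself — dispersion estimation, exact tests — is upstream and out of scope),
and gene-set memberships given as GMT collections, optionally closed over an
ontology DAG.

## Growth

Within one growth period (the interval between culture renewals), biomass is
assumed to grow or decay exponentially, with fluorescence (RFU) proportional
to biomass. The per-day rate is `mu = (ln N1 - ln N0)/(t1 - t0)`. Two
analysis choices deserve note:

* **Period selection.** "After stabilization" is operationalized as *keep
  the last two periods of each well*, with a single-period fallback for
  short (rapidly decaying) series. No change-point detection is attempted —
  the selection rule is pluggable (`period_rates(keep_periods = ...)`) and
  the default mirrors a design in which an acclimatization period precedes
  the measured ones.
* **Replication unit.** Each selected well x period record enters the
  Kruskal–Wallis test as one observation (so 12 wells x 2 periods = 24
  records per condition). Treating periods within a well as independent
  overstates replication if within-well autocorrelation is strong; the
  record table is exposed so users can aggregate per well first if they
  prefer.

Dunn's post-hoc test is implemented as rank-based z statistics with the
standard tie correction and Benjamini–Hochberg adjustment. The compact
letter display is computed by greedy insert-and-absorb over the
non-significance graph; letters are assigned in order of decreasing
condition median. Growth patterns are classified by an explicit rule set:
acidic median < 0 is *acid-intolerant* (collapse), acidic median positive,
highest, and holding its own letter is *acidophile*, all-positive medians
otherwise is *generalist*. The collapse threshold (median < 0) is a
heuristic; configurations outside all three rules return `NA` rather than a
forced label.

## Gene-level scores

Genes pass the inclusion filter CPM ≥ 1 in ≥ 2 replicates (`cpm_filter()`,
both thresholds configurable); DEGs are called at FDR < .01. The gene score
is the signed log FDR,

$$\mathrm{SLFDR} = \ln(\mathrm{FDR})\cdot\frac{\log_2 FC}{|\log_2 FC|},$$

kept deliberately in its printed orientation: a significantly upregulated
gene scores strongly *negative*. All rank-based downstream machinery is
direction-aware of this, and `slfdr(flip_sign = TRUE)` provides the
conventional orientation for export. Two numerical guards: FDR = 0 is
floored at `fdr_floor = 1e-300` (keeps the log finite without perturbing any
realistic FDR), and `log2FC = 0` — whose sign the formula leaves undefined —
maps to score 0 with a warning rather than an error, since such genes are
never DEGs and should not break ranking.

## Enrichment

Three complementary detectors run per gene set, all against the *filtered*
gene universe (not only annotated genes — a deliberate choice, configurable
by restricting the collection first):

* **FCS.** The set-level statistic is the Wilcoxon rank-sum of in-set vs
  out-of-set SLFDR scores — the aggregation is the named test itself rather
  than a separate mean/median statistic. Significance comes from a
  *gene-sampling* null: random member sets of equal size drawn without
  replacement from the universe, two-sided empirical p with the +1
  correction. When `choose(N, n)` ≤ `exact_limit` (default 1e5) the null is
  enumerated exhaustively and the p-value is exact. Rank-based scoring makes
  the p-value invariant under monotone transforms of the scores. An
  asymptotic Wilcoxon null is available (`null = "asymptotic"`), sampling is
  the default. Default `n_perm = 10000` bounds the attainable two-sided p at
  ~2e-4; reduce it only for screening.
* **ORA.** Two 2×2 chi-square tests per set (up vs not-up × in vs out, and
  the down mirror), without continuity correction (the cited test's
  default), each requiring the in-set proportion to exceed the out-of-set
  proportion for a directional call. Two tables rather than one 2×3 omnibus:
  the question is directional and a set may be *both* enriched and depleted.
  "Outside" means universe minus the set. A zero margin yields p = 1 with a
  warning. Chi-square expected counts are small when DEGs are rare; this
  makes ORA slightly anticonservative on tiny sets, which the null
  simulations quantify (see below).
* **UGS.** Deterministic: at least `min_degs` DEGs all in one direction and
  none in the other. The minimum defaults to 2 because a minimum of 1 would
  flag every set containing a single DEG; it is exposed as `ugs_min_degs`.
  UGS has no error control by construction — its null call rate is a
  property of the data (DEG rate and set sizes) and is reported, not
  bounded.

**FDR families and combination.** BH runs per method × direction across all
sets of one strain × contrast × set-type collection (matching how results
are tabulated per set type); FCS p-values are adjusted within the subfamily
sharing the observed shift direction. The composite call is the union over
methods at FDR .01 (UGS by its criterion), with supporting methods recorded
per direction.

## Response clustering

Affected sets form strain-pH enrichment groups labelled
`<strain>_<lowDigit><En|Dp><highDigit>` (pH truncated to its integer digit).
Groups are vectors of gene-set presence/absence; their dissimilarity is the
Euclidean-like square-root-transformed Jaccard distance
`sqrt(1 - a/(a+b+c))`, which satisfies the triangle inequality (checked by
simulation in the tests) so average-linkage clustering on it is well
defined. Conventions: two empty groups are at distance 0, empty vs
non-empty at 1, both logged. The linkage method is configurable
(`order_groups(linkage=)`); average linkage is the default and leaf-order
ties are broken by sorting labels lexicographically before clustering, so
the tree is invariant to input permutation. The heatmap fill gradient
starts at the minimum estimated off-diagonal distance, which spreads
resolution over the observed range instead of anchoring at 0.

# The synthetic-data generator

The generator defines the study conditions under which the package is
validated:

* **Growth series** (`simulate_growth`): exponential trajectories with
  multiplicative lognormal noise of coefficient of variation `noise_cv`
  (default 0.05, a typical plate-reader repeatability scale), mean-1
  multiplier so the expected log-increment per period is exactly
  `mu * period_length`, readings always positive. The default design — 12
  wells per strain × pH (demo runs use 8), 4 periods of 3 days, rates read
  from a `mu_true` table — mirrors a plate-based common-garden setup with
  renewal every 3 days, where the last two periods per well give 24 records
  per condition.
* **DE tables** (`simulate_de`): null genes draw FDR from Beta(shape, 1)
  with shape `log(deg_rate_null)/log(0.01)` so that P(FDR < .01) equals
  `deg_rate_null` exactly (default 0.02 — a typical DEG fraction in a mild
  contrast); planted-set genes become DEGs with probability
  `effect_deg_rate` (default 0.8) and are forced below the threshold with
  the planted direction (all one direction when
  `effect_unidirectional = TRUE`). log2FC magnitudes are lognormal — only
  the sign matters to SLFDR, so this choice affects realism, not scoring.
  Gene sets are sampled independently and may overlap, as real GO/KEGG
  annotations do. The truth object records planted set labels and the
  *realized* per-gene DEG labels, which is exactly what DEG calling must
  recover. Optional replicate-level CPM matrices (3 replicates per
  condition, negative-binomial counts around condition means with the fold
  change applied at the low-pH condition) support the expression filter and
  sample-distance checks. The true effect size of real set-level
  signals is unknown; the generator's effect parameters are free knobs of
  the validation design, not estimates of nature.
* **Ontology** (`simulate_ontology`): a rooted DAG with strictly increasing
  term depths (so every root-to-leaf path has at most `max_depth` edges) and
  occasional second parents; only "is_a"-style parent edges are modelled.

What the generator does **not** emulate: library-size and compositional
artefacts, correlated genes within sets, batch effects, annotation bias
(set membership correlated with expression level), or inter-strain
phylogenetic structure in the response. Passing tests therefore demonstrate
correctness of the statistical machinery under its stated assumptions, not
robustness to those real-data phenomena.

# Validation design and problem sizes

The test suite and `scripts/acceptance.R` run, at sizes chosen to keep a
full run in minutes on one CPU while leaving Monte-Carlo error small
relative to the tolerances:

* formula fidelity on randomized inputs (exact to 1e-12);
* UGS against a brute-force label scan on 200 random datasets;
* FCS against exhaustive gene-sampling enumeration on universes of ≤ 10
  genes;
* error control on 1000 null sets (universe 2000 genes, DEG rate 0.02,
  2000 permutations): FCS and ORA per-direction false-positive rates within
  the 99% Monte-Carlo band of ≤ .01, UGS null rate reported and compared
  across generator seeds;
* recovery of planted unidirectional sets (universe 5000, set size 20,
  effect DEG rate 0.8): at least 90% correct composite directions;
* growth recovery (noiseless exact; cv 0.05 with 24 records within 2%) and
  the Kruskal–Wallis type-I rate over 1000 replicates within the 99%
  binomial band of .05;
* sqrt-Jaccard distances against exhaustive small-pair enumeration, metric
  axioms over 10,000 random triples, and recovery of planted response
  structure in the leaf order;
* the exact group-label scheme, including `NPAL-12_7En8`.

# Known limitations

* Dunn + compact letters assume the z approximation; very small per-group
  counts (< 4) make letters unstable.
* ORA's chi-square is anticonservative for very small sets at low DEG
  rates; with FDR control at .01 the measured per-direction false-positive
  rate stays within the stated band, but users comparing methods per set
  should prefer the composite call's recorded support.
* UGS is sensitive to `deg_rate_null` through chance unidirectional null
  sets; always interpret UGS-only calls together with its reported null
  rate.
* The pipeline treats contrasts independently; no cross-contrast shrinkage
  or consistency model is attempted.
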