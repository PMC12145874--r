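#' Expression filter on a CPM matrix
#'
#' Returns the gene universe passing the inclusion filter: genes with at
#' least `min_cpm` counts per million in at least `min_reps` samples. This is
#' the universe against which DEG calling and enrichment are computed.
#'
#' @param cpm Numeric matrix, genes x samples, of counts-per-million values;
#'   rownames are gene ids.
#' @param min_cpm Minimum CPM (default 1).
#' @param min_reps Minimum number of samples meeting `min_cpm` (default 2).
#'
#' @return Character vector of gene ids passing the filter.
#' @export
cpm_filter <- function(cpm, min_cpm = 1, min_reps = 2L) {
  if (!is.matrix(cpm) || is.null(rownames(cpm)))
    stop("cpm_filter: 'cpm' must be a matrix with gene rownames")
  if (ncol(cpm) < min_reps)
    stop("cpm_filter: fewer samples (", ncol(cpm),
         ") than 'min_reps' (", min_reps, ")")
  if (any(cpm < 0)) stop("cpm_filter: negative CPM values")
  rownames(cpm)[rowSums(cpm >= min_cpm) >= min_reps]
}

#' Signed ln(FDR) gene-level score
#'
#' \deqn{\mathrm{SLFDR} = \ln(\mathrm{FDR}) \cdot
#'   \frac{\log_2 FC}{|\log_2 FC|}}
#' i.e. the natural log of the adjusted p-value signed by the direction of
#' the fold change. Under this convention a significantly UPregulated gene
#' gets a strongly NEGATIVE score (ln of a small FDR is very negative and
#' the sign factor is +1). Zero fold change has an undefined sign in the
#' formula and maps to a score of 0 with a warning. An FDR of exactly 0 is
#' floored at `fdr_floor` to keep the log finite.
#'
#' @param fdr Adjusted p-values in \[0, 1\]; vectorized.
#' @param log2fc Signed log2 fold changes, same length.
#' @param fdr_floor Numerical floor for FDR (default 1e-300).
#' @param flip_sign If `TRUE`, return the negated score so that upregulation
#'   is positive (the more conventional orientation); default `FALSE`, the
#'   formula as printed.
#'
#' @return Numeric vector of signed scores.
#' @export
slfdr <- function(fdr, log2fc, fdr_floor = 1e-300, flip_sign = FALSE) {
  if (any(fdr < 0 | fdr > 1)) stop("slfdr: 'fdr' must lie in [0, 1]")
  if (length(fdr) != length(log2fc)) stop("slfdr: length mismatch")
  if (any(log2fc == 0))
    warning("slfdr: log2fc of 0 has undefined sign; score set to 0")
  score <- log(pmax(fdr, fdr_floor)) * sign(log2fc)
  if (flip_sign) score <- -score
  score
}

#' Call differentially expressed genes and attach SLFDR scores
#'
#' Labels each gene `up` (fdr < alpha and log2fc > 0), `down` (fdr < alpha
#' and log2fc < 0) or `none`, and attaches the [slfdr()] score. The table
#' should already be restricted to the filtered gene universe.
#'
#' @param de Data frame with columns `gene_id`, `log2fc`, `fdr` (one row per
#'   gene).
#' @param alpha FDR significance cut-off (default .01).
#' @param ... Passed to [slfdr()].
#'
#' @return The input data frame with added columns `slfdr` and `deg_label`;
#'   class `scored_genes`.
#' @export
call_degs <- function(de, alpha = 0.01, ...) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(de)))
    stop("call_degs: 'de' must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(de$gene_id))
    stop("call_degs: duplicate gene ids in the DE table")
  de$slfdr <- slfdr(de$fdr, de$log2fc, ...)
  de$deg_label <- ifelse(de$fdr < alpha & de$log2fc > 0, "up",
                  ifelse(de$fdr < alpha & de$log2fc < 0, "down", "none"))
  class(de) <- c("scored_genes", class(de))
  attr(de, "alpha") <- alpha
  de
}

#' Sample-to-sample expression distances
#'
#' Computes Pearson correlation and Euclidean distance matrices among samples
#' from centered log2-transformed expression: `x = log2(CPM + pseudocount)`,
#' centered per gene by its mean across samples. Replicates of a condition
#' are expected to be each other's nearest neighbours when condition effects
#' dominate.
#'
#' @param cpm Genes x samples CPM matrix.
#' @param pseudocount Added before the log (default 1).
#'
#' @return List with `pearson` (correlation matrix, unit diagonal) and
#'   `euclidean` (distance matrix). Samples with zero variance after
#'   centering yield `NA` correlations with a warning.
#' @export
sample_distances <- function(cpm, pseudocount = 1) {
  if (ncol(cpm) < 2L) stop("sample_distances: need >= 2 samples")
  x <- log2(cpm + pseudocount)
  xc <- x - rowMeans(x)
  sds <- apply(xc, 2, stats::sd)
  if (any(sds == 0))
    warning("sample_distances: zero-variance sample(s); correlations are NA: ",
            paste(colnames(cpm)[sds == 0], collapse = ", "))
  pearson <- suppressWarnings(stats::cor(xc))
  diag(pearson) <- 1
  euclidean <- as.matrix(stats::dist(t(xc)))
  list(pearson = pearson, euclidean = euclidean)
}
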