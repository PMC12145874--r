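#' Functional class scoring of one gene set (Wilcoxon rank-sum, gene-sampling null)
#'
#' Aggregates SLFDR gene-level scores into a global statistic for the set:
#' the Wilcoxon rank-sum of in-set scores against out-of-set scores (joint
#' ranking with average ranks for ties). Significance is assessed by gene
#' sampling: random member sets of equal size are drawn without replacement
#' from the universe and the two-sided empirical p-value is computed with the
#' +1 correction,
#' \deqn{p = \min\left(1,\; 2\min\left(\frac{1 + \#\{W^* \le W\}}{B + 1},
#'   \frac{1 + \#\{W^* \ge W\}}{B + 1}\right)\right).}
#' When the number of distinct equal-size subsets is at most `exact_limit`
#' the null is enumerated exhaustively instead and the p-value is exact
#' (proportion of subsets at least as extreme, no +1 correction).
#'
#' Direction follows the shift of in-set ranks: under the printed SLFDR
#' convention, significantly upregulated genes have strongly negative scores,
#' so a rank sum BELOW expectation marks an upregulation tendency
#' ("enriched") and above expectation a downregulation tendency ("depleted").
#'
#' @param scores Numeric vector of SLFDR scores over the whole gene universe,
#'   named by gene id.
#' @param members Character vector of the set's gene ids (must be a proper
#'   non-empty subset of the universe).
#' @param n_perm Number of gene-sampling draws (default 10000).
#' @param seed Optional integer seed for the sampling null.
#' @param null Either `"sampling"` (default) or `"asymptotic"` (normal
#'   approximation via [stats::wilcox.test()]).
#' @param exact_limit Enumerate the null exhaustively when `choose(N, n)` is
#'   at most this value (default 1e5); set to 0 to force sampling.
#'
#' @return One-row data frame: `n_set`, `statistic` (in-set rank sum),
#'   `direction` (shift sign: enriched/depleted/none), `p`.
#' @export
fcs_test <- function(scores, members, n_perm = 10000L, seed = NULL,
                     null = c("sampling", "asymptotic"), exact_limit = 1e5) {
  null <- match.arg(null)
  if (is.null(names(scores))) stop("fcs_test: 'scores' must be named by gene id")
  in_set <- names(scores) %in% members
  n <- sum(in_set); N <- length(scores)
  if (n == 0L) stop("fcs_test: set empty after universe restriction")
  if (n == N) stop("fcs_test: set equals the universe; comparison undefined")
  r <- rank(scores)
  W <- sum(r[in_set])
  expected <- n * (N + 1) / 2
  direction <- if (W < expected) "enriched" else if (W > expected) "depleted" else "none"
  eps <- 1e-9
  if (null == "asymptotic") {
    p <- stats::wilcox.test(scores[in_set], scores[!in_set], exact = FALSE)$p.value
  } else if (exact_limit > 0 && choose(N, n) <= exact_limit) {
    all_sums <- utils::combn(r, n, FUN = sum)
    p_lo <- sum(all_sums <= W + eps) / length(all_sums)
    p_hi <- sum(all_sums >= W - eps) / length(all_sums)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    perm <- vapply(seq_len(n_perm), function(i) sum(r[sample.int(N, n)]),
                   numeric(1))
    p_lo <- (1 + sum(perm <= W + eps)) / (n_perm + 1)
    p_hi <- (1 + sum(perm >= W - eps)) / (n_perm + 1)
    p <- min(1, 2 * min(p_lo, p_hi))
  }
  data.frame(n_set = n, statistic = W, direction = direction, p = p,
             stringsAsFactors = FALSE)
}

#' Over-representation analysis of one gene set (paired 2x2 chi-square tests)
#'
#' Tests whether the proportions of significantly upregulated and
#' downregulated genes inside the set exceed those outside it, with one 2x2
#' chi-square test per direction (up vs not-up x in vs out; down vs not-down
#' x in vs out), without continuity correction. A set can come out enriched,
#' depleted, both, or neither; the direction requires the in-set proportion
#' to exceed the out-of-set proportion. Degenerate tables (a zero margin)
#' yield p = 1 with a warning.
#'
#' @param scored A `scored_genes` data frame from [call_degs()], restricted
#'   to the universe.
#' @param members Character vector of the set's gene ids.
#' @param correct Continuity correction flag passed to
#'   [stats::chisq.test()] (default `FALSE`).
#'
#' @return One-row data frame: `n_set`, `n_deg_up`, `n_deg_down`, `p_up`,
#'   `p_down`, `up_excess`, `down_excess` (logical: in-set proportion higher).
#' @export
ora_test <- function(scored, members, correct = FALSE) {
  in_set <- scored$gene_id %in% members
  n <- sum(in_set); N <- nrow(scored)
  if (n == 0L) stop("ora_test: set empty after universe restriction")
  if (n == N) stop("ora_test: set equals the universe; comparison undefined")
  one_direction <- function(label) {
    hit <- scored$deg_label == label
    tab <- matrix(c(sum(hit & in_set), sum(!hit & in_set),
                    sum(hit & !in_set), sum(!hit & !in_set)), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("ora_test: degenerate 2x2 table for direction '", label,
              "'; p = 1")
      p <- 1
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
    }
    list(p = p, k_in = tab[1, 1], k_out = tab[1, 2],
         excess = tab[1, 1] / n > tab[1, 2] / (N - n))
  }
  up <- one_direction("up")
  down <- one_direction("down")
  data.frame(n_set = n, n_deg_up = up$k_in, n_deg_down = down$k_in,
             p_up = up$p, p_down = down$p,
             up_excess = up$excess, down_excess = down$excess,
             stringsAsFactors = FALSE)
}

#' Unidirectional gene-set (UGS) call for one gene set
#'
#' The deterministic criterion for unidirectional responses: a set is
#' `enriched` when it contains at least `min_degs` upregulated DEGs and no
#' downregulated DEG, `depleted` in the mirror case, and `none` otherwise —
#' regardless of the DEG proportion within the set. No p-value is attached.
#'
#' @param deg_labels Character vector of DEG labels (`up`/`down`/`none`) for
#'   the set's member genes.
#' @param min_degs Minimum number of same-direction DEGs for a call
#'   (default 2; a minimum of 1 would flag every singleton-DEG set).
#'
#' @return One-row data frame: `n_set`, `n_deg_up`, `n_deg_down`,
#'   `direction`.
#' @export
ugs_call <- function(deg_labels, min_degs = 2L) {
  n_up <- sum(deg_labels == "up")
  n_down <- sum(deg_labels == "down")
  direction <- if (n_up >= min_degs && n_down == 0L) "enriched"
    else if (n_down >= min_degs && n_up == 0L) "depleted"
    else "none"
  data.frame(n_set = length(deg_labels), n_deg_up = n_up, n_deg_down = n_down,
             direction = direction, stringsAsFactors = FALSE)
}

#' Run the three enrichment analyses over a gene-set collection
#'
#' Applies [fcs_test()], [ora_test()] and [ugs_call()] to every set of the
#' collection against the scored gene universe, then combines them with
#' [adjust_and_combine()]. Sets are restricted to the universe first; the
#' FCS sampling null derives one sub-seed per set from `seed` so per-set
#' results do not depend on evaluation order.
#'
#' @param scored A `scored_genes` data frame from [call_degs()].
#' @param collection A [gene_set_collection()]; restricted to
#'   `scored$gene_id` internally.
#' @param methods Subset of `c("fcs", "ora", "ugs")`.
#' @param alpha FDR significance cut-off for FCS and ORA (default .01).
#' @param n_perm,fcs_null,exact_limit Passed to [fcs_test()].
#' @param ugs_min_degs Passed to [ugs_call()].
#' @param seed Integer seed for the FCS sampling null.
#'
#' @return List with per-method data frames (`fcs`, `ora`, `ugs`, those run)
#'   and `composite` from [adjust_and_combine()].
#' @export
run_enrichment <- function(scored, collection,
                           methods = c("fcs", "ora", "ugs"),
                           alpha = 0.01, n_perm = 10000L,
                           fcs_null = "sampling", exact_limit = 1e5,
                           ugs_min_degs = 2L, seed = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  methods <- match.arg(methods, c("fcs", "ora", "ugs"), several.ok = TRUE)
  collection <- suppressMessages(
    restrict_to_universe(collection, scored$gene_id))
  sets <- collection$sets
  ids <- names(sets)
  scores <- setNames(scored$slfdr, scored$gene_id)
  labels <- setNames(scored$deg_label, scored$gene_id)
  out <- list()
  if ("fcs" %in% methods) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sub_seeds <- sample.int(2^30, length(sets))
    rows <- lapply(seq_along(sets), function(i)
      fcs_test(scores, sets[[i]], n_perm = n_perm, seed = sub_seeds[i],
               null = fcs_null, exact_limit = exact_limit))
    out$fcs <- cbind(data.frame(set_id = ids, stringsAsFactors = FALSE),
                     do.call(rbind, rows))
  }
  if ("ora" %in% methods) {
    rows <- lapply(sets, function(m) ora_test(scored, m))
    out$ora <- cbind(data.frame(set_id = ids, stringsAsFactors = FALSE),
                     do.call(rbind, rows))
  }
  if ("ugs" %in% methods) {
    rows <- lapply(sets, function(m) ugs_call(labels[m], min_degs = ugs_min_degs))
    out$ugs <- cbind(data.frame(set_id = ids, stringsAsFactors = FALSE),
                     do.call(rbind, rows))
  }
  out$composite <- adjust_and_combine(fcs = out$fcs, ora = out$ora,
                                      ugs = out$ugs, alpha = alpha)
  out$composite$set_type <- unname(collection$set_type[out$composite$set_id])
  out
}

#' Per-method FDR adjustment and composite affected-set call
#'
#' Benjamini-Hochberg adjustment is applied per method and direction across
#' all sets of one strain x contrast x set-type family: FCS p-values are
#' adjusted within the subfamily of sets sharing the observed shift
#' direction; ORA up- and down-test p-values are adjusted as two separate
#' families. A set is then called enriched (depleted) when at least one
#' method calls it so — FCS/ORA at `fdr < alpha` (ORA additionally requiring
#' the in-set proportion excess), UGS by its deterministic criterion — and
#' the supporting methods are recorded per direction.
#'
#' @param fcs,ora,ugs Per-method data frames as produced by
#'   [run_enrichment()] (any may be `NULL`; a warning is emitted and the
#'   combination proceeds over the available methods).
#' @param alpha FDR cut-off for FCS and ORA (default .01).
#'
#' @return Data frame with one row per set id: `set_id`, `enriched`,
#'   `depleted`, `methods_enriched`, `methods_depleted` (comma-joined), plus
#'   per-method FDR columns where applicable.
#' @export
adjust_and_combine <- function(fcs = NULL, ora = NULL, ugs = NULL,
                               alpha = 0.01) {
  avail <- c(fcs = !is.null(fcs), ora = !is.null(ora), ugs = !is.null(ugs))
  if (!any(avail)) stop("adjust_and_combine: no method outputs supplied")
  if (!all(avail))
    warning("adjust_and_combine: combining over available methods only: ",
            paste(names(avail)[avail], collapse = ", "))
  ids <- unique(c(fcs$set_id, ora$set_id, ugs$set_id))
  res <- data.frame(set_id = ids, enriched = FALSE, depleted = FALSE,
                    methods_enriched = "", methods_depleted = "",
                    stringsAsFactors = FALSE)
  add_support <- function(res, ids_hit, direction, method) {
    col <- if (direction == "enriched") "enriched" else "depleted"
    mcol <- paste0("methods_", col)
    i <- res$set_id %in% ids_hit
    res[[col]][i] <- TRUE
    res[[mcol]][i] <- ifelse(nzchar(res[[mcol]][i]),
                             paste(res[[mcol]][i], method, sep = ","), method)
    res
  }
  if (!is.null(fcs)) {
    fcs$fdr <- NA_real_
    for (d in c("enriched", "depleted")) {
      fam <- fcs$direction == d
      if (any(fam)) fcs$fdr[fam] <- stats::p.adjust(fcs$p[fam], method = "BH")
      hits <- fcs$set_id[fam & fcs$fdr < alpha]
      hits <- hits[!is.na(hits)]
      res <- add_support(res, hits, d, "FCS")
    }
    res$fcs_fdr <- fcs$fdr[match(res$set_id, fcs$set_id)]
    res$fcs_direction <- fcs$direction[match(res$set_id, fcs$set_id)]
  }
  if (!is.null(ora)) {
    ora$fdr_up <- stats::p.adjust(ora$p_up, method = "BH")
    ora$fdr_down <- stats::p.adjust(ora$p_down, method = "BH")
    res <- add_support(res, ora$set_id[ora$fdr_up < alpha & ora$up_excess],
                       "enriched", "ORA")
    res <- add_support(res, ora$set_id[ora$fdr_down < alpha & ora$down_excess],
                       "depleted", "ORA")
    res$ora_fdr_up <- ora$fdr_up[match(res$set_id, ora$set_id)]
    res$ora_fdr_down <- ora$fdr_down[match(res$set_id, ora$set_id)]
  }
  if (!is.null(ugs)) {
    res <- add_support(res, ugs$set_id[ugs$direction == "enriched"],
                       "enriched", "UGS")
    res <- add_support(res, ugs$set_id[ugs$direction == "depleted"],
                       "depleted", "UGS")
    res$ugs_direction <- ugs$direction[match(res$set_id, ugs$set_id)]
  }
  res
}
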