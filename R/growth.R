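#' Per-period exponential growth rate
#'
#' Computes the per-day growth rate over one growth period from fluorescence
#' (biomass proxy) readings at the period boundaries:
#' \deqn{\mu = \frac{\ln N_1 - \ln N_0}{t_1 - t_0}}
#' where \eqn{N_0, N_1} are relative fluorescence units (RFU) at the start
#' and end of the period. Vectorized over all arguments.
#'
#' @param n0,n1 RFU at the start and end of the period; must be positive.
#' @param t0,t1 Times in days; `t1` must exceed `t0`.
#'
#' @return Per-day growth rate(s); negative for decaying populations.
#' @export
growth_rate <- function(n0, n1, t0, t1) {
  if (any(n0 <= 0) || any(n1 <= 0))
    stop("growth_rate: RFU values must be positive")
  if (any(t1 <= t0))
    stop("growth_rate: t1 must be greater than t0")
  (log(n1) - log(n0)) / (t1 - t0)
}

#' Per-period growth rates from a series table
#'
#' Splits a long-format series table into wells, computes the growth rate of
#' every consecutive period, and applies a period-selection rule. The default
#' rule keeps the last two periods (the periods after growth stabilization);
#' when only one period exists the single period is kept, mirroring rapidly
#' decaying cultures for which only one period can be selected.
#'
#' @param series Data frame with columns `well_id`, `strain`, `ph`,
#'   `time_days`, `rfu`; times strictly increasing within a well.
#' @param keep_periods Either `"last2"` (default), `"all"`, or a function
#'   taking the number of periods and returning the integer indices to keep.
#'
#' @return Data frame with columns `well_id`, `strain`, `ph`, `period_index`,
#'   `mu`, one row per selected period per well.
#' @export
period_rates <- function(series, keep_periods = "last2") {
  need <- c("well_id", "strain", "ph", "time_days", "rfu")
  if (!all(need %in% names(series)))
    stop("period_rates: 'series' must have columns ",
         paste(need, collapse = ", "))
  rule <- if (is.function(keep_periods)) keep_periods
    else if (identical(keep_periods, "last2"))
      function(np) seq_len(np)[seq_len(np) > np - 2L]
    else if (identical(keep_periods, "all")) seq_len
    else stop("period_rates: unknown selection rule")
  parts <- split(series, series$well_id)
  out <- lapply(parts, function(d) {
    d <- d[order(d$time_days), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    np <- nrow(d) - 1L
    mu <- growth_rate(d$rfu[-nrow(d)], d$rfu[-1L],
                      d$time_days[-nrow(d)], d$time_days[-1L])
    keep <- rule(np)
    if (length(keep) == 0L) return(NULL)
    data.frame(well_id = d$well_id[1L], strain = d$strain[1L], ph = d$ph[1L],
               period_index = keep, mu = mu[keep], stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    warning("period_rates: selection rule produced no records")
    return(data.frame(well_id = character(0), strain = character(0),
                      ph = numeric(0), period_index = integer(0),
                      mu = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dunn's post-hoc test with tie correction
#'
#' Pairwise rank-based z-tests following a Kruskal-Wallis analysis. All
#' observations are ranked jointly (ties get average ranks); for groups i, j
#' the statistic is
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values and Benjamini-Hochberg adjustment across
#' all pairs.
#'
#' @param x Numeric response values.
#' @param g Grouping factor/vector.
#'
#' @return Data frame with columns `group1`, `group2`, `z`, `p`, `fdr`.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("dunn_test: need at least two groups")
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise significance
#'
#' Assigns letters to groups such that two groups share a letter if and only
#' if they are not declared significantly different, using the greedy
#' insert-and-absorb algorithm: start from one letter covering all groups,
#' split on every significant pair, and absorb letter sets contained in
#' others.
#'
#' @param groups Character vector of group names, in display order (letters
#'   are assigned left to right).
#' @param sig_pairs Two-column matrix or data frame of significantly
#'   different pairs.
#'
#' @return Named character vector mapping each group to its letter string.
#' @export
compact_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  if (!is.null(sig_pairs) && NROW(sig_pairs) > 0) {
    for (k in seq_len(NROW(sig_pairs))) {
      a <- as.character(sig_pairs[k, 1]); b <- as.character(sig_pairs[k, 2])
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else new_sets <- c(new_sets, list(s))
      }
      new_sets <- new_sets[lengths(new_sets) > 0]
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) {
        for (j in seq_along(new_sets)) {
          if (i == j || !keep[i] || !keep[j]) next
          if (all(new_sets[[i]] %in% new_sets[[j]]) &&
              (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j))
            keep[i] <- FALSE
        }
      }
      sets <- new_sets[keep]
    }
  }
  # order letter sets by the first (display-order) group they contain
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (grp in sets[[i]]) out[grp] <- paste0(out[grp], letters[i])
  }
  out
}

#' Test for a pH effect on growth rate within one strain
#'
#' Kruskal-Wallis test of growth-rate records across pH conditions, followed
#' by Dunn's pairwise post-hoc tests with Benjamini-Hochberg FDR adjustment
#' and a compact letter display at the declared threshold. Conditions sharing
#' a letter are statistically indistinguishable.
#'
#' @param records Data frame as from [period_rates()] (needs `ph` and `mu`),
#'   typically already filtered to one strain.
#' @param strain Optional strain id; if given, `records` is filtered to it.
#' @param alpha FDR threshold for the letter display (default .05).
#'
#' @return List of class `growth_test` with `strain`, `kw_p`, `dunn` (data
#'   frame from [dunn_test()]), `letters` (named by condition, ordered by
#'   decreasing median), and `medians`.
#' @export
test_ph_effect <- function(records, strain = NULL, alpha = 0.05) {
  if (!is.null(strain)) records <- records[records$strain == strain, , drop = FALSE]
  g <- factor(records$ph)
  if (nlevels(g) < 2L) stop("test_ph_effect: need records from >= 2 conditions")
  if (any(tapply(records$mu, g, length) < 2L))
    stop("test_ph_effect: need >= 2 records per condition")
  medians <- tapply(records$mu, g, stats::median)
  ord <- names(sort(medians, decreasing = TRUE))
  if (length(unique(records$mu)) == 1L) {
    warning("test_ph_effect: all growth rates tied; degenerate case, p = 1")
    kw_p <- 1
    dunn <- dunn_test(records$mu, g)
    dunn$p <- 1; dunn$fdr <- 1; dunn$z <- 0
  } else {
    kw_p <- stats::kruskal.test(records$mu, g)$p.value
    dunn <- dunn_test(records$mu, g)
  }
  sig <- dunn[dunn$fdr < alpha, c("group1", "group2"), drop = FALSE]
  letters_map <- compact_letters(ord, sig)
  structure(list(strain = if (is.null(strain)) unique(records$strain) else strain,
                 kw_p = kw_p, dunn = dunn,
                 letters = letters_map[levels(g)],
                 medians = medians, alpha = alpha),
            class = "growth_test")
}

#' Classify a strain's growth pattern across the pH gradient
#'
#' Rule set distilled from the observed response classes:
#' \itemize{
#'   \item \emph{acid_intolerant}: the population collapses under acidic
#'     conditions (median growth rate at the lowest pH < 0);
#'   \item \emph{acidophile}: growth at the lowest pH is positive AND
#'     significantly fastest (its condition holds a letter shared with no
#'     other condition, and the highest median);
#'   \item \emph{generalist}: all medians positive otherwise.
#' }
#' The thresholds (median < 0 as collapse) are a heuristic reading of the
#' narrative classes; a configuration outside all three rules returns `NA`
#' with a warning.
#'
#' @param medians Named numeric vector of per-condition median growth rates
#'   (names are pH labels).
#' @param letters Named character vector of compact letters per condition, as
#'   from [test_ph_effect()].
#' @param acid_ph Label of the acidic condition; defaults to the numerically
#'   lowest pH among the names of `medians`.
#'
#' @return One of `"acidophile"`, `"generalist"`, `"acid_intolerant"`, or
#'   `NA_character_`.
#' @export
classify_growth_pattern <- function(medians, letters, acid_ph = NULL) {
  if (is.null(acid_ph))
    acid_ph <- names(medians)[which.min(as.numeric(names(medians)))]
  if (!acid_ph %in% names(medians) || !acid_ph %in% names(letters))
    stop("classify_growth_pattern: acidic condition '", acid_ph,
         "' missing from medians or letters")
  if (anyNA(medians)) stop("classify_growth_pattern: missing condition medians")
  acid_med <- medians[[acid_ph]]
  if (acid_med < 0) return("acid_intolerant")
  others <- setdiff(names(medians), acid_ph)
  acid_letters <- strsplit(letters[[acid_ph]], "")[[1]]
  shared <- any(vapply(others, function(o)
    any(strsplit(letters[[o]], "")[[1]] %in% acid_letters), logical(1)))
  if (acid_med > 0 && !shared && acid_med == max(medians)) return("acidophile")
  if (all(medians > 0)) return("generalist")
  warning("classify_growth_pattern: configuration matches no pattern; NA")
  NA_character_
}
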