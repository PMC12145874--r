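#' Configuration for the growth-series simulator
#'
#' Defines a common-garden design: a panel of strains grown under several pH
#' conditions, each strain x pH combination replicated over wells, with
#' fluorescence read at the boundaries of consecutive growth periods.
#'
#' @param strains Character vector of strain identifiers.
#' @param ph Numeric vector of pH condition labels (e.g. `c(4.7, 7.0, 8.2)`).
#' @param n_wells Number of replicate wells per strain x pH combination.
#' @param n_periods Number of growth periods; each series has `n_periods + 1`
#'   readings.
#' @param period_length Length of one growth period in days.
#' @param mu_true Data frame with columns `strain`, `ph`, `mu` giving the true
#'   per-day exponential growth rate for every strain x pH combination.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise applied to every reading. `0` disables noise.
#' @param rfu0 Initial relative fluorescence units (RFU) at inoculation.
#'
#' @return An object of class `growth_sim_config`.
#' @export
growth_sim_config <- function(strains, ph, n_wells = 4L, n_periods = 4L,
                              period_length = 3, mu_true = NULL,
                              noise_cv = 0.05, rfu0 = 100) {
  if (length(strains) < 1L) stop("invalid growth_sim_config: 'strains' must be non-empty")
  if (length(ph) < 1L) stop("invalid growth_sim_config: 'ph' must be non-empty")
  if (n_wells < 1L) stop("invalid growth_sim_config: 'n_wells' must be >= 1")
  if (n_periods < 1L) stop("invalid growth_sim_config: 'n_periods' must be >= 1")
  if (period_length <= 0) stop("invalid growth_sim_config: 'period_length' must be > 0")
  if (noise_cv < 0) stop("invalid growth_sim_config: 'noise_cv' must be >= 0")
  if (rfu0 <= 0) stop("invalid growth_sim_config: 'rfu0' must be > 0")
  if (is.null(mu_true)) {
    mu_true <- expand.grid(strain = strains, ph = ph,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu_true$mu <- 0.3
  }
  mu_true <- as.data.frame(mu_true, stringsAsFactors = FALSE)
  need <- c("strain", "ph", "mu")
  if (!all(need %in% names(mu_true)))
    stop("invalid growth_sim_config: 'mu_true' must have columns strain, ph, mu")
  combos <- expand.grid(strain = strains, ph = ph,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(combos$strain, combos$ph)
  have <- paste(mu_true$strain, mu_true$ph)
  if (!all(key %in% have))
    stop("invalid growth_sim_config: 'mu_true' is missing strain x ph combinations: ",
         paste(setdiff(key, have), collapse = ", "))
  structure(list(strains = as.character(strains), ph = as.numeric(ph),
                 n_wells = as.integer(n_wells), n_periods = as.integer(n_periods),
                 period_length = period_length, mu_true = mu_true,
                 noise_cv = noise_cv, rfu0 = rfu0),
            class = "growth_sim_config")
}

#' Simulate fluorescence growth series
#'
#' Generates exponential growth trajectories with multiplicative lognormal
#' measurement noise, emulating well-plate fluorescence monitoring over
#' consecutive growth periods. The noise multiplier has mean 1, so the expected
#' log-increment over one period equals `mu * period_length` and readings are
#' always positive.
#'
#' @param config A [growth_sim_config()] object.
#' @param seed Integer seed; identical config + seed reproduce identical output.
#'
#' @return A list with `series`, a data frame with columns `well_id`, `strain`,
#'   `ph`, `time_days`, `rfu` (long format, one row per reading), and `truth`,
#'   a list carrying the generating `mu_true` table.
#' @export
simulate_growth <- function(config, seed = 1L) {
  stopifnot(inherits(config, "growth_sim_config"))
  set.seed(as.integer(seed))
  times <- seq(0, by = config$period_length, length.out = config$n_periods + 1L)
  mu_key <- paste(config$mu_true$strain, config$mu_true$ph)
  out <- vector("list", length(config$strains) * length(config$ph))
  k <- 0L
  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  for (s in config$strains) {
    for (p in config$ph) {
      mu <- config$mu_true$mu[match(paste(s, p), mu_key)]
      for (w in seq_len(config$n_wells)) {
        expected <- config$rfu0 * exp(mu * times)
        noise <- if (sdlog > 0) {
          exp(stats::rnorm(length(times), mean = -sdlog^2 / 2, sd = sdlog))
        } else rep(1, length(times))
        k <- k + 1L
        out[[k]] <- data.frame(
          well_id = sprintf("%s_pH%s_w%02d", s, format(p), w),
          strain = s, ph = p, time_days = times,
          rfu = expected * noise, stringsAsFactors = FALSE)
      }
    }
  }
  list(series = do.call(rbind, out),
       truth = list(mu_true = config$mu_true))
}

#' Configuration for the differential-expression simulator
#'
#' Describes one synthetic strain x contrast dataset: a gene universe, a
#' collection of (possibly overlapping) gene sets, a subset of sets planted
#' with a directional differential-expression signal, and the null behaviour
#' of the remaining genes.
#'
#' Null genes draw their FDR from a Beta(`fdr_alpha_shape`, 1) distribution;
#' by default the shape is chosen so that the probability of a null gene
#' falling below the 0.01 significance cut-off equals `deg_rate_null`.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_sets Number of gene sets.
#' @param set_size_range Length-2 integer vector, inclusive bounds on set size.
#' @param frac_enriched_sets,frac_depleted_sets Fractions of sets planted with
#'   an upregulation (enriched) or downregulation (depleted) signal.
#' @param deg_rate_null Probability that a null gene crosses the FDR < .01
#'   threshold.
#' @param effect_deg_rate Probability that a gene inside a planted set is a
#'   differentially expressed gene (DEG).
#' @param effect_unidirectional If `TRUE`, all planted-set DEGs share one
#'   direction (up in enriched sets, down in depleted sets).
#' @param fdr_alpha_shape Optional shape of the null Beta(shape, 1) FDR
#'   distribution; overrides the value derived from `deg_rate_null`.
#' @param emit_cpm If `TRUE`, also emit a replicate-level CPM matrix (3
#'   replicates per contrast condition) consistent with the DE table.
#'
#' @return An object of class `de_sim_config`.
#' @export
de_sim_config <- function(n_genes = 5000L, n_sets = 100L,
                          set_size_range = c(10L, 30L),
                          frac_enriched_sets = 0.1, frac_depleted_sets = 0.1,
                          deg_rate_null = 0.02, effect_deg_rate = 0.8,
                          effect_unidirectional = TRUE,
                          fdr_alpha_shape = NULL, emit_cpm = FALSE) {
  if (n_genes < 2L) stop("invalid de_sim_config: 'n_genes' must be >= 2")
  if (n_sets < 0L) stop("invalid de_sim_config: 'n_sets' must be >= 0")
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2])
    stop("invalid de_sim_config: 'set_size_range' must be (min, max) with min <= max")
  if (set_size_range[1] < 2L || set_size_range[2] > n_genes)
    stop("invalid de_sim_config: 'set_size_range' must lie within [2, n_genes]")
  for (nm in c("frac_enriched_sets", "frac_depleted_sets", "deg_rate_null",
               "effect_deg_rate")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop("invalid de_sim_config: '", nm, "' must be in [0, 1]")
  }
  if (frac_enriched_sets + frac_depleted_sets > 1)
    stop("invalid de_sim_config: 'frac_enriched_sets' + 'frac_depleted_sets' must be <= 1")
  if (is.null(fdr_alpha_shape)) {
    fdr_alpha_shape <- if (deg_rate_null > 0) log(deg_rate_null) / log(0.01) else Inf
  }
  structure(list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 frac_enriched_sets = frac_enriched_sets,
                 frac_depleted_sets = frac_depleted_sets,
                 deg_rate_null = deg_rate_null,
                 effect_deg_rate = effect_deg_rate,
                 effect_unidirectional = isTRUE(effect_unidirectional),
                 fdr_alpha_shape = fdr_alpha_shape,
                 emit_cpm = isTRUE(emit_cpm)),
            class = "de_sim_config")
}

#' Simulate a differential-expression table with planted gene-set signals
#'
#' Builds a gene universe, samples gene sets without replacement within the
#' configured size range (sets may overlap), plants enriched/depleted signals
#' in a fraction of them, and draws per-gene FDR and log2 fold-change values.
#' Planted-effect genes are forced below the 0.01 FDR threshold with the
#' planted direction; all other genes draw FDR from Beta(shape, 1) with a
#' random fold-change sign. The truth object records the planted set labels
#' and the REALIZED per-gene DEG labels (fdr < .01, signed by log2fc), which
#' downstream DEG calling must recover exactly.
#'
#' @param config A [de_sim_config()] object.
#' @param seed Integer seed.
#' @param strain,contrast Identifiers stamped on the emitted DE table
#'   (contrast is `c(low_ph, high_ph)`).
#'
#' @return A list with `de` (data frame `gene_id`, `log2fc`, `fdr`), `sets`
#'   (a [gene_set_collection()]), `truth` (list with `planted_sets`,
#'   `deg_labels`, `planted_genes`), and optionally `cpm` (matrix) with
#'   `cpm_samples` metadata when `emit_cpm` is set.
#' @export
simulate_de <- function(config, seed = 1L, strain = "S1",
                        contrast = c(4.7, 8.2)) {
  stopifnot(inherits(config, "de_sim_config"))
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(config$n_genes))

  # gene sets: independent sampling, overlaps allowed
  sizes <- if (config$n_sets > 0)
    sample(seq(config$set_size_range[1], config$set_size_range[2]),
           config$n_sets, replace = TRUE) else integer(0)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("set%04d", seq_along(sets))

  n_enr <- round(config$frac_enriched_sets * config$n_sets)
  n_dep <- round(config$frac_depleted_sets * config$n_sets)
  planted <- rep("null", config$n_sets)
  if (n_enr + n_dep > 0) {
    pick <- sample(config$n_sets, n_enr + n_dep)
    planted[pick[seq_len(n_enr)]] <- "enriched"
    if (n_dep > 0) planted[pick[n_enr + seq_len(n_dep)]] <- "depleted"
  }
  names(planted) <- names(sets)

  # per-gene planted effect: first planting wins on overlap
  effect_dir <- setNames(rep("none", config$n_genes), genes)
  for (i in seq_along(sets)) {
    if (planted[i] == "null") next
    members <- sets[[i]]
    hit <- members[stats::runif(length(members)) < config$effect_deg_rate]
    hit <- hit[effect_dir[hit] == "none"]
    dir <- if (planted[i] == "enriched") "up" else "down"
    if (!config$effect_unidirectional && length(hit) > 0) {
      effect_dir[hit] <- sample(c("up", "down"), length(hit), replace = TRUE)
    } else {
      effect_dir[hit] <- dir
    }
  }

  fdr <- numeric(config$n_genes)
  sign_lfc <- numeric(config$n_genes)
  is_effect <- effect_dir != "none"
  # planted DEGs: FDR uniform below the .01 cut-off, direction as planted
  fdr[is_effect] <- stats::runif(sum(is_effect), 0, 0.01 - 1e-12)
  sign_lfc[is_effect] <- ifelse(effect_dir[is_effect] == "up", 1, -1)
  n_null <- sum(!is_effect)
  fdr[!is_effect] <- if (is.finite(config$fdr_alpha_shape))
    stats::rbeta(n_null, config$fdr_alpha_shape, 1) else
    pmin(1, 1 - stats::runif(n_null, 0, 1e-9))  # deg_rate_null = 0
  sign_lfc[!is_effect] <- sample(c(-1, 1), n_null, replace = TRUE)
  log2fc <- sign_lfc * stats::rlnorm(config$n_genes, meanlog = 0.3, sdlog = 0.6)

  de <- data.frame(gene_id = genes, log2fc = log2fc, fdr = fdr,
                   stringsAsFactors = FALSE)
  attr(de, "strain") <- strain
  attr(de, "contrast") <- contrast

  realized <- ifelse(fdr < 0.01, ifelse(log2fc > 0, "up", "down"), "none")
  truth <- list(planted_sets = planted,
                deg_labels = setNames(realized, genes),
                planted_genes = effect_dir)

  coll <- gene_set_collection(sets,
                              set_type = setNames(rep("GO", length(sets)),
                                                  names(sets)),
                              universe = genes)
  out <- list(de = de, sets = coll, truth = truth)

  if (config$emit_cpm) {
    base_mean <- stats::rlnorm(config$n_genes, meanlog = 4, sdlog = 1.5)
    fc <- rep(1, config$n_genes)
    fc[is_effect] <- 2^(log2fc[is_effect])
    mu_low <- base_mean * fc    # low-pH condition carries the fold change
    mu_high <- base_mean
    counts <- cbind(
      sapply(1:3, function(i) stats::rnbinom(config$n_genes, mu = mu_low, size = 10)),
      sapply(1:3, function(i) stats::rnbinom(config$n_genes, mu = mu_high, size = 10)))
    cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
    rownames(cpm) <- genes
    samples <- data.frame(
      sample = sprintf("%s_pH%s_rep%d", strain, rep(format(contrast), each = 3), rep(1:3, 2)),
      strain = strain, ph = rep(contrast, each = 3), replicate = rep(1:3, 2),
      stringsAsFactors = FALSE)
    colnames(cpm) <- samples$sample
    out$cpm <- cpm
    out$cpm_samples <- samples
  }
  out
}

#' Simulate a toy ontology DAG with gene annotations
#'
#' Builds a rooted directed acyclic graph of `n_terms` terms in which every
#' non-root term has at least one parent and every root-to-leaf path has at
#' most `max_depth` edges (terms carry strictly increasing depths along any
#' edge), then annotates genes with random leaf-ward terms. The edge table is
#' the contract consumed by [propagate_ancestors()].
#'
#' @param n_terms Number of terms (>= 1); the first is the root.
#' @param max_depth Maximum root-to-leaf path length in edges.
#' @param seed Integer seed.
#' @param n_genes Number of genes to annotate.
#' @param extra_parent_prob Probability that a non-root term receives a second
#'   parent (making the graph a genuine DAG rather than a tree).
#'
#' @return A list with `edges` (data frame `child`, `parent`), `root`,
#'   `depth` (named integer vector), and `annotations` (named list
#'   gene -> character vector of directly assigned terms).
#' @export
simulate_ontology <- function(n_terms, max_depth = 4L, seed = 1L,
                              n_genes = 20L, extra_parent_prob = 0.3) {
  if (n_terms < 1L) stop("invalid configuration: 'n_terms' must be >= 1")
  if (max_depth < 1L) stop("invalid configuration: 'max_depth' must be >= 1")
  set.seed(as.integer(seed))
  terms <- sprintf("T%04d", seq_len(n_terms))
  depth <- setNames(integer(n_terms), terms)
  edges <- list()
  for (i in seq_len(n_terms)[-1]) {
    eligible <- terms[seq_len(i - 1L)][depth[seq_len(i - 1L)] < max_depth]
    if (length(eligible) == 0L) eligible <- terms[1L]
    parent <- sample(eligible, 1L)
    depth[i] <- depth[parent] + 1L
    edges[[length(edges) + 1L]] <- c(terms[i], parent)
    shallower <- terms[seq_len(i - 1L)][depth[seq_len(i - 1L)] < depth[i]]
    shallower <- setdiff(shallower, parent)
    if (length(shallower) > 0 && stats::runif(1) < extra_parent_prob) {
      edges[[length(edges) + 1L]] <- c(terms[i], sample(shallower, 1L))
    }
  }
  edge_df <- if (length(edges) > 0) {
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE) |>
      stats::setNames(c("child", "parent"))
  } else data.frame(child = character(0), parent = character(0))
  genes <- sprintf("g%05d", seq_len(n_genes))
  annotations <- lapply(genes, function(g)
    sample(terms, min(length(terms), sample(1:3, 1L))))
  names(annotations) <- genes
  list(edges = edge_df, root = terms[1L], depth = depth,
       annotations = annotations)
}
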