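#' Write/read tab-separated tables with pipeline conventions
#'
#' Plain-text TSV, no quoting, no row names; the on-disk interchange format
#' for every stage output.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `path` (write) or a data frame (read), invisibly for write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' Bundles simulation settings, contrasts and analysis thresholds, with the
#' defaults used throughout: DEG FDR cut-off .01, growth FDR cut-off .05,
#' expression filter CPM >= 1 in >= 2 replicates, UGS minimum of 2
#' same-direction DEGs. A single seed is fanned out to stage-specific
#' derived seeds so stages are independently reproducible.
#'
#' @param strains Character vector of strain ids.
#' @param ph Numeric pH conditions, low to high.
#' @param mu_true Optional data frame `strain`, `ph`, `mu` of true growth
#'   rates for the growth simulator.
#' @param contrasts Data frame with columns `strain`, `low_ph`, `high_ph`;
#'   defaults to every strain x every low-vs-high pH pair.
#' @param growth Named list of overrides for [growth_sim_config()].
#' @param de Named list of overrides for [de_sim_config()].
#' @param deg_alpha,growth_alpha,min_cpm,min_reps,ugs_min_degs,n_perm
#'   Analysis thresholds.
#' @param seed Master integer seed.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(strains, ph = c(4.7, 7.0, 8.2), mu_true = NULL,
                       contrasts = NULL, growth = list(), de = list(),
                       deg_alpha = 0.01, growth_alpha = 0.05,
                       min_cpm = 1, min_reps = 2L, ugs_min_degs = 2L,
                       n_perm = 2000L, seed = 1L) {
  ph <- sort(as.numeric(ph))
  if (is.null(contrasts)) {
    pairs <- utils::combn(ph, 2L)
    contrasts <- do.call(rbind, lapply(strains, function(s)
      data.frame(strain = s, low_ph = pairs[1, ], high_ph = pairs[2, ],
                 stringsAsFactors = FALSE)))
  }
  if (!all(c("strain", "low_ph", "high_ph") %in% names(contrasts)))
    stop("run_config: 'contrasts' needs columns strain, low_ph, high_ph")
  if (!all(contrasts$strain %in% strains))
    stop("run_config: contrasts reference undeclared strains")
  if (!all(c(contrasts$low_ph, contrasts$high_ph) %in% ph))
    stop("run_config: contrasts reference undeclared pH conditions")
  if (any(contrasts$low_ph >= contrasts$high_ph))
    stop("run_config: contrast orientation must be low_ph < high_ph")
  for (nm in c("deg_alpha", "growth_alpha")) {
    v <- get(nm)
    if (v <= 0 || v > 1) stop("run_config: '", nm, "' must be in (0, 1]")
  }
  structure(list(strains = strains, ph = ph, mu_true = mu_true,
                 contrasts = contrasts, growth = growth, de = de,
                 deg_alpha = deg_alpha, growth_alpha = growth_alpha,
                 min_cpm = min_cpm, min_reps = as.integer(min_reps),
                 ugs_min_degs = as.integer(ugs_min_degs),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()]
#'   (`mu_true` and `contrasts` as lists of records).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  args <- y
  args$mu_true <- to_df(y$mu_true)
  args$contrasts <- to_df(y$contrasts)
  do.call(run_config, args)
}

stage_seed <- function(seed, k) (as.integer(seed) %% 20000L) * 100000L + k

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage in order — growth simulation, per-period growth
#' rates, Kruskal-Wallis/Dunn tests and growth-pattern classification;
#' per-contrast DE simulation, DEG calling with SLFDR scores, the three
#' enrichment analyses and composite calls; strain-pH enrichment groups and
#' their sqrt-Jaccard response clustering — writing each stage's tables
#' under `out_dir` together with a JSON manifest (config echo, seed,
#' per-stage row counts, md5 checksums of every output). Re-running with an
#' identical config reproduces identical tables.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param heatmap If `TRUE` (default), also render the heatmap PNGs.
#'
#' @return Invisible list with all in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, heatmap = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv(x, p)
    written <<- c(written, p)
    p
  }
  fail <- function(stage, e) {
    manifest <- list(status = "failed", stage = stage,
                     error = conditionMessage(e), outputs = written)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- growth ---------------------------------------------------------------
  res <- list()
  tryCatch({
    gcfg <- do.call(growth_sim_config, c(
      list(strains = config$strains, ph = config$ph, mu_true = config$mu_true),
      config$growth))
    sim <- simulate_growth(gcfg, seed = stage_seed(config$seed, 1L))
    emit(sim$series, "growth_series.tsv")
    rates <- period_rates(sim$series)
    emit(rates, "growth_rates.tsv")
    tests <- lapply(config$strains, function(s)
      test_ph_effect(rates, strain = s, alpha = config$growth_alpha))
    names(tests) <- config$strains
    test_tbl <- do.call(rbind, lapply(tests, function(t)
      data.frame(strain = t$strain, kw_p = t$kw_p,
                 ph = names(t$medians), median_mu = as.numeric(t$medians),
                 letter = unname(t$letters[names(t$medians)]),
                 stringsAsFactors = FALSE)))
    emit(test_tbl, "growth_tests.tsv")
    classes <- vapply(tests, function(t)
      classify_growth_pattern(t$medians, t$letters), character(1))
    emit(data.frame(strain = names(classes), pattern = unname(classes),
                    stringsAsFactors = FALSE), "growth_patterns.tsv")
    res$growth <- list(sim = sim, rates = rates, tests = tests,
                       patterns = classes)
  }, error = function(e) fail("growth", e))

  # -- scoring + enrichment per contrast ------------------------------------
  tryCatch({
    contrasts <- config$contrasts
    scored_all <- list(); enrich_all <- list(); groups <- list()
    for (i in seq_len(nrow(contrasts))) {
      s <- contrasts$strain[i]
      lo <- contrasts$low_ph[i]; hi <- contrasts$high_ph[i]
      dcfg <- do.call(de_sim_config, config$de)
      dsim <- simulate_de(dcfg, seed = stage_seed(config$seed, 10L + i),
                          strain = s, contrast = c(lo, hi))
      universe <- if (!is.null(dsim$cpm))
        cpm_filter(dsim$cpm, config$min_cpm, config$min_reps)
        else dsim$de$gene_id
      de <- dsim$de[dsim$de$gene_id %in% universe, , drop = FALSE]
      scored <- call_degs(de, alpha = config$deg_alpha)
      tag <- sprintf("%s_%dv%d", s, trunc(lo), trunc(hi))
      emit(scored, paste0("scored_", tag, ".tsv"))
      enr <- run_enrichment(scored, dsim$sets, alpha = config$deg_alpha,
                            n_perm = config$n_perm,
                            ugs_min_degs = config$ugs_min_degs,
                            seed = stage_seed(config$seed, 50L + i))
      emit(enr$composite, paste0("composite_", tag, ".tsv"))
      gr <- build_groups(enr$composite, s, c(lo, hi))
      scored_all[[tag]] <- scored
      enrich_all[[tag]] <- enr
      groups <- c(groups, gr)
    }
    res$scored <- scored_all
    res$enrichment <- enrich_all
    res$groups <- groups
  }, error = function(e) fail("enrichment", e))

  # -- response clustering --------------------------------------------------
  tryCatch({
    d <- suppressMessages(jaccard_sqrt_distance(res$groups))
    ord <- order_groups(d)
    emit(data.frame(label = ord$order, position = seq_along(ord$order),
                    stringsAsFactors = FALSE), "group_order.tsv")
    prefix <- file.path(out_dir, "response_distance")
    if (heatmap) {
      export_heatmap(d, ord$order, prefix)
      written <- c(written, paste0(prefix, ".tsv"))
    } else {
      m <- unclass(d)[ord$order, ord$order]
      emit(data.frame(label = rownames(m), m, check.names = FALSE),
           "response_distance.tsv")
    }
    res$distance <- d
    res$order <- ord
  }, error = function(e) fail("clustering", e))

  manifest <- list(
    status = "ok",
    seed = config$seed,
    config_hash = unname(tools::md5sum(
      local({ f <- tempfile(); saveRDS(config, f, version = 2); f }))),
    n_strains = length(config$strains),
    n_contrasts = nrow(config$contrasts),
    n_groups = length(res$groups),
    composite_calls = sum(vapply(res$enrichment, function(e)
      sum(e$composite$enriched) + sum(e$composite$depleted), numeric(1))),
    outputs = lapply(written, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)),
           rows = if (grepl("\\.tsv$", p)) nrow(read_tsv(p)) else NA))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
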