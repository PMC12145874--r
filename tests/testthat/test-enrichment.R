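test_that("FCS flags maximal separation as enriched at the attainable floor", {
  scores <- setNames(c(rep(-10, 5), rep(0, 95)), sprintf("g%03d", 1:100))
  res <- fcs_test(scores, sprintf("g%03d", 1:5), n_perm = 999, seed = 1,
                  exact_limit = 0)
  expect_equal(res$direction, "enriched")
  expect_lte(res$p, 2 * (1 + 0) / (999 + 1))

  expect_error(fcs_test(scores, names(scores)), "equals the universe")
  expect_error(fcs_test(scores, "nope"), "empty")
})

test_that("FCS small-universe p equals exhaustive enumeration over equal-size subsets", {
  set.seed(5)
  for (rep in 1:10) {
    N <- sample(6:10, 1)
    n <- sample(2:4, 1)
    scores <- setNames(round(rnorm(N), 2), sprintf("g%02d", 1:N))
    if (rep %% 2 == 0) scores[2] <- scores[1]  # inject ties
    members <- sample(names(scores), n)
    res <- fcs_test(scores, members, exact_limit = 1e5)
    # oracle: enumerate every size-n subset, two-sided tail of the rank sum
    r <- rank(scores)
    W <- sum(r[members])
    subsets <- combn(seq_len(N), n)
    sums <- apply(subsets, 2, function(ix) sum(r[ix]))
    p_oracle <- min(1, 2 * min(mean(sums <= W + 1e-9),
                               mean(sums >= W - 1e-9)))
    expect_identical(res$p, p_oracle)
    expect_identical(res$statistic, W)
  }
})

test_that("FCS sampling p is invariant under monotone score transforms", {
  set.seed(6)
  scores <- setNames(rnorm(60), sprintf("g%02d", 1:60))
  members <- sample(names(scores), 8)
  a <- fcs_test(scores, members, n_perm = 500, seed = 11, exact_limit = 0)
  b <- fcs_test(exp(scores) + 5, members, n_perm = 500, seed = 11,
                exact_limit = 0)
  expect_identical(a$p, b$p)
  expect_identical(a$direction, b$direction)
})

test_that("FCS null sets are rarely called at FDR .01", {
  set.seed(7)
  scores <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  scored_like <- data.frame(gene_id = names(scores))
  calls <- lapply(1:50, function(i)
    fcs_test(scores, sample(names(scores), 15), n_perm = 400, seed = i,
             exact_limit = 0))
  fcs_tbl <- cbind(data.frame(set_id = sprintf("N%02d", 1:50)),
                   do.call(rbind, calls))
  comp <- adjust_and_combine(fcs = fcs_tbl, ora = NULL, ugs = NULL) |>
    suppressWarnings()
  expect_lte(sum(comp$enriched) + sum(comp$depleted), 2)
})

test_that("ORA matches hand-computed 2x2 chi-square tables", {
  # universe 1000, 20 up DEGs, a set of 10 holding 8 of them
  labels <- rep("none", 1000)
  labels[1:20] <- "up"
  scored <- make_scored(labels, seed = 1)
  members <- scored$gene_id[c(1:8, 21, 22)]
  # no down DEGs exist, so the down-direction table degenerates with a warning
  expect_warning(res <- ora_test(scored, members), "degenerate")
  chisq_2x2 <- function(k_in, n_in, k_out, n_out) {
    tab <- matrix(c(k_in, n_in - k_in, k_out, n_out - k_out), 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  expect_equal(res$p_up, chisq_2x2(8, 10, 12, 990))
  expect_true(res$up_excess)
  expect_equal(res$n_deg_up, 8)

  # proportions identical inside and out -> zero statistic, p = 1
  labels2 <- rep(c("up", "none"), c(100, 900))
  scored2 <- make_scored(labels2, seed = 2)
  members2 <- scored2$gene_id[c(1:10, 101:190)]  # 10% up, as outside
  res2 <- suppressWarnings(ora_test(scored2, members2))
  expect_equal(res2$p_up, 1)
  expect_false(res2$up_excess)

  # both directions over-represented in one set
  labels3 <- rep("none", 1000)
  labels3[1:4] <- "up"; labels3[5:8] <- "down"
  labels3[900:905] <- "up"; labels3[906:911] <- "down"
  scored3 <- make_scored(labels3, seed = 3)
  members3 <- scored3$gene_id[c(1:8, 20, 21)]
  res3 <- ora_test(scored3, members3)
  expect_equal(res3$p_up, chisq_2x2(4, 10, 6, 990))
  expect_equal(res3$p_down, chisq_2x2(4, 10, 6, 990))
  expect_true(res3$up_excess && res3$down_excess)

  # no DEGs anywhere -> degenerate margin, p = 1 with a warning
  scored4 <- make_scored(rep("none", 50), seed = 4)
  w <- capture_warnings(res4 <- ora_test(scored4, scored4$gene_id[1:5]))
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(res4$p_up, 1)
})

test_that("UGS implements the exclusive-direction criterion", {
  expect_equal(ugs_call(c("up", "up", "none", "none"))$direction, "enriched")
  expect_equal(ugs_call(c("up", "down"))$direction, "none")
  expect_equal(ugs_call(c("down", "down", "down"))$direction, "depleted")
  expect_equal(ugs_call("up")$direction, "none")          # below min_degs
  expect_equal(ugs_call("up", min_degs = 1)$direction, "enriched")
})

test_that("UGS equals a brute-force label scan on simulated data", {
  for (seed in 1:10) {
    cfg <- de_sim_config(n_genes = 300, n_sets = 25, set_size_range = c(4, 15),
                         frac_enriched_sets = 0.2, frac_depleted_sets = 0.2,
                         deg_rate_null = 0.05, effect_deg_rate = 0.7)
    sim <- simulate_de(cfg, seed = seed)
    scored <- call_degs(sim$de)
    labels <- setNames(scored$deg_label, scored$gene_id)
    for (id in names(sim$sets$sets)) {
      m <- sim$sets$sets[[id]]
      got <- ugs_call(labels[m])$direction
      ups <- sum(labels[m] == "up"); dns <- sum(labels[m] == "down")
      want <- if (ups >= 2 && dns == 0) "enriched"
        else if (dns >= 2 && ups == 0) "depleted" else "none"
      expect_identical(got, want)
    }
  }
})

test_that("composite calls take the union over methods with recorded support", {
  fcs <- data.frame(set_id = c("A", "B"), n_set = 5, statistic = 1,
                    direction = c("enriched", "depleted"), p = c(0.5, 1e-5))
  ora <- data.frame(set_id = c("A", "B"), n_set = 5, n_deg_up = c(0, 0),
                    n_deg_down = c(0, 4), p_up = c(1, 1), p_down = c(1, 1e-6),
                    up_excess = FALSE, down_excess = c(FALSE, TRUE))
  ugs <- data.frame(set_id = c("A", "B"), n_set = 5, n_deg_up = c(3, 0),
                    n_deg_down = 0, direction = c("enriched", "none"))
  comp <- adjust_and_combine(fcs = fcs, ora = ora, ugs = ugs, alpha = 0.01)
  a <- comp[comp$set_id == "A", ]
  expect_true(a$enriched); expect_false(a$depleted)
  expect_equal(a$methods_enriched, "UGS")       # only UGS supports A
  b <- comp[comp$set_id == "B", ]
  expect_true(b$depleted)
  expect_equal(b$methods_depleted, "FCS,ORA")
  # BH never decreases a raw p
  expect_true(all(comp$ora_fdr_down >= ora$p_down))
  expect_warning(adjust_and_combine(ugs = ugs), "available methods")
})

test_that("a set enriched by FCS and depleted by ORA carries both flags", {
  fcs <- data.frame(set_id = "X", n_set = 10, statistic = 1,
                    direction = "enriched", p = 1e-6)
  ora <- data.frame(set_id = "X", n_set = 10, n_deg_up = 0, n_deg_down = 6,
                    p_up = 1, p_down = 1e-8, up_excess = FALSE,
                    down_excess = TRUE)
  comp <- suppressWarnings(adjust_and_combine(fcs = fcs, ora = ora))
  expect_true(comp$enriched && comp$depleted)
})

test_that("strong unidirectional signals get consistent UGS and FCS directions", {
  cfg <- de_sim_config(n_genes = 1000, n_sets = 10, set_size_range = c(15, 25),
                       frac_enriched_sets = 0.3, frac_depleted_sets = 0.2,
                       deg_rate_null = 0.02, effect_deg_rate = 1,
                       effect_unidirectional = TRUE)
  sim <- simulate_de(cfg, seed = 31)
  scored <- call_degs(sim$de)
  enr <- run_enrichment(scored, sim$sets, n_perm = 1000, seed = 32)
  planted <- sim$truth$planted_sets[sim$truth$planted_sets != "null"]
  for (id in names(planted)) {
    ugs_dir <- enr$ugs$direction[enr$ugs$set_id == id]
    fcs_dir <- enr$fcs$direction[enr$fcs$set_id == id]
    if (ugs_dir != "none") expect_identical(fcs_dir, ugs_dir)
    # the planted direction is recovered by the composite
    flag <- if (planted[[id]] == "enriched") "enriched" else "depleted"
    expect_true(enr$composite[[flag]][enr$composite$set_id == id])
  }
})

test_that("run_enrichment is reproducible under a fixed seed", {
  cfg <- de_sim_config(n_genes = 400, n_sets = 12, set_size_range = c(5, 15))
  sim <- simulate_de(cfg, seed = 13)
  scored <- call_degs(sim$de)
  e1 <- run_enrichment(scored, sim$sets, n_perm = 300, seed = 99)
  e2 <- run_enrichment(scored, sim$sets, n_perm = 300, seed = 99)
  expect_identical(e1, e2)
})
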