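test_that("enrichment groups carry the strain_lowDirHigh label scheme", {
  comp <- data.frame(set_id = c("GO:1", "GO:2", "GO:3"),
                     enriched = c(TRUE, FALSE, TRUE),
                     depleted = c(FALSE, TRUE, TRUE))
  gr <- build_groups(comp, "NPAL-12", c(7.0, 8.2))
  expect_equal(gr$En$label, "NPAL-12_7En8")
  expect_equal(gr$Dp$label, "NPAL-12_7Dp8")
  expect_setequal(gr$En$members, c("GO:1", "GO:3"))
  expect_setequal(gr$Dp$members, c("GO:2", "GO:3"))  # 'both' lands in both

  gr2 <- build_groups(comp, "EUNS-26", c(4.7, 8.2))
  expect_equal(gr2$En$label, "EUNS-26_4En8")

  none <- build_groups(comp[0, ], "S", c(4.7, 7.0))
  expect_length(none$En$members, 0)
  expect_equal(none$En$label, "S_4En7")
})

test_that("sqrt-Jaccard distance matches the a/(a+b+c) formula and conventions", {
  g <- function(label, members) list(label = label, members = members)
  d <- jaccard_sqrt_distance(list(g("A", c("x", "y")), g("B", c("x", "y")),
                                  g("C", c("p", "q")), g("D", c("y", "z"))))
  expect_equal(d["A", "B"], 0)            # identical groups
  expect_equal(d["A", "C"], 1)            # disjoint groups
  expect_equal(d["A", "D"], sqrt(1 - 1/3))
  expect_equal(unclass(d), t(unclass(d)))
  expect_equal(diag(unclass(d)), setNames(rep(0, 4), LETTERS[1:4]))

  expect_message(
    de <- jaccard_sqrt_distance(list(g("E1", character(0)),
                                     g("E2", character(0)),
                                     g("F", "x"))),
    "convention")
  expect_equal(de["E1", "E2"], 0)
  expect_equal(de["E1", "F"], 1)

  # ids present in no group do not exist for the distance (vacuous by
  # construction: distances depend only on memberships)
  d2 <- jaccard_sqrt_distance(list(g("A", c("x", "y")), g("D", c("y", "z"))))
  expect_equal(d2["A", "D"], d["A", "D"])
})

test_that("sqrt-Jaccard agrees with vegan and satisfies the triangle inequality", {
  set.seed(12)
  ids <- sprintf("t%02d", 1:12)
  groups <- lapply(1:6, function(i)
    list(label = paste0("G", i), members = sample(ids, sample(2:8, 1))))
  d <- jaccard_sqrt_distance(groups)
  # vegan oracle on the presence/absence matrix
  pa <- t(sapply(groups, function(g) as.integer(ids %in% g$members)))
  rownames(pa) <- sapply(groups, `[[`, "label")
  ref <- sqrt(as.matrix(vegan::vegdist(pa, method = "jaccard", binary = TRUE)))
  expect_equal(unclass(d), ref, ignore_attr = TRUE, tolerance = 1e-12)

  # metric axioms over random triples of small sets
  set.seed(13)
  for (i in 1:500) {
    tri <- lapply(1:3, function(k)
      list(label = paste0("g", k), members = sample(ids, sample(1:6, 1))))
    dd <- jaccard_sqrt_distance(tri)
    expect_lte(dd[1, 2], dd[1, 3] + dd[3, 2] + 1e-12)
    expect_gte(min(dd), 0)
  }
})

test_that("group ordering is deterministic, permutation-invariant, and greedy-consistent", {
  g <- function(label, members) list(label = label, members = members)
  gr <- list(g("A", c("x", "y")), g("B", c("x", "y")), g("C", c("p", "q")))
  d <- jaccard_sqrt_distance(gr)
  ord <- order_groups(d)
  pos <- match(c("A", "B"), ord$order)
  expect_equal(abs(diff(pos)), 1)      # identical pair are adjacent leaves

  # permuted input -> same merge heights and leaf order
  dp <- unclass(d)[c(3, 1, 2), c(3, 1, 2)]
  ordp <- order_groups(dp)
  expect_identical(ordp$order, ord$order)
  expect_equal(ordp$hclust$height, ord$hclust$height)

  # 3-group merge order equals a brute-force minimum-distance scan
  set.seed(3)
  ids <- sprintf("t%02d", 1:10)
  gr3 <- lapply(1:3, function(i)
    list(label = paste0("G", i), members = sample(ids, sample(2:6, 1))))
  d3 <- jaccard_sqrt_distance(gr3)
  hc <- order_groups(d3)$hclust
  m <- unclass(d3)
  off <- which(m == min(m[upper.tri(m)]), arr.ind = TRUE)
  first_pair <- sort(rownames(m)[off[1, ]])
  merged1 <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(merged1, first_pair)

  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(order_groups(bad), "not symmetric")
})

test_that("heatmap export writes an exact symmetric TSV with block structure visible", {
  g <- function(label, members) list(label = label, members = members)
  # two planted blocks sharing members within but not across
  blocks <- list(g("B1a", c("s1", "s2", "s3")), g("B1b", c("s1", "s2", "s4")),
                 g("B2a", c("t1", "t2", "t3")), g("B2b", c("t1", "t2", "t4")))
  d <- jaccard_sqrt_distance(blocks)
  ord <- order_groups(d)$order
  prefix <- file.path(withr::local_tempdir(), "hm")
  export_heatmap(d, ord, prefix)
  tab <- read_tsv(paste0(prefix, ".tsv"))
  m <- as.matrix(tab[, -1]); rownames(m) <- tab$label
  expect_equal(m[ord, ord], unclass(d)[ord, ord], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m, t(m)[rownames(m), colnames(m)], tolerance = 1e-12,
               ignore_attr = TRUE)
  within <- c(m["B1a", "B1b"], m["B2a", "B2b"])
  between <- c(m["B1a", "B2a"], m["B1a", "B2b"], m["B1b", "B2a"])
  expect_true(max(within) < min(between))
  expect_true(file.exists(paste0(prefix, ".png")))

  expect_error(export_heatmap(d, c("B1a", "nope", "B2a", "B2b"), prefix),
               "permutation")
})

test_that("planted similar-response strains cluster together", {
  g <- function(label, members) list(label = label, members = members)
  shared <- sprintf("GO:%02d", 1:8)
  sim1 <- g("S1_4En8", c(shared, "GO:91"))
  sim2 <- g("S2_4En8", c(shared, "GO:92"))
  other1 <- g("S3_4En8", sprintf("K:%02d", 1:7))
  other2 <- g("S4_4En8", sprintf("M:%02d", 1:7))
  d <- jaccard_sqrt_distance(list(sim1, other1, sim2, other2))
  ord <- order_groups(d)$order
  pos <- match(c("S1_4En8", "S2_4En8"), ord)
  expect_equal(abs(diff(pos)), 1)
})
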