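#' Build strain-pH enrichment groups from composite calls
#'
#' Collects the affected gene-set ids of one strain and one pairwise pH
#' contrast into two groups, one per enrichment direction. Group labels are
#' the strain name with the direction code (En, enriched; Dp, depleted)
#' placed between the two pH conditions, with pH values truncated to their
#' integer digit: strain "NPAL-12", contrast pH 7.0 vs 8.2, enriched ->
#' `"NPAL-12_7En8"` (gene sets enriched at pH 7.0 compared to pH 8.2).
#' A set flagged both enriched and depleted appears in both groups; empty
#' groups are retained with an empty member set.
#'
#' @param composite Composite-call data frame from [adjust_and_combine()]
#'   (needs `set_id`, `enriched`, `depleted`), for one strain x contrast.
#' @param strain Strain identifier.
#' @param contrast Numeric length-2 vector `c(low_ph, high_ph)`.
#'
#' @return Named list of two `enrichment_group` objects (`En`, `Dp`), each a
#'   list with `strain`, `contrast`, `direction`, `members`, `label`.
#' @export
build_groups <- function(composite, strain, contrast) {
  stopifnot(length(contrast) == 2L)
  lo <- trunc(as.numeric(contrast[1])); hi <- trunc(as.numeric(contrast[2]))
  mk <- function(direction, code, members) {
    structure(list(strain = strain, contrast = as.numeric(contrast),
                   direction = code,
                   members = sort(unique(as.character(members))),
                   label = sprintf("%s_%d%s%d", strain, lo, code, hi)),
              class = "enrichment_group")
  }
  list(En = mk("enriched", "En", composite$set_id[composite$enriched]),
       Dp = mk("depleted", "Dp", composite$set_id[composite$depleted]))
}

#' Square-root-transformed Jaccard dissimilarity among enrichment groups
#'
#' Treats each group as a presence/absence vector over gene-set ids. For
#' groups A, B with a shared, b and c private members, the Jaccard similarity
#' is \eqn{s = a/(a+b+c)} and the Euclidean-like distance is
#' \eqn{\sqrt{1 - s}}. Two empty groups are at distance 0 by convention
#' (logged via a message); an empty vs a non-empty group is at distance 1.
#' Gene-set ids absent from every group do not affect the distances.
#'
#' @param groups List of `enrichment_group` objects (or plain lists with
#'   `members` and `label`).
#'
#' @return Symmetric matrix of distances in \[0, 1\] with zero diagonal,
#'   labelled by group labels; class `group_distance_matrix`.
#' @export
jaccard_sqrt_distance <- function(groups) {
  if (length(groups) < 2L) stop("jaccard_sqrt_distance: need >= 2 groups")
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop("jaccard_sqrt_distance: duplicate group labels")
  members <- lapply(groups, function(g) unique(g$members))
  k <- length(groups)
  d <- matrix(0, k, k, dimnames = list(labels, labels))
  empty_pair <- FALSE
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- length(intersect(members[[i]], members[[j]]))
      u <- length(union(members[[i]], members[[j]]))
      if (u == 0L) { s <- 1; empty_pair <- TRUE } else s <- a / u
      d[i, j] <- d[j, i] <- sqrt(1 - s)
    }
  }
  if (empty_pair)
    message("jaccard_sqrt_distance: empty group pair(s) at distance 0 by convention")
  class(d) <- c("group_distance_matrix", class(d))
  d
}

#' Order enrichment groups by hierarchical clustering
#'
#' Agglomerative clustering on the group distance matrix (average linkage by
#' default). For determinism under input permutation, rows/columns are
#' sorted lexicographically by label before clustering, so ties are broken
#' by label order.
#'
#' @param d A symmetric distance matrix as from [jaccard_sqrt_distance()].
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"average"`).
#'
#' @return List with `order` (labels in leaf order) and `hclust` (the tree).
#' @export
order_groups <- function(d, linkage = "average") {
  d <- unclass(d)
  if (!isTRUE(all.equal(d, t(d))))
    stop("order_groups: distance matrix is not symmetric")
  idx <- order(rownames(d))
  d <- d[idx, idx, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  list(order = rownames(d)[hc$order], hclust = hc)
}

#' Export a group-distance heatmap and its underlying table
#'
#' Writes the distance matrix, reordered by the given leaf order, as a TSV
#' (exact values) and renders a raster heatmap whose fill gradient starts at
#' the minimum estimated (off-diagonal) distance.
#'
#' @param d Distance matrix from [jaccard_sqrt_distance()].
#' @param order Character vector of labels in display order, as from
#'   [order_groups()]; defaults to the matrix order.
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.png`.
#'
#' @return Invisible list with the paths written.
#' @export
export_heatmap <- function(d, order = rownames(d), path_prefix) {
  d <- unclass(d)
  if (!all(order %in% rownames(d)) || length(order) != nrow(d))
    stop("export_heatmap: 'order' must be a permutation of the matrix labels")
  m <- d[order, order, drop = FALSE]
  tsv <- paste0(path_prefix, ".tsv")
  png_path <- paste0(path_prefix, ".png")
  ok <- tryCatch({
    utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                       tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop("export_heatmap: failed writing ", tsv, ": ", conditionMessage(e)))
  off <- m[upper.tri(m) | lower.tri(m)]
  lo <- if (length(off) > 0) min(off) else 0
  breaks <- seq(lo, max(m, 1), length.out = 101)
  tryCatch({
    grDevices::png(png_path, width = 900, height = 800)
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = breaks, main = "Response similarity (sqrt-Jaccard distance)")
    grDevices::dev.off()
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    stop("export_heatmap: failed rendering ", png_path, ": ",
         conditionMessage(e))
  })
  invisible(list(tsv = tsv, png = png_path))
}
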