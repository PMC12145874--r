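#' Gene-set collection
#'
#' Container for named gene sets of one or more set types (GO, IPR, KO,
#' BRITE, MODULE, OG) over a gene universe. Every member gene must belong to
#' the universe and no set may be empty.
#'
#' @param sets Named list, set id -> character vector of gene ids.
#' @param set_type Named character vector, set id -> type tag; defaults to
#'   `"GO"` for all sets.
#' @param universe Character vector of gene ids; defaults to the union of all
#'   members.
#'
#' @return Object of class `gene_set_collection` with elements `sets`
#'   (members deduplicated), `set_type`, `universe`.
#' @export
gene_set_collection <- function(sets, set_type = NULL, universe = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("gene_set_collection: 'sets' must have unique names")
  if (length(sets) == 0L) sets <- setNames(list(), character(0))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L))
    stop("gene_set_collection: empty gene sets are not allowed")
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  stray <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(stray) > 0)
    stop("gene_set_collection: member genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) " ..." else "")
  if (is.null(set_type))
    set_type <- setNames(rep("GO", length(sets)), names(sets))
  if (!all(names(sets) %in% names(set_type)))
    stop("gene_set_collection: 'set_type' must cover every set id")
  structure(list(sets = sets, set_type = set_type[names(sets)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over",
      length(x$universe), "genes\n")
  tt <- table(x$set_type)
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT lines are `set_id<TAB>description<TAB>gene1<TAB>gene2...`; at least
#' three fields are required. Duplicate genes within a line are dropped with
#' a warning (set semantics); malformed lines raise an error carrying the
#' line number.
#'
#' @param path GMT file path.
#' @param set_type Type tag applied to all sets in this file (default "GO").
#' @param universe Optional explicit universe; defaults to the union of
#'   members.
#'
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, set_type = "GO", universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("read_gmt: malformed GMT line ", i, " in ", path,
           " (need >= 3 tab-separated fields)")
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("read_gmt: duplicate gene ids in set '", fields[1],
              "' (line ", i, "); deduplicated")
      genes <- unique(genes)
    }
    ids[i] <- fields[1]
    sets[[i]] <- genes
  }
  if (anyDuplicated(ids))
    stop("read_gmt: duplicate set ids in ", path)
  names(sets) <- ids
  gene_set_collection(sets,
                      set_type = setNames(rep(set_type, length(sets)), ids),
                      universe = universe)
}

#' Write a gene-set collection to a GMT file
#'
#' Members are written sorted, so write-then-read round-trips to the same
#' canonicalized collection. The set type is written into the description
#' field.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$set_type[[id]], sort(collection$sets[[id]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Propagate ontology ancestors onto gene annotations
#'
#' Closes each gene's term set under the parent relation: a gene annotated
#' with a term is also annotated with every ancestor of that term up to the
#' root(s). The edge table must be acyclic and must contain every annotated
#' term as a known node (a term with no outgoing edge is a root).
#'
#' @param annotations Named list, gene id -> character vector of directly
#'   assigned terms.
#' @param edges Data frame with columns `child`, `parent`.
#'
#' @return Named list, gene id -> character vector of terms closed under the
#'   parent relation (sorted). Idempotent.
#' @export
propagate_ancestors <- function(annotations, edges) {
  stopifnot(is.list(annotations), all(c("child", "parent") %in% names(edges)))
  terms_known <- unique(c(edges$child, edges$parent))
  used <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(used, terms_known)
  if (length(unknown) > 0 && nrow(edges) > 0)
    stop("propagate_ancestors: terms absent from the ontology: ",
         paste(unknown, collapse = ", "))
  if (nrow(edges) > 0) {
    gr <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                        directed = TRUE)
    if (!igraph::is_dag(gr))
      stop("propagate_ancestors: cycle detected in the ontology edge table")
  }
  parents <- split(edges$parent, edges$child)
  closure_cache <- new.env(parent = emptyenv())
  closure <- function(term) {
    if (!is.null(closure_cache[[term]])) return(closure_cache[[term]])
    anc <- term
    ps <- parents[[term]]
    if (!is.null(ps)) for (p in ps) anc <- union(anc, closure(p))
    closure_cache[[term]] <- anc
    anc
  }
  lapply(annotations, function(ts)
    sort(unique(unlist(lapply(ts, closure), use.names = FALSE))))
}

#' Restrict a gene-set collection to a gene universe
#'
#' Intersects every set with the given universe (typically the genes passing
#' the expression filter); sets that become empty are dropped and counted in
#' a message. Enrichment must always be scored against the filtered universe.
#'
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of gene ids to keep.
#'
#' @return A restricted [gene_set_collection()] whose universe is
#'   `intersect(collection$universe, universe)`.
#' @export
restrict_to_universe <- function(collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  new_universe <- intersect(collection$universe, universe)
  trimmed <- lapply(collection$sets, intersect, y = new_universe)
  empty <- lengths(trimmed) == 0L
  if (any(empty))
    message("restrict_to_universe: dropped ", sum(empty),
            " set(s) emptied by the universe restriction")
  trimmed <- trimmed[!empty]
  gene_set_collection(trimmed, set_type = collection$set_type[names(trimmed)],
                      universe = new_universe)
}
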