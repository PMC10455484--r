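#' Identity-distance matrix for a set of protein sequences
#'
#' Pairwise distance `d(i, j) = 1 - identity(i, j) / 100` from global
#' alignment percent identity ([percent_identity()]); symmetric with a
#' zero diagonal by construction.
#'
#' @param records protein-record `data.frame` with at least two rows
#'   (columns `id`, `sequence`); ids become the matrix labels.
#' @param rules a [cypome_rules()] object (scoring scheme).
#' @return a symmetric numeric matrix with `id` dimnames.
#' @export
distance_matrix <- function(records, rules = cypome_rules()) {
  rules <- as_cypome_rules(rules)
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records for a distance matrix",
                   call. = FALSE)
  if (anyDuplicated(records$id)) {
    stop("duplicate sequence ids", call. = FALSE)
  }
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- 1 - percent_identity(records$sequence[i],
                                  records$sequence[j], rules) / 100
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on an identity-distance
#' matrix; exact on additive distances. Negative branch-length estimates
#' (which NJ can produce on non-additive input) are clamped to zero.
#'
#' @param dm symmetric numeric distance matrix with labels (e.g. from
#'   [distance_matrix()]), at least 3 taxa.
#' @return an unrooted `ape::phylo` tree with non-negative branch
#'   lengths.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm))
  if (nrow(dm) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) stop("distance matrix must be labelled",
                                  call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tree <- ape::nj(as.dist(dm))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Nearest named leaf on a tree
#'
#' Returns the named reference leaf with the minimum path length (sum of
#' branch lengths) to the query leaf, the relation used to resolve
#' borderline subfamily calls. Ties go to the lexicographically smallest
#' label.
#'
#' @param tree an `ape::phylo` tree.
#' @param query_id a leaf label.
#' @param named_ids non-empty character vector of candidate (named
#'   reference) leaf labels.
#' @return the chosen leaf label.
#' @export
nearest_named_leaf <- function(tree, query_id, named_ids) {
  stopifnot(inherits(tree, "phylo"))
  if (!(query_id %in% tree$tip.label)) {
    stop("query '", query_id, "' is not a leaf of the tree", call. = FALSE)
  }
  named_ids <- setdiff(named_ids, query_id)
  if (length(named_ids) == 0L) {
    stop("no named leaf ids supplied", call. = FALSE)
  }
  missing_ids <- setdiff(named_ids, tree$tip.label)
  if (length(missing_ids) == length(named_ids)) {
    stop("none of the named ids are leaves of the tree", call. = FALSE)
  }
  named_ids <- intersect(named_ids, tree$tip.label)
  pd <- cophenetic(tree)[query_id, named_ids]
  cand <- names(pd)[pd == min(pd)]
  sort(cand)[1L]
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] so the
#' pipeline's tree artifacts round-trip through plain text.
#'
#' @param tree an `ape::phylo` tree.
#' @param path file path.
#' @return `write_newick` returns `path` invisibly; `read_newick`
#'   returns an `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
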