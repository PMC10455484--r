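#' Species-by-family presence/absence matrix
#'
#' Builds the conservation matrix used for heatmap display and
#' clustering: one row per species, one column per P450 family, coded
#' `presence_code` (default 3) where the species has at least one
#' assignment of that family and `absence_code` (default -3) otherwise —
#' the MeV-style red/green encoding.
#'
#' @param assignments `data.frame` with columns `species_id` and
#'   `family` (one row per assigned P450).
#' @param all_species character vector: the species universe (row
#'   order).
#' @param all_families character vector: the family universe (column
#'   order). Defaults to the families observed in `assignments`.
#' @param rules a [cypome_rules()] object (presence/absence codes).
#' @return a numeric matrix with species rows and family columns.
#' @export
presence_matrix <- function(assignments, all_species,
                            all_families = NULL,
                            rules = cypome_rules()) {
  rules <- as_cypome_rules(rules)
  stopifnot(is.data.frame(assignments), length(all_species) > 0L)
  if (anyDuplicated(all_species)) stop("duplicate species labels",
                                       call. = FALSE)
  if (is.null(all_families)) {
    all_families <- sort(unique(assignments$family))
  }
  if (anyDuplicated(all_families)) stop("duplicate family labels",
                                        call. = FALSE)
  unknown <- setdiff(unique(assignments$species_id), all_species)
  if (length(unknown) > 0L) {
    stop("assignments reference unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pm <- matrix(rules$absence_code, nrow = length(all_species),
               ncol = length(all_families),
               dimnames = list(all_species, all_families))
  present <- unique(assignments[assignments$family %in% all_families,
                                c("species_id", "family")])
  if (nrow(present) > 0L) {
    pm[cbind(present$species_id, present$family)] <- rules$presence_code
  }
  pm
}

#' Families conserved across at least k species
#'
#' @param pm presence/absence matrix from [presence_matrix()].
#' @param k minimum number of species (with `k = nrow(pm)` this is
#'   strict conservation across the whole cohort).
#' @param rules a [cypome_rules()] object (presence code).
#' @return character vector of family labels, in column order.
#' @export
conserved_families <- function(pm, k = nrow(pm), rules = cypome_rules()) {
  rules <- as_cypome_rules(rules)
  stopifnot(is.matrix(pm))
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(pm)) stop("k exceeds the number of species rows",
                         call. = FALSE)
  n_present <- colSums(pm == rules$presence_code)
  colnames(pm)[n_present >= k]
}

# Deterministic average-linkage (UPGMA) agglomeration via Lance-Williams
# updates. Presence matrices are packed with exactly tied distances, so
# the merge order must be pinned down: at each step the closest pair
# wins, and among pairs tied within `eps` the one whose clusters carry
# the smallest original row indices. Returns an `hclust`-compatible
# object so standard plotting works.
average_linkage <- function(D, labels, eps = 1e-9) {
  n <- nrow(D)
  dmat <- D
  size <- rep(1L, n)
  minlab <- seq_len(n)          # smallest original index in each cluster
  code <- -seq_len(n)           # hclust merge codes: -leaf or +step
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- nrow(dmat)
    up <- which(upper.tri(dmat), arr.ind = TRUE)
    dv <- dmat[up]
    tied <- which(dv <= min(dv) + eps)
    lab_i <- minlab[up[tied, 1L]]
    lab_j <- minlab[up[tied, 2L]]
    lo <- pmin(lab_i, lab_j)
    hi <- pmax(lab_i, lab_j)
    pick <- tied[order(lo, hi)][1L]
    i <- up[pick, 1L]
    j <- up[pick, 2L]
    height[step] <- dmat[i, j]
    merge[step, ] <- sort(c(code[i], code[j]))
    # Lance-Williams average update against every other cluster
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- (size[i] * dmat[i, keep] + size[j] * dmat[j, keep]) /
      (size[i] + size[j])
    dmat <- dmat[keep, keep, drop = FALSE]
    dmat <- rbind(cbind(dmat, newd), c(newd, 0))
    size <- c(size[keep], size[i] + size[j])
    minlab <- c(minlab[keep], min(minlab[i], minlab[j]))
    code <- c(code[keep], step)
  }
  # leaf ordering by unpacking the merge tree
  descend <- function(k) {
    if (k < 0L) return(-k)
    c(descend(merge[k, 1L]), descend(merge[k, 2L]))
  }
  structure(
    list(merge = merge, height = height,
         order = descend(n - 1L), labels = labels,
         method = "average", dist.method = "euclidean",
         call = match.call()),
    class = "hclust"
  )
}

#' Hierarchically cluster the rows and columns of a presence matrix
#'
#' Agglomerative clustering with the Euclidean metric and average
#' linkage (UPGMA) on both axes, the MeV-style ordering used for heatmap
#' display. Merges are fully deterministic: exactly tied cluster pairs
#' (ubiquitous in two-valued presence matrices) are resolved towards the
#' clusters containing the smallest original row indices. Degenerate
#' axes (fewer than 2 rows or columns) keep their identity ordering.
#'
#' @param pm numeric matrix (e.g. from [presence_matrix()]).
#' @return a list with `row_order` and `col_order` (label vectors) and
#'   `row_tree`, `col_tree` (`hclust`-compatible objects or `NULL` for
#'   degenerate axes).
#' @export
cluster_rows_cols <- function(pm) {
  stopifnot(is.matrix(pm))
  cluster_axis <- function(m) {
    if (nrow(m) < 2L) {
      return(list(order = rownames(m), tree = NULL))
    }
    D <- as.matrix(dist(m, method = "euclidean"))
    h <- average_linkage(D, rownames(m))
    list(order = rownames(m)[h$order], tree = h)
  }
  rows <- cluster_axis(pm)
  cols <- cluster_axis(t(pm))
  list(row_order = rows$order, col_order = cols$order,
       row_tree = rows$tree, col_tree = cols$tree)
}

#' Partition family sets into shared and group-unique components
#'
#' Exact set algebra over per-group family sets: the shared set is the
#' intersection of all groups; a family is unique to a group when it
#' occurs in that group only. For the two-group saprotroph /
#' ectomycorrhizal comparison this is the classic Venn partition.
#'
#' @param family_sets named list of character vectors (one per group,
#'   e.g. `list(SAP = ..., ECM = ...)`), non-empty.
#' @return a list of class `cypome_venn`: `shared` (character vector),
#'   `unique_to_group` (named list), `group_totals` (named integer
#'   vector), `union_size`.
#' @examples
#' venn_partition(list(SAP = c("A", "B"), ECM = c("B", "C")))
#' @export
venn_partition <- function(family_sets) {
  if (!is.list(family_sets) || length(family_sets) == 0L ||
      is.null(names(family_sets)) || any(!nzchar(names(family_sets)))) {
    stop("family_sets must be a non-empty named list", call. = FALSE)
  }
  sets <- lapply(family_sets, unique)
  shared <- Reduce(intersect, sets)
  unique_to_group <- lapply(seq_along(sets), function(i) {
    setdiff(sets[[i]], unique(unlist(sets[-i])))
  })
  names(unique_to_group) <- names(sets)
  structure(
    list(
      shared = sort(shared),
      unique_to_group = lapply(unique_to_group, sort),
      group_totals = vapply(sets, length, integer(1)),
      union_size = length(unique(unlist(sets)))
    ),
    class = "cypome_venn"
  )
}

#' @export
print.cypome_venn <- function(x, ...) {
  cat("Family partition over", length(x$group_totals), "groups\n")
  for (g in names(x$group_totals)) {
    cat(sprintf("  %s: %d families (%d unique)\n", g, x$group_totals[[g]],
                length(x$unique_to_group[[g]])))
  }
  cat(sprintf("  shared by all: %d; union: %d\n",
              length(x$shared), x$union_size))
  invisible(x)
}

#' Two-group venn arithmetic from printed counts
#'
#' When only group totals and the shared count are known (as printed in
#' a comparative figure), the remaining partition is determined:
#' `union = total_1 + total_2 - shared` and
#' `unique_g = total_g - shared`.
#'
#' @param group_totals named numeric vector of length 2.
#' @param shared number of families common to both groups.
#' @return a list with `group_totals`, `shared`, `unique_to_group`
#'   (named), and `union_size`.
#' @examples
#' venn_from_counts(c(SAP = 103, ECM = 89), shared = 39)
#' @export
venn_from_counts <- function(group_totals, shared) {
  if (length(group_totals) != 2L || is.null(names(group_totals))) {
    stop("group_totals must be a named vector of length 2", call. = FALSE)
  }
  if (shared > min(group_totals) || shared < 0) {
    stop("shared count must lie in [0, min(group totals)]", call. = FALSE)
  }
  list(
    group_totals = group_totals,
    shared = shared,
    unique_to_group = group_totals - shared,
    union_size = unname(sum(group_totals) - shared)
  )
}

#' Cohort summary statistics
#'
#' Per-group and overall totals, rounded means (half away from zero, the
#' reporting convention for every printed average), extremes with their
#' species, and — when per-family counts are supplied — the list of
#' bloomed families (member count at or above the bloom threshold).
#'
#' @param species_counts `data.frame` with one row per species; needs a
#'   species label column (`species`), a `lifestyle` column, and the
#'   count column named by `count_col`.
#' @param count_col name of the per-species count column (default
#'   `"p450s"`).
#' @param family_counts optional `data.frame` with columns `family` and
#'   `count` (e.g. the table5 fixture) for bloom detection.
#' @param rules a [cypome_rules()] object.
#' @return a list of class `cypome_stats`: `total`, `mean`, `min`,
#'   `max`, `argmin`, `argmax`, `per_group` (list keyed by lifestyle
#'   with the same fields), and `bloom_families` (or `NULL`).
#' @examples
#' summary_stats(load_fixture("table4"),
#'               family_counts = load_fixture("table5"))
#' @export
summary_stats <- function(species_counts, count_col = "p450s",
                          family_counts = NULL, rules = cypome_rules()) {
  rules <- as_cypome_rules(rules)
  stopifnot(is.data.frame(species_counts), nrow(species_counts) > 0L,
            count_col %in% names(species_counts),
            all(c("species", "lifestyle") %in% names(species_counts)))
  if (anyNA(species_counts$lifestyle) ||
      any(!nzchar(species_counts$lifestyle))) {
    stop("species missing lifestyle label: ",
         paste(species_counts$species[
           is.na(species_counts$lifestyle) |
             !nzchar(species_counts$lifestyle)], collapse = ", "),
         call. = FALSE)
  }
  stats_of <- function(df) {
    x <- df[[count_col]]
    list(
      total = sum(x),
      mean = round_half_away(mean(x)),
      min = min(x),
      max = max(x),
      argmin = df$species[which.min(x)],
      argmax = df$species[which.max(x)]
    )
  }
  per_group <- lapply(split(species_counts, species_counts$lifestyle),
                      stats_of)
  bloom <- NULL
  if (!is.null(family_counts)) {
    stopifnot(all(c("family", "count") %in% names(family_counts)))
    bloom <- family_counts$family[
      family_counts$count >= rules$bloom_member_threshold]
  }
  structure(
    c(stats_of(species_counts),
      list(per_group = per_group, bloom_families = bloom)),
    class = "cypome_stats"
  )
}

#' @export
print.cypome_stats <- function(x, ...) {
  cat(sprintf("Total %d; mean %d; range %d (%s) - %d (%s)\n",
              x$total, x$mean, x$min, x$argmin, x$max, x$argmax))
  for (g in names(x$per_group)) {
    s <- x$per_group[[g]]
    cat(sprintf("  %s: total %d, mean %d, range %d-%d\n",
                g, s$total, s$mean, s$min, s$max))
  }
  if (!is.null(x$bloom_families)) {
    cat("  bloomed families:",
        paste(x$bloom_families, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a presence/absence matrix as a MeV-importable TSV
#'
#' @param pm matrix from [presence_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(pm, path) {
  df <- data.frame(species = rownames(pm), pm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
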