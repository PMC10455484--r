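#' Construct a biosynthetic gene cluster set
#'
#' Container for secondary-metabolite biosynthetic gene clusters (BGCs)
#' as exported by cluster-prediction tools: a cluster table (one row per
#' cluster: species, index, type) and a member-gene table (one row per
#' gene with 1-based inclusive coordinates). Hybrid cluster types are
#' comma-joined tokens of the standard anti-SMASH vocabulary (e.g.
#' `"NRPS,T1PKS"`).
#'
#' @param clusters `data.frame` with columns `species_id`,
#'   `cluster_index`, `cluster_type`.
#' @param genes `data.frame` with columns `species_id`, `cluster_index`,
#'   `gene_id`, `start`, `end`, `strand`.
#' @return an object of class `bgc_clusters`.
#' @export
bgc_clusters <- function(clusters, genes) {
  stopifnot(is.data.frame(clusters), is.data.frame(genes),
            all(c("species_id", "cluster_index", "cluster_type") %in%
                  names(clusters)),
            all(c("species_id", "cluster_index", "gene_id",
                  "start", "end", "strand") %in% names(genes)))
  key <- paste(clusters$species_id, clusters$cluster_index)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    stop("duplicate cluster_index within species: ",
         paste(dup, collapse = "; "), call. = FALSE)
  }
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start]
    stop("gene(s) with end < start: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(paste(genes$species_id, genes$cluster_index), key)
  if (length(orphan) > 0L) {
    stop("gene rows reference unknown cluster(s): ",
         paste(orphan, collapse = "; "), call. = FALSE)
  }
  structure(list(clusters = clusters, genes = genes),
            class = "bgc_clusters")
}

#' @export
print.bgc_clusters <- function(x, ...) {
  cat(sprintf("BGC set: %d clusters, %d member genes, %d species\n",
              nrow(x$clusters), nrow(x$genes),
              length(unique(x$clusters$species_id))))
  invisible(x)
}

#' Parse a simplified BGC cluster table
#'
#' Reads the flat TSV contract any cluster-prediction export can be
#' reduced to: columns `species_id`, `cluster_index`, `cluster_type`,
#' `gene_id`, `start`, `end`, `strand`, one row per member gene,
#' coordinates 1-based inclusive. Rows sharing (species, index) form one
#' cluster; a (species, index) pair appearing with conflicting types is
#' an error.
#'
#' @param path TSV file path.
#' @return a [bgc_clusters()] object.
#' @export
parse_cluster_table <- function(path) {
  if (!file.exists(path)) stop("cluster table not found: ", path,
                               call. = FALSE)
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("species_id", "cluster_index", "cluster_type",
                "gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("cluster table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(tbl$species_id, tbl$cluster_index)
  type_by_key <- tapply(tbl$cluster_type, key,
                        function(x) length(unique(x)))
  if (any(type_by_key > 1L)) {
    stop("conflicting cluster_type for cluster(s): ",
         paste(names(type_by_key)[type_by_key > 1L], collapse = "; "),
         call. = FALSE)
  }
  clusters <- unique(tbl[, c("species_id", "cluster_index", "cluster_type")])
  genes <- tbl[, c("species_id", "cluster_index", "gene_id",
                   "start", "end", "strand")]
  bgc_clusters(clusters, genes)
}

#' Cross-reference P450s into gene clusters
#'
#' Finds every cluster member gene whose id maps to an assigned P450
#' name, mirroring the manual data-mining step that places P450s inside
#' predicted clusters. Unmatched genes are silently ignored.
#'
#' @param clusters a [bgc_clusters()] object.
#' @param p450_gene_map named character vector mapping `gene_id` to an
#'   assigned CYP label.
#' @return a `data.frame` with columns `species_id`, `cluster_index`,
#'   `cluster_type`, `p450_name`, `gene_id`, ordered by (species,
#'   cluster index, gene id). Zero rows when nothing matches.
#' @export
xref_p450s <- function(clusters, p450_gene_map) {
  stopifnot(inherits(clusters, "bgc_clusters"))
  genes <- clusters$genes
  hit <- genes$gene_id %in% names(p450_gene_map)
  out <- genes[hit, c("species_id", "cluster_index", "gene_id")]
  if (nrow(out) == 0L) {
    return(data.frame(species_id = character(0), cluster_index = integer(0),
                      cluster_type = character(0), p450_name = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  ckey <- paste(clusters$clusters$species_id, clusters$clusters$cluster_index)
  out$cluster_type <- clusters$clusters$cluster_type[
    match(paste(out$species_id, out$cluster_index), ckey)]
  out$p450_name <- unname(p450_gene_map[out$gene_id])
  out <- out[order(out$species_id, out$cluster_index, out$gene_id),
             c("species_id", "cluster_index", "cluster_type",
               "p450_name", "gene_id")]
  rownames(out) <- NULL
  out
}

#' Summarise a BGC set and its P450 content
#'
#' Exact tallies over a cluster set: clusters per species, clusters per
#' type (hybrid comma-joined types count once per listed token, but once
#' only in the total), overall total, rounded mean per species (half
#' away from zero), the number of P450-in-cluster occurrences, and P450
#' occurrences per cluster type.
#'
#' @param clusters a [bgc_clusters()] object, or a `data.frame` of
#'   clusters (columns `species_id`, `cluster_index`, `cluster_type`).
#' @param xrefs optional P450 cross-reference `data.frame` from
#'   [xref_p450s()].
#' @return a list of class `bgc_stats`: `per_species`, `per_type`
#'   (named integer vectors), `total`, `mean_per_species`,
#'   `p450_entry_count`, `p450_in_type`.
#' @export
bgc_summary <- function(clusters, xrefs = NULL) {
  cl <- if (inherits(clusters, "bgc_clusters")) clusters$clusters else clusters
  stopifnot(is.data.frame(cl))
  if (nrow(cl) == 0L) {
    return(structure(list(per_species = integer(0), per_type = integer(0),
                          total = 0L, mean_per_species = 0,
                          p450_entry_count = 0L, p450_in_type = integer(0)),
                     class = "bgc_stats"))
  }
  per_species <- table(cl$species_id)
  type_tokens <- function(x) trimws(unlist(strsplit(x, ",", fixed = TRUE)))
  per_type <- table(type_tokens(cl$cluster_type))
  total <- nrow(cl)
  p450_in_type <- integer(0)
  n_xref <- 0L
  if (!is.null(xrefs) && nrow(xrefs) > 0L) {
    n_xref <- nrow(xrefs)
    p450_in_type <- table(type_tokens(xrefs$cluster_type))
  }
  structure(
    list(
      per_species = c(per_species),
      per_type = c(per_type),
      total = total,
      mean_per_species = round_half_away(total / length(per_species)),
      p450_entry_count = n_xref,
      p450_in_type = c(p450_in_type)
    ),
    class = "bgc_stats"
  )
}

#' @export
print.bgc_stats <- function(x, ...) {
  cat(sprintf("BGCs: %d total over %d species (mean %g per species)\n",
              x$total, length(x$per_species), x$mean_per_species))
  if (length(x$per_type) > 0L) {
    tt <- sort(x$per_type, decreasing = TRUE)
    cat("  by type:", paste(sprintf("%s: %d", names(tt), tt),
                            collapse = ", "), "\n")
  }
  cat(sprintf("  P450 cluster occurrences: %d\n", x$p450_entry_count))
  invisible(x)
}
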