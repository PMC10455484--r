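#' Parse a CYP name into family, subfamily and member number
#'
#' CYP names follow the International P450 Nomenclature: the prefix
#' `CYP`, an Arabic family number, a subfamily capital letter, and a
#' member number, e.g. `CYP52A3` is member 3 of subfamily A of family
#' CYP52. Subfamily and member are optional (`CYP51` is a bare family).
#'
#' @param cyp_name character vector of CYP names.
#' @return a `data.frame` with columns `cyp_name`, `family` (e.g.
#'   `"CYP52"`), `subfamily` (letter or `NA`), `member` (integer or
#'   `NA`).
#' @examples
#' parse_cyp_name(c("CYP52A3", "CYP51"))
#' @export
parse_cyp_name <- function(cyp_name) {
  m <- regmatches(cyp_name,
                  regexec("^CYP([0-9]+)([A-Z]*)([0-9]*)$", cyp_name))
  bad <- cyp_name[vapply(m, length, integer(1)) == 0L]
  if (length(bad) > 0L) {
    stop("not a valid CYP name: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sub_letters <- vapply(m, `[[`, character(1), 3L)
  if (any(nchar(sub_letters) > 1L)) {
    stop("subfamily must be a single letter: ",
         paste(cyp_name[nchar(sub_letters) > 1L], collapse = ", "),
         call. = FALSE)
  }
  members <- vapply(m, `[[`, character(1), 4L)
  data.frame(
    cyp_name = cyp_name,
    family = paste0("CYP", vapply(m, `[[`, character(1), 2L)),
    subfamily = ifelse(nzchar(sub_letters), sub_letters, NA_character_),
    member = ifelse(nzchar(members), suppressWarnings(as.integer(members)),
                    NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Read a named P450 reference FASTA
#'
#' Headers must begin with the CYP name token (e.g. `>CYP52A3 ...`); the
#' name is validated with [parse_cyp_name()].
#'
#' @param path FASTA file of named reference P450s.
#' @return a `data.frame` with columns `cyp_name`, `family`, `subfamily`,
#'   `member`, `sequence`.
#' @export
read_reference_fasta <- function(path) {
  recs <- read_fasta(path, species_id = "reference")
  parsed <- parse_cyp_name(recs$id)
  cbind(parsed, sequence = recs$sequence, stringsAsFactors = FALSE)
}

#' Assign P450 family and subfamily to curated queries
#'
#' Implements the International P450 Nomenclature identity rules against
#' a named reference set. For each query the best-identity reference is
#' found (ties broken by lexicographically smallest CYP name); identity
#' strictly above the subfamily threshold inherits the reference's family
#' and subfamily; identity between the family and subfamily thresholds
#' (inclusive) inherits the family with subfamily `NEW`; identity below
#' the family threshold founds a new family, labelled from a
#' deterministic placeholder series (`NEWFAM1`, `NEWFAM2`, ... in query
#' order — official CYP numbers are committee-assigned and out of scope).
#'
#' Queries whose best identity falls within the borderline band around
#' the subfamily threshold are flagged; if a phylogeny is supplied and
#' the query is one of its leaves, the borderline subfamily call is
#' overridden by the subfamily of the nearest named reference leaf
#' ([nearest_named_leaf()]), mirroring the phylogeny-assisted manual
#' curation step.
#'
#' @param queries protein-record `data.frame` of triaged P450s.
#' @param references reference `data.frame` (columns `cyp_name`,
#'   `sequence`; see [read_reference_fasta()]). Must be non-empty.
#' @param rules a [cypome_rules()] object.
#' @param tree optional `ape::phylo` tree containing query and reference
#'   leaves, used only for borderline subfamily resolution.
#' @return a `data.frame` with one row per query: `query_id`, `family`,
#'   `subfamily`, `best_ref`, `identity`, `is_new_family`, `borderline`.
#' @export
assign_cohort <- function(queries, references, rules = cypome_rules(),
                          tree = NULL) {
  rules <- as_cypome_rules(rules)
  stopifnot(is.data.frame(queries))
  if (is.null(references) || nrow(references) == 0L) {
    stop("reference set is empty", call. = FALSE)
  }
  ref_parsed <- parse_cyp_name(references$cyp_name)
  newfam_counter <- 0L
  out <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    ids <- vapply(references$sequence, function(ref) {
      percent_identity(q$sequence, ref, rules)
    }, numeric(1))
    best <- max(ids)
    # ties by lexicographically smallest cyp_name
    cand <- which(ids == best)
    cand <- cand[order(references$cyp_name[cand])][1L]
    best_ref <- references$cyp_name[cand]
    fam <- ref_parsed$family[cand]
    subfam <- ref_parsed$subfamily[cand]

    borderline <- abs(best - rules$subfamily_identity_threshold) <=
      rules$borderline_band_halfwidth
    is_new_family <- best < rules$family_identity_threshold

    if (is_new_family) {
      newfam_counter <- newfam_counter + 1L
      family_label <- paste0("NEWFAM", newfam_counter)
      subfamily_label <- "NEW"
    } else if (best > rules$subfamily_identity_threshold) {
      family_label <- fam
      subfamily_label <- if (is.na(subfam)) "NEW" else subfam
    } else {
      family_label <- fam
      subfamily_label <- "NEW"
    }

    if (borderline && !is_new_family && !is.null(tree) &&
        q$id %in% tree$tip.label) {
      named_ids <- intersect(references$cyp_name, tree$tip.label)
      if (length(named_ids) > 0L) {
        nearest <- nearest_named_leaf(tree, q$id, named_ids)
        near_sub <- parse_cyp_name(nearest)$subfamily
        if (!is.na(near_sub)) subfamily_label <- near_sub
      }
    }

    out[[i]] <- data.frame(
      query_id = q$id,
      family = family_label,
      subfamily = subfamily_label,
      best_ref = best_ref,
      identity = best,
      is_new_family = is_new_family,
      borderline = borderline,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Assign family and subfamily to a single query
#'
#' Convenience wrapper around [assign_cohort()] for one protein record.
#'
#' @param query a single-row protein record (or list with `id`,
#'   `sequence`).
#' @inheritParams assign_cohort
#' @return a one-row assignment `data.frame` (see [assign_cohort()]).
#' @export
assign_family <- function(query, references, rules = cypome_rules(),
                          tree = NULL) {
  q <- data.frame(id = as.character(query$id),
                  sequence = as.character(query$sequence),
                  stringsAsFactors = FALSE)
  assign_cohort(q, references, rules, tree)
}
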