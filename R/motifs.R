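#' Scan a protein sequence for the two P450 signature motifs
#'
#' Finds every occurrence of the K-helix EXXR motif (Glu-x-x-Arg, anywhere
#' in the sequence) and the heme-binding CXG motif (Cys-x-Gly, restricted
#' to the C-terminal third of the sequence, where the axial heme-ligating
#' cysteine lies; the restriction suppresses spurious Cys-x-Gly matches
#' elsewhere). Overlapping matches are reported, one per distinct start
#' position. An `X` in the sequence can stand in a wildcard position but
#' never satisfies a fixed motif residue.
#'
#' @param sequence amino-acid sequence string (canonical residues plus X).
#' @param rules a [cypome_rules()] object carrying the motif patterns.
#' @return a `data.frame` with columns `motif` (`"EXXR"` or `"CXG"`),
#'   `start` (1-based position) and `match` (the matched substring),
#'   ordered by motif then position. Zero rows when nothing matches.
#' @examples
#' scan_motifs("MAAAEALRAAAAAAAAAFGAGPRNCIG")
#' @export
scan_motifs <- function(sequence, rules = cypome_rules()) {
  rules <- as_cypome_rules(rules)
  check_aa_sequence(sequence)
  n <- nchar(sequence)

  all_starts <- function(pattern) {
    m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  # Patterns are fixed-width (one character class or literal per position).
  motif_width <- function(pattern) nchar(gsub("\\[[^]]*\\]", ".", pattern))

  exxr_starts <- all_starts(rules$exxr_pattern)
  exxr_w <- motif_width(rules$exxr_pattern)

  cxg_starts <- all_starts(rules$cxg_pattern)
  cxg_w <- motif_width(rules$cxg_pattern)
  # C-terminal third: matches must start after the first two thirds.
  tail_start <- floor(2 * n / 3) + 1L
  cxg_starts <- cxg_starts[cxg_starts >= tail_start]

  hits <- rbind(
    if (length(exxr_starts) > 0L) {
      data.frame(motif = "EXXR", start = exxr_starts,
                 match = substring(sequence, exxr_starts,
                                   exxr_starts + exxr_w - 1L),
                 stringsAsFactors = FALSE)
    },
    if (length(cxg_starts) > 0L) {
      data.frame(motif = "CXG", start = cxg_starts,
                 match = substring(sequence, cxg_starts,
                                   cxg_starts + cxg_w - 1L),
                 stringsAsFactors = FALSE)
    }
  )
  if (is.null(hits)) {
    hits <- data.frame(motif = character(0), start = integer(0),
                       match = character(0), stringsAsFactors = FALSE)
  }
  hits
}

#' Triage one candidate protein
#'
#' Applies the published curation rule: a candidate with both signature
#' motifs and at least `fragment_length_cutoff` residues is a `P450`; one
#' with exactly one motif, or both motifs but short length, is a
#' `FRAGMENT`. Motif-free candidates are split heuristically: with a best
#' reference identity at or above the false-positive threshold they are
#' `FALSE_POSITIVE` (degenerate P450-like sequences), otherwise `NO_HIT`.
#'
#' @param record a single-row protein record (or a list with `id` and
#'   `sequence`).
#' @param rules a [cypome_rules()] object.
#' @param best_reference_identity optional percent identity of the
#'   candidate to its best named P450 reference; used only for the
#'   FALSE_POSITIVE / NO_HIT split of motif-free candidates.
#' @return a list of class `cypome_triage` with elements `protein_id`,
#'   `category`, `motif_hits`, `length`, `best_reference_identity`.
#' @export
triage <- function(record, rules = cypome_rules(),
                   best_reference_identity = NA_real_) {
  rules <- as_cypome_rules(rules)
  sequence <- record$sequence
  if (is.null(sequence)) stop("record has no $sequence", call. = FALSE)
  hits <- scan_motifs(sequence, rules)
  n_motifs <- length(unique(hits$motif))
  len <- nchar(sequence)

  category <- if (n_motifs == 2L && len >= rules$fragment_length_cutoff) {
    "P450"
  } else if (n_motifs >= 1L) {
    "FRAGMENT"
  } else if (!is.na(best_reference_identity) &&
             best_reference_identity >= rules$false_positive_identity_threshold) {
    "FALSE_POSITIVE"
  } else {
    "NO_HIT"
  }
  structure(
    list(
      protein_id = if (!is.null(record$id)) as.character(record$id) else NA_character_,
      category = category,
      motif_hits = hits,
      length = len,
      best_reference_identity = best_reference_identity
    ),
    class = "cypome_triage"
  )
}

#' @export
print.cypome_triage <- function(x, ...) {
  cat(sprintf("%s: %s (%d aa, motifs: %s)\n",
              x$protein_id, x$category, x$length,
              if (nrow(x$motif_hits) > 0L) {
                paste(unique(x$motif_hits$motif), collapse = "+")
              } else "none"))
  invisible(x)
}

#' Triage a whole proteome
#'
#' Runs [triage()] over every candidate of one species and tallies the
#' four categories. If a named reference set is supplied, motif-free
#' candidates are aligned against it to drive the FALSE_POSITIVE /
#' NO_HIT split; without references they all fall to NO_HIT.
#'
#' @param records protein-record `data.frame` (one species; mixed
#'   `species_id` values are an error).
#' @param rules a [cypome_rules()] object.
#' @param references optional reference `data.frame` with columns
#'   `cyp_name` and `sequence` (see [read_reference_fasta()]).
#' @return a list with `counts` (named vector: `total_hits`, `p450s`,
#'   `fragments`, `false_positives`, `no_hits`, which partition the
#'   input) and `results`, a per-candidate `data.frame` with columns
#'   `protein_id`, `species_id`, `length`, `category`, `exxr_positions`,
#'   `cxg_positions`, `best_identity`.
#' @export
triage_proteome <- function(records, rules = cypome_rules(),
                            references = NULL) {
  rules <- as_cypome_rules(rules)
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0L && length(unique(records$species_id)) != 1L) {
    stop("records mix species ids: ",
         paste(unique(records$species_id), collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    hits <- scan_motifs(rec$sequence, rules)
    best_id <- NA_real_
    if (length(unique(hits$motif)) == 0L && !is.null(references) &&
        nrow(references) > 0L) {
      best_id <- max(vapply(references$sequence, function(ref) {
        percent_identity(rec$sequence, ref, rules)
      }, numeric(1)))
    }
    tr <- triage(rec, rules, best_reference_identity = best_id)
    rows[[i]] <- data.frame(
      protein_id = rec$id,
      species_id = rec$species_id,
      length = tr$length,
      category = tr$category,
      exxr_positions = paste(hits$start[hits$motif == "EXXR"], collapse = ","),
      cxg_positions = paste(hits$start[hits$motif == "CXG"], collapse = ","),
      best_identity = best_id,
      stringsAsFactors = FALSE
    )
  }
  results <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(protein_id = character(0), species_id = character(0),
               length = integer(0), category = character(0),
               exxr_positions = character(0), cxg_positions = character(0),
               best_identity = numeric(0), stringsAsFactors = FALSE)
  }
  counts <- c(
    total_hits = nrow(results),
    p450s = sum(results$category == "P450"),
    fragments = sum(results$category == "FRAGMENT"),
    false_positives = sum(results$category == "FALSE_POSITIVE"),
    no_hits = sum(results$category == "NO_HIT")
  )
  list(counts = counts, results = results)
}

# Remove every match of one motif from a sequence by substituting the
# fixed first residue (E for EXXR, C for CXG) with alanine. Used by the
# synthetic generator to build fragments and degenerate sequences.
ablate_motif <- function(sequence, motif = c("EXXR", "CXG"),
                         rules = cypome_rules()) {
  motif <- match.arg(motif)
  rules <- as_cypome_rules(rules)
  repeat {
    hits <- scan_motifs(sequence, rules)
    starts <- hits$start[hits$motif == motif]
    if (length(starts) == 0L) return(sequence)
    substr(sequence, starts[1L], starts[1L]) <- "A"
  }
}
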