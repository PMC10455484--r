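#' Curation rule set
#'
#' Bundles every tunable threshold of the curation pipeline. The defaults
#' are the published curation rules: candidates carrying both signature
#' motifs and at least 350 residues are P450s; >40% / >55% amino-acid
#' identity to a named reference places a query in the same family /
#' subfamily; a family with at least 30 members in the cohort counts as
#' "bloomed"; presence/absence matrices are coded 3 / -3.
#'
#' @param family_identity_threshold percent identity at or above which a
#'   query joins the best reference's family (default 40).
#' @param subfamily_identity_threshold percent identity strictly above
#'   which it also joins the reference's subfamily (default 55).
#' @param fragment_length_cutoff minimum residue count for a full-length
#'   P450 call (default 350).
#' @param borderline_band_halfwidth identities within this many percent of
#'   the subfamily threshold are flagged borderline and may be resolved on
#'   a phylogeny (default 2).
#' @param false_positive_identity_threshold motif-free candidates with at
#'   least this percent identity to the reference set are called
#'   FALSE_POSITIVE (degenerate P450-like sequences); below it, or with no
#'   references supplied, NO_HIT (default 20). This split is a documented
#'   heuristic: the source curation protocol does not define it.
#' @param bloom_member_threshold member count from which a family counts
#'   as bloomed (default 30).
#' @param presence_code,absence_code cell codes of the presence/absence
#'   matrix (defaults 3 and -3, the MeV-style heatmap convention).
#' @param exxr_pattern,cxg_pattern regular expressions for the two P450
#'   signature motifs: the K-helix Glu-x-x-Arg salt bridge and the
#'   heme-binding Cys-x-Gly. The CXG scan is restricted to the C-terminal
#'   third of the sequence, where the axial heme cysteine lies.
#' @param gap_opening,gap_extension affine gap penalties for global
#'   alignment; a gap of length L costs `gap_opening + L * gap_extension`.
#' @param substitution_matrix name of the substitution matrix (only
#'   "BLOSUM62" is shipped).
#'
#' @return an object of class `cypome_rules` (a validated named list).
#' @examples
#' rules <- cypome_rules()
#' rules$family_identity_threshold
#' @export
cypome_rules <- function(family_identity_threshold = 40,
                         subfamily_identity_threshold = 55,
                         fragment_length_cutoff = 350,
                         borderline_band_halfwidth = 2,
                         false_positive_identity_threshold = 20,
                         bloom_member_threshold = 30,
                         presence_code = 3,
                         absence_code = -3,
                         exxr_pattern = "E..R",
                         cxg_pattern = "C.G",
                         gap_opening = 10,
                         gap_extension = 1,
                         substitution_matrix = "BLOSUM62") {
  rules <- list(
    family_identity_threshold = family_identity_threshold,
    subfamily_identity_threshold = subfamily_identity_threshold,
    fragment_length_cutoff = fragment_length_cutoff,
    borderline_band_halfwidth = borderline_band_halfwidth,
    false_positive_identity_threshold = false_positive_identity_threshold,
    bloom_member_threshold = bloom_member_threshold,
    presence_code = presence_code,
    absence_code = absence_code,
    exxr_pattern = exxr_pattern,
    cxg_pattern = cxg_pattern,
    gap_opening = gap_opening,
    gap_extension = gap_extension,
    substitution_matrix = substitution_matrix
  )
  if (!(family_identity_threshold > 0 &&
        family_identity_threshold < subfamily_identity_threshold &&
        subfamily_identity_threshold < 100)) {
    stop("thresholds must satisfy 0 < family < subfamily < 100",
         call. = FALSE)
  }
  if (fragment_length_cutoff <= 0) {
    stop("fragment_length_cutoff must be positive", call. = FALSE)
  }
  if (presence_code == absence_code) {
    stop("presence_code and absence_code must differ", call. = FALSE)
  }
  if (borderline_band_halfwidth < 0) {
    stop("borderline_band_halfwidth must be non-negative", call. = FALSE)
  }
  structure(rules, class = "cypome_rules")
}

#' @export
print.cypome_rules <- function(x, ...) {
  cat("CYPome curation rules\n")
  cat(sprintf("  family / subfamily identity thresholds: %g%% / %g%%\n",
              x$family_identity_threshold, x$subfamily_identity_threshold))
  cat(sprintf("  fragment length cutoff: %g aa\n", x$fragment_length_cutoff))
  cat(sprintf("  borderline band: +/- %g%% around %g%%\n",
              x$borderline_band_halfwidth, x$subfamily_identity_threshold))
  cat(sprintf("  bloom threshold: >= %g members\n", x$bloom_member_threshold))
  cat(sprintf("  presence / absence codes: %g / %g\n",
              x$presence_code, x$absence_code))
  cat(sprintf("  motifs: EXXR = /%s/ (anywhere), CXG = /%s/ (C-terminal third)\n",
              x$exxr_pattern, x$cxg_pattern))
  cat(sprintf("  alignment: %s, gap open %g, extend %g\n",
              x$substitution_matrix, x$gap_opening, x$gap_extension))
  invisible(x)
}

as_cypome_rules <- function(rules) {
  if (is.null(rules)) return(cypome_rules())
  if (!inherits(rules, "cypome_rules")) {
    stop("rules must be created with cypome_rules()", call. = FALSE)
  }
  rules
}
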