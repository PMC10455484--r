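#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties (a gap of length L costs `gap_opening + L * gap_extension`;
#' defaults 10 and 1). The dynamic programming is done by
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b amino-acid sequence strings (non-empty, canonical alphabet
#'   plus X).
#' @param rules a [cypome_rules()] object carrying the scoring scheme.
#' @return an object of class `cypome_alignment`: a list with
#'   `aligned_a`, `aligned_b` (equal-length gapped strings, gap `-`),
#'   `score`, and `identity_pct` (see [percent_identity()] for the
#'   denominator convention).
#' @examples
#' aln <- global_align("HEAGAWGHEE", "HEAGAWGHEE")
#' aln$identity_pct
#' @export
global_align <- function(a, b, rules = cypome_rules()) {
  rules <- as_cypome_rules(rules)
  check_aa_sequence(a, "sequence a")
  check_aa_sequence(b, "sequence b")
  if (!identical(rules$substitution_matrix, "BLOSUM62")) {
    stop("only BLOSUM62 scoring is shipped", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = rules$gap_opening,
    gapExtension = rules$gap_extension,
    type = "global"
  )
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  structure(
    list(
      aligned_a = unname(aligned_a),
      aligned_b = unname(aligned_b),
      score = Biostrings::score(aln),
      identity_pct = identity_from_aligned(aligned_a, aligned_b)
    ),
    class = "cypome_alignment"
  )
}

#' @export
print.cypome_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %.1f, identity %.1f%% over %d columns\n",
              x$score, x$identity_pct, nchar(x$aligned_a)))
  invisible(x)
}

# Percent identity from two equal-length gapped strings. Identical
# non-gap columns over all columns except terminal-overhang gap runs
# (leading/trailing gaps of either string). Internal gaps stay in the
# denominator. The terminal exclusion approximates the identity a local
# aligner would report when one sequence is a sub-fragment of the other.
identity_from_aligned <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  n <- length(ca)
  keep <- rep(TRUE, n)
  for (cc in list(ca, cb)) {
    i <- 1L
    while (i <= n && cc[i] == "-") { keep[i] <- FALSE; i <- i + 1L }
    i <- n
    while (i >= 1L && cc[i] == "-") { keep[i] <- FALSE; i <- i - 1L }
  }
  denom <- sum(keep)
  if (denom == 0L) return(0)
  ident <- sum(keep & ca == cb & ca != "-")
  100 * ident / denom
}

#' Percent identity between two protein sequences
#'
#' Globally aligns the two sequences ([global_align()]) and reports
#' 100 x (identical aligned columns) / (alignment columns), where
#' terminal-overhang gap columns are excluded from the denominator but
#' internal gaps are not. A sequence aligned against its own prefix is
#' therefore 100% identical.
#'
#' The two sequences are passed to the aligner in a canonical order
#' (lexicographically smaller first), so the measure is symmetric by
#' construction even when several co-optimal alignments with different
#' column identities exist.
#'
#' @inheritParams global_align
#' @return percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACDEFGHIK", "ACNEFGHIK")  # 8/9
#' @export
percent_identity <- function(a, b, rules = cypome_rules()) {
  if (identical(a, b)) {
    check_aa_sequence(a)
    return(100)
  }
  if (a > b) {
    tmp <- a
    a <- b
    b <- tmp
  }
  global_align(a, b, rules)$identity_pct
}
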