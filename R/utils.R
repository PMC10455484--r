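# Shared internal helpers and constants.

# 20 canonical amino acids; X is tolerated on input but never satisfies a
# fixed motif position.
AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALPHABET <- c(AA_CANONICAL, "X")

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero
#' (so 30.5 becomes 31 and -30.5 becomes -31), the convention used for
#' every reported per-species average in this package. Note that base
#' [round()] uses banker's rounding (half to even) instead.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_away(c(40.8, 33.14, 30.5, -2.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Validate an amino-acid sequence string. Returns invisibly; stops with a
# message naming `what` on violation.
check_aa_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (!nzchar(sequence)) {
    stop(what, " is empty", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(
      what, " contains non-canonical residue(s): ",
      paste(bad, collapse = ", "),
      " (allowed: 20 canonical amino acids plus X)",
      call. = FALSE
    )
  }
  invisible(sequence)
}

# Build a protein-record data.frame (id, species_id, sequence, length).
protein_records <- function(id, species_id, sequence) {
  stopifnot(length(id) == length(sequence))
  data.frame(
    id = as.character(id),
    species_id = rep_len(as.character(species_id), length(id)),
    sequence = as.character(sequence),
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
}

# sample() that never falls into the 1:x scalar trap.
sample_from <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# BLOSUM62 from Biostrings, fetched once per session.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
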