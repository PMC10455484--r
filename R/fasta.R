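#' Read an amino-acid FASTA file into a protein-record table
#'
#' Parses a multi-record amino-acid FASTA file and returns one row per
#' entry. Sequences are uppercased, a single terminal stop codon (`*`) is
#' stripped, and any residue outside the 20 canonical amino acids plus X
#' is rejected (motif scanning semantics are only defined on that
#' alphabet). Record ids (the first whitespace-delimited header token)
#' must be unique within the file.
#'
#' @param path path to a FASTA file.
#' @param species_id species key attached to every record (default: the
#'   file name without extension).
#' @return a `data.frame` with columns `id`, `species_id`, `sequence`,
#'   `length`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, species_id = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) {
      stop("empty sequence for record '", ids[[i]], "' in ", path,
           call. = FALSE)
    }
    check_aa_sequence(seqs[[i]], what = paste0("record '", ids[[i]], "'"))
  }
  protein_records(ids, species_id, unname(seqs))
}

#' Write protein records to FASTA
#'
#' @param records a protein-record `data.frame` as returned by
#'   [read_fasta()] (columns `id` and `sequence` are used).
#' @param path output file path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
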