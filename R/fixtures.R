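# Packaged transcriptions of the study's printed summary tables.
#
# table4: per-species curation outcome (hits, P450s, no-hits, false
#   positives, fragments) with SAP/ECM lifestyle labels, 19 species.
# table5: per-family member and subfamily counts, 153 families.
# table6: per-species family and subfamily counts, 19 species.
# table7: per-species BGC counts, 12 species; the P450-in-cluster entries
#   ride along as the "xrefs" attribute (9 occurrences).
# figure2: SAP/ECM family totals and their shared-family count, the input
#   to the two-group venn arithmetic.
#
# Load-time assertions guard against transcription drift.

FIXTURE_IDS <- c("table4", "table5", "table6", "table7", "figure2")

#' Load a packaged study table
#'
#' Returns the shipped transcription of one of the study's printed
#' summary tables. Row counts and marginal totals are asserted at load
#' time, so a silently corrupted fixture fails fast.
#'
#' @param table_id one of `"table4"` (per-species curation counts),
#'   `"table5"` (per-family member/subfamily counts), `"table6"`
#'   (per-species family/subfamily counts), `"table7"` (per-species BGC
#'   counts, with the P450-in-cluster occurrences attached as attribute
#'   `"xrefs"`), or `"figure2"` (lifestyle-group family totals and shared
#'   count).
#' @return a `data.frame`; for `"table7"` with attribute `"xrefs"`.
#' @examples
#' tbl4 <- load_fixture("table4")
#' sum(tbl4$p450s)
#' @export
load_fixture <- function(table_id) {
  if (!is.character(table_id) || length(table_id) != 1L ||
      !(table_id %in% FIXTURE_IDS)) {
    stop("unknown fixture table id: ", paste(table_id, collapse = ", "),
         " (known: ", paste(FIXTURE_IDS, collapse = ", "), ")",
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(table_id, ".tsv"),
                      package = "cypome", mustWork = TRUE)
  tbl <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)

  switch(table_id,
    table4 = {
      stopifnot(
        nrow(tbl) == 19L,
        sum(tbl$total_hits) == 779L,
        sum(tbl$p450s) == 668L,
        sum(tbl$fragments) == 88L,
        all(tbl$lifestyle %in% c("SAP", "ECM")),
        all(tbl$total_hits ==
              tbl$p450s + tbl$no_hits + tbl$false_positives + tbl$fragments)
      )
    },
    table5 = {
      stopifnot(nrow(tbl) == 153L, sum(tbl$count) == 668L,
                sum(tbl$n_subfamilies) == 245L,
                !anyDuplicated(tbl$family))
    },
    table6 = {
      stopifnot(nrow(tbl) == 19L, sum(tbl$n_families) == 501L,
                sum(tbl$n_subfamilies) == 580L)
    },
    table7 = {
      stopifnot(nrow(tbl) == 12L, sum(tbl$n_clusters) == 142L)
      xpath <- system.file("extdata", "table7_xrefs.tsv",
                           package = "cypome", mustWork = TRUE)
      xrefs <- read.delim(xpath, stringsAsFactors = FALSE)
      stopifnot(nrow(xrefs) == 9L,
                all(xrefs$species %in% tbl$species))
      attr(tbl, "xrefs") <- xrefs
    },
    figure2 = {
      stopifnot(nrow(tbl) == 3L,
                all(c("SAP", "ECM", "SHARED") %in% tbl$group))
    }
  )
  tbl
}
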