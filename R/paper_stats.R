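#' Headline aggregates of the packaged study tables
#'
#' Recomputes, from the shipped fixture tables, every headline aggregate
#' of the study: curation totals and per-lifestyle means from the
#' per-species census (table4), bloom families and the per-species
#' family mean from the family tables (table5, table6), the two-group
#' family venn arithmetic (figure2), and the BGC totals and P450
#' cluster occurrences (table7). All means use half-away-from-zero
#' rounding ([round_half_away()]).
#'
#' @return a named list: `total_hits`, `total_p450s`, `total_fragments`,
#'   `total_false_positives`, `total_no_hits`, `mean_p450s`,
#'   `sap_mean_p450s`, `ecm_mean_p450s`, `max_p450s`, `min_p450s`,
#'   `max_species`, `min_species`, `n_families`, `n_subfamilies`,
#'   `bloom_families`, `mean_families_per_species`,
#'   `mean_subfamilies_per_species`, `sap_families`, `ecm_families`,
#'   `shared_families`, `unique_sap_families`, `unique_ecm_families`,
#'   `union_families`, `bgc_total_clusters`, `bgc_mean_per_species`,
#'   `bgc_p450_entries`, `bgc_p450_terpene_entries`.
#' @examples
#' stats <- paper_stats()
#' stats$total_p450s
#' @export
paper_stats <- function() {
  rules <- cypome_rules()
  tbl4 <- load_fixture("table4")
  tbl5 <- load_fixture("table5")
  tbl6 <- load_fixture("table6")
  tbl7 <- load_fixture("table7")
  fig2 <- load_fixture("figure2")

  s4 <- summary_stats(tbl4, count_col = "p450s", family_counts = tbl5,
                      rules = rules)

  fam_mean <- round_half_away(mean(tbl6$n_families))
  subfam_mean <- round_half_away(mean(tbl6$n_subfamilies))

  totals <- setNames(fig2$n_families[match(c("SAP", "ECM"), fig2$group)],
                     c("SAP", "ECM"))
  shared <- fig2$n_families[fig2$group == "SHARED"]
  venn <- venn_from_counts(totals, shared)

  xrefs <- attr(tbl7, "xrefs")
  bgc_total <- sum(tbl7$n_clusters)
  bgc_mean <- round_half_away(mean(tbl7$n_clusters))
  terpene_entries <- sum(tolower(xrefs$cluster_type) == "terpene")

  list(
    total_hits = sum(tbl4$total_hits),
    total_p450s = s4$total,
    total_fragments = sum(tbl4$fragments),
    total_false_positives = sum(tbl4$false_positives),
    total_no_hits = sum(tbl4$no_hits),
    mean_p450s = s4$mean,
    sap_mean_p450s = s4$per_group$SAP$mean,
    ecm_mean_p450s = s4$per_group$ECM$mean,
    max_p450s = s4$max,
    min_p450s = s4$min,
    max_species = s4$argmax,
    min_species = s4$argmin,
    n_families = nrow(tbl5),
    n_subfamilies = sum(tbl5$n_subfamilies),
    bloom_families = s4$bloom_families,
    mean_families_per_species = fam_mean,
    mean_subfamilies_per_species = subfam_mean,
    sap_families = unname(totals[["SAP"]]),
    ecm_families = unname(totals[["ECM"]]),
    shared_families = shared,
    unique_sap_families = unname(venn$unique_to_group[["SAP"]]),
    unique_ecm_families = unname(venn$unique_to_group[["ECM"]]),
    union_families = venn$union_size,
    bgc_total_clusters = bgc_total,
    bgc_mean_per_species = bgc_mean,
    bgc_p450_entries = nrow(xrefs),
    bgc_p450_terpene_entries = terpene_entries
  )
}
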