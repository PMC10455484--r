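# Seeded synthetic cohorts with known ground truth: planted P450
# families at controlled identity bands, fragments, decoys, degenerate
# (false-positive) sequences, and BGC tables with planted P450 members.
# This is the test bed standing in for real proteome downloads.

#' Specification for a synthetic cohort
#'
#' Collects every knob of the synthetic-proteome generator. The identity
#' bands are placed around the 40% / 55% nomenclature thresholds so that
#' planted labels are recoverable unambiguously: members mutated into
#' `same_subfamily` ([60, 75]) must inherit family and subfamily,
#' `same_family` ([42, 54]) family only, and `new_family` ([20, 35])
#' must found new families. Bands must be pairwise disjoint and keep at
#' least 1 percent clear of both thresholds.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_species number of species in the cohort.
#' @param n_sap how many of them are saprotrophs (the rest are
#'   ectomycorrhizal).
#' @param n_founder_families number of founder reference families.
#' @param members_per_family integer range (length 2) of members drawn
#'   per planted family per species.
#' @param identity_bands named list of percent-identity bands
#'   (`same_subfamily`, `same_family`, `new_family`).
#' @param fragment_rate,decoy_rate,false_positive_rate expected fraction
#'   of planted P450 members accompanied by fragments / motif-free
#'   decoys / degenerate motif-ablated sequences.
#' @param sequence_length residue-count range for generated sequences.
#' @param band_weights sampling weights for the three bands when drawing
#'   non-lead members.
#' @param p450_per_species optional integer vector (length `n_species`)
#'   fixing the exact number of planted P450s per species, e.g. to size
#'   a cohort after a published per-species P450 census.
#' @param clusters_per_species integer range of BGC counts per species.
#' @param cluster_types vocabulary of cluster type tokens.
#' @param hybrid_rate probability that a cluster gets a two-token hybrid
#'   type.
#' @param p450_in_cluster_rate probability that a species has one
#'   cluster carrying a planted P450 member gene.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_species = 6L,
                           n_sap = 2L,
                           n_founder_families = 5L,
                           members_per_family = c(1L, 3L),
                           identity_bands = list(
                             same_subfamily = c(60, 75),
                             same_family = c(42, 54),
                             new_family = c(20, 35)
                           ),
                           fragment_rate = 0.1,
                           decoy_rate = 0.1,
                           false_positive_rate = 0.05,
                           sequence_length = c(450L, 550L),
                           band_weights = c(same_subfamily = 0.6,
                                            same_family = 0.25,
                                            new_family = 0.15),
                           p450_per_species = NULL,
                           clusters_per_species = c(2L, 4L),
                           cluster_types = c("terpene", "NRPS",
                                             "NRPS-like", "T1PKS",
                                             "fungal-RiPP"),
                           hybrid_rate = 0.1,
                           p450_in_cluster_rate = 0.7) {
  spec <- list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    n_sap = as.integer(n_sap),
    n_founder_families = as.integer(n_founder_families),
    members_per_family = as.integer(members_per_family),
    identity_bands = identity_bands,
    fragment_rate = fragment_rate, decoy_rate = decoy_rate,
    false_positive_rate = false_positive_rate,
    sequence_length = as.integer(sequence_length),
    band_weights = band_weights,
    p450_per_species = p450_per_species,
    clusters_per_species = as.integer(clusters_per_species),
    cluster_types = cluster_types,
    hybrid_rate = hybrid_rate,
    p450_in_cluster_rate = p450_in_cluster_rate
  )
  stopifnot(
    spec$n_species >= 1L, spec$n_sap >= 0L, spec$n_sap <= spec$n_species,
    spec$n_founder_families >= 1L,
    length(spec$members_per_family) == 2L,
    spec$members_per_family[1L] >= 1L,
    diff(spec$members_per_family) >= 0L,
    length(spec$sequence_length) == 2L, spec$sequence_length[1L] >= 60L
  )
  rates <- c(spec$fragment_rate, spec$decoy_rate, spec$false_positive_rate,
             spec$hybrid_rate, spec$p450_in_cluster_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  bands <- spec$identity_bands
  stopifnot(all(c("same_subfamily", "same_family", "new_family") %in%
                  names(bands)))
  for (b in bands) {
    stopifnot(length(b) == 2L, b[1L] <= b[2L], b[1L] >= 0, b[2L] <= 100)
    for (thr in c(40, 55)) {
      if (b[1L] < thr + 1 && b[2L] > thr - 1) {
        stop("identity band [", b[1L], ", ", b[2L],
             "] comes within 1% of the ", thr, "% threshold",
             call. = FALSE)
      }
    }
  }
  o <- order(vapply(bands, `[[`, numeric(1), 1L))
  sorted <- bands[o]
  for (i in seq_len(length(sorted) - 1L)) {
    if (sorted[[i]][2L] >= sorted[[i + 1L]][1L]) {
      stop("identity bands must be disjoint", call. = FALSE)
    }
  }
  if (!is.null(spec$p450_per_species) &&
      length(spec$p450_per_species) != spec$n_species) {
    stop("p450_per_species must have one entry per species", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d species (%d SAP), %d founder families, seed %d\n",
    x$n_species, x$n_sap, x$n_founder_families, x$seed))
  invisible(x)
}

# Random amino-acid sequence as a single string.
random_aa_seq <- function(n, alphabet = AA_CANONICAL) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Generate one founder: random sequence with an EXXR motif implanted
# mid-sequence and a CXG motif implanted in the C-terminal third.
# Fixed motif positions are recorded in attr "protected".
make_founder_seq <- function(len) {
  s <- strsplit(random_aa_seq(len), "", fixed = TRUE)[[1L]]
  mid <- floor(len / 2)
  s[mid] <- "E"
  s[mid + 3L] <- "R"
  c0 <- len - sample(5:25, 1L)  # start of CXG, well inside the final third
  s[c0] <- "C"
  s[c0 + 2L] <- "G"
  out <- paste(s, collapse = "")
  attr(out, "protected") <- c(mid, mid + 3L, c0, c0 + 2L)
  out
}

.make_reference_set <- function(spec, rules = cypome_rules(),
                                max_tries = 50L) {
  refs <- vector("list", spec$n_founder_families)
  seqs <- character(0)
  for (i in seq_len(spec$n_founder_families)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(spec$sequence_length[1L]:spec$sequence_length[2L], 1L)
      cand <- make_founder_seq(len)
      divergent <- all(vapply(seqs, function(s) {
        percent_identity(cand, s, rules) < 35
      }, logical(1)))
      if (divergent) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not generate a founder with <35% identity to the ",
           "existing references after ", max_tries, " attempts",
           call. = FALSE)
    }
    refs[[i]] <- cand
    seqs <- c(seqs, cand)
  }
  # placeholder 9000-series names, outside real CYP family numbering
  names <- sprintf("CYP%dA1", 9000L + seq_len(spec$n_founder_families))
  out <- data.frame(
    cyp_name = names,
    family = sprintf("CYP%d", 9000L + seq_len(spec$n_founder_families)),
    subfamily = "A",
    member = 1L,
    sequence = vapply(refs, as.character, character(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "protected") <- lapply(refs, attr, "protected")
  out
}

#' Generate the named founder reference set
#'
#' Builds `n_founder_families` random full-length P450-like sequences
#' (EXXR implanted mid-sequence, CXG in the C-terminal third), resampled
#' until every founder pair is below 35% identity. Names follow the
#' placeholder series `CYP9001A1`, `CYP9002A1`, ... which lies outside
#' real CYP family numbering.
#'
#' @param spec a [synthetic_spec()].
#' @param rules a [cypome_rules()] object.
#' @return a reference `data.frame` (columns `cyp_name`, `family`,
#'   `subfamily`, `member`, `sequence`) with the fixed motif positions
#'   of each founder in attribute `"protected"`.
#' @export
make_reference_set <- function(spec, rules = cypome_rules()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  .make_reference_set(spec, rules)
}

#' Mutate a sequence into a target identity band
#'
#' Applies random substitutions (never at protected positions, never
#' inserting or deleting) until the global-alignment percent identity to
#' the source sequence falls inside `band`. Substitution-only mutation
#' keeps identity monotone in the number of changed positions, which
#' makes band targeting a short search.
#'
#' @param sequence source amino-acid string.
#' @param band numeric length-2 percent-identity interval.
#' @param rules a [cypome_rules()] object (identity convention).
#' @param protected 1-based positions that must not be substituted
#'   (e.g. fixed motif residues).
#' @param seed optional integer seed; when `NULL` the current RNG state
#'   is used.
#' @param max_iter adjustment-step budget.
#' @return the mutated sequence string.
#' @export
mutate_to_band <- function(sequence, band, rules = cypome_rules(),
                           protected = integer(0), seed = NULL,
                           max_iter = 200L) {
  rules <- as_cypome_rules(rules)
  check_aa_sequence(sequence)
  stopifnot(length(band) == 2L, band[1L] <= band[2L],
            band[1L] >= 0, band[2L] <= 100)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  mutable <- setdiff(seq_len(n), protected)
  floor_pct <- 100 * length(protected) / n
  if (band[2L] < floor_pct) {
    stop("identity band [", band[1L], ", ", band[2L],
         "] is unreachable: ", length(protected), " of ", n,
         " positions are protected (identity floor ",
         sprintf("%.1f", floor_pct), "%)", call. = FALSE)
  }
  substitute_at <- function(ch, pos) {
    for (p in pos) ch[p] <- sample(setdiff(AA_CANONICAL, ch[p]), 1L)
    ch
  }
  target <- mean(band)
  k <- min(length(mutable), max(0L, round(n * (1 - target / 100))))
  touched <- if (k > 0L) sample(mutable, k) else integer(0)
  mut <- substitute_at(chars, touched)
  untouched <- setdiff(mutable, touched)
  for (iter in seq_len(max_iter)) {
    pid <- percent_identity(paste(mut, collapse = ""), sequence, rules)
    if (pid >= band[1L] && pid <= band[2L]) {
      return(paste(mut, collapse = ""))
    }
    if (pid > band[2L]) {
      if (length(untouched) == 0L) {
        stop("identity band unreachable with substitutions only",
             call. = FALSE)
      }
      p <- untouched[1L]
      untouched <- untouched[-1L]
      touched <- c(touched, p)
      mut <- substitute_at(mut, p)
    } else {
      if (length(touched) == 0L) {
        stop("identity band unreachable (already at source identity)",
             call. = FALSE)
      }
      p <- touched[length(touched)]
      touched <- touched[-length(touched)]
      untouched <- c(p, untouched)
      mut[p] <- chars[p]
    }
  }
  stop("failed to reach identity band within ", max_iter, " steps",
       call. = FALSE)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Emulates the inputs of the whole curation pipeline for `n_species`
#' synthetic species: per species, planted family members drawn from
#' the founder references and mutated into the spec's identity bands;
#' fragments made by truncating below the length cutoff or ablating the
#' EXXR motif; decoys drawn from an E/C-free alphabet so neither motif
#' can occur; degenerate (false-positive) sequences made by ablating
#' both motifs from a family member; and per-species BGC tables with
#' planted P450 member genes. Every planted label is recorded.
#'
#' @param spec a [synthetic_spec()].
#' @param rules a [cypome_rules()] object.
#' @return an object of class `cypome_cohort`: a list with `species`
#'   (data.frame `species_id`, `lifestyle`), `references`, `proteins`
#'   (protein records over all species), `truth` (per protein: planted
#'   `category`, `family`, `subfamily`, `band`, `is_new_family`),
#'   `clusters` (a [bgc_clusters()] object), `truth_xrefs`, and `spec`.
#' @export
generate_cohort <- function(spec, rules = cypome_rules()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rules <- as_cypome_rules(rules)
  set.seed(spec$seed)
  refs <- .make_reference_set(spec, rules)
  protected <- attr(refs, "protected")

  species <- data.frame(
    species_id = sprintf("SP%02d", seq_len(spec$n_species)),
    lifestyle = c(rep("SAP", spec$n_sap),
                  rep("ECM", spec$n_species - spec$n_sap)),
    stringsAsFactors = FALSE
  )

  # family plan: founder 1 planted everywhere (a fully conserved family);
  # every other founder in a random subset of species, never empty.
  plan <- matrix(FALSE, spec$n_species, spec$n_founder_families,
                 dimnames = list(species$species_id, refs$family))
  plan[, 1L] <- TRUE
  if (spec$n_founder_families > 1L) {
    for (f in 2L:spec$n_founder_families) {
      plan[, f] <- runif(spec$n_species) < 0.7
      if (!any(plan[, f])) plan[sample(spec$n_species, 1L), f] <- TRUE
    }
  }

  bands <- spec$identity_bands
  prot_rows <- list()
  truth_rows <- list()
  gene_counter <- 0L

  add_protein <- function(sp, seq_str, category, family, subfamily, band,
                          is_new_family) {
    gene_counter <<- gene_counter + 1L
    id <- sprintf("%s_g%04d", sp, gene_counter)
    prot_rows[[length(prot_rows) + 1L]] <<- data.frame(
      id = id, species_id = sp, sequence = seq_str,
      length = nchar(seq_str), stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      id = id, species_id = sp, category = category,
      family = family, subfamily = subfamily, band = band,
      is_new_family = is_new_family, stringsAsFactors = FALSE)
    id
  }

  for (s in seq_len(spec$n_species)) {
    sp <- species$species_id[s]
    planted <- which(plan[s, ])

    if (is.null(spec$p450_per_species)) {
      fam_draw <- unlist(lapply(planted, function(f) {
        rep(f, sample(spec$members_per_family[1L]:spec$members_per_family[2L],
                      1L))
      }))
    } else {
      m_s <- spec$p450_per_species[s]
      fam_draw <- if (m_s >= length(planted)) {
        c(planted, sample_from(planted, m_s - length(planted),
                               replace = TRUE))
      } else {
        sample_from(planted, m_s)
      }
    }

    seen_family <- logical(spec$n_founder_families)
    n_members <- length(fam_draw)
    for (f in fam_draw) {
      # the lead member of each planted family sits in the subfamily band,
      # so the family is recoverable in every species it was planted in
      band_name <- if (!seen_family[f]) {
        "same_subfamily"
      } else {
        sample(names(spec$band_weights), 1L, prob = spec$band_weights)
      }
      seen_family[f] <- TRUE
      mut <- mutate_to_band(refs$sequence[f], bands[[band_name]], rules,
                            protected = protected[[f]])
      if (band_name == "new_family") {
        add_protein(sp, mut, "P450", NA_character_, NA_character_,
                    band_name, TRUE)
      } else {
        add_protein(sp, mut, "P450", refs$family[f],
                    if (band_name == "same_subfamily") refs$subfamily[f]
                    else "NEW",
                    band_name, FALSE)
      }
    }

    n_frag <- round(spec$fragment_rate * n_members)
    for (i in seq_len(n_frag)) {
      f <- sample_from(planted, 1L)
      mut <- mutate_to_band(refs$sequence[f], bands$same_subfamily, rules,
                            protected = protected[[f]])
      if (runif(1) < 0.5) {
        # truncate below the length cutoff, keeping the EXXR motif
        exxr_end <- protected[[f]][2L]
        t_len <- sample(max(exxr_end + 5L, 200L):
                          (rules$fragment_length_cutoff - 1L), 1L)
        frag <- substr(mut, 1L, t_len)
      } else {
        # ablate every EXXR occurrence, keep full length
        frag <- ablate_motif(mut, "EXXR", rules)
      }
      add_protein(sp, frag, "FRAGMENT", NA_character_, NA_character_,
                  "fragment", FALSE)
    }

    n_fp <- round(spec$false_positive_rate * n_members)
    for (i in seq_len(n_fp)) {
      f <- sample_from(planted, 1L)
      mut <- mutate_to_band(refs$sequence[f], bands$same_family, rules,
                            protected = protected[[f]])
      degen <- ablate_motif(ablate_motif(mut, "EXXR", rules), "CXG", rules)
      add_protein(sp, degen, "FALSE_POSITIVE", NA_character_,
                  NA_character_, "degenerate", FALSE)
    }

    n_dec <- round(spec$decoy_rate * n_members)
    for (i in seq_len(n_dec)) {
      len <- sample(spec$sequence_length[1L]:spec$sequence_length[2L], 1L)
      decoy <- random_aa_seq(len, alphabet = setdiff(AA_CANONICAL,
                                                     c("E", "C")))
      add_protein(sp, decoy, "NO_HIT", NA_character_, NA_character_,
                  "decoy", FALSE)
    }
  }

  proteins <- do.call(rbind, prot_rows)
  truth <- do.call(rbind, truth_rows)

  # BGC tables with planted P450 membership
  cl_rows <- list()
  gene_rows <- list()
  xref_rows <- list()
  for (s in seq_len(spec$n_species)) {
    sp <- species$species_id[s]
    n_cl <- sample(spec$clusters_per_species[1L]:
                     spec$clusters_per_species[2L], 1L)
    p450_ids <- truth$id[truth$species_id == sp & truth$category == "P450"]
    plant_cluster <- if (length(p450_ids) > 0L &&
                         runif(1) < spec$p450_in_cluster_rate) {
      sample(n_cl, 1L)
    } else 0L
    for (ci in seq_len(n_cl)) {
      ctype <- sample_from(spec$cluster_types, 1L)
      if (runif(1) < spec$hybrid_rate) {
        ctype <- paste(sort(c(ctype, sample_from(setdiff(spec$cluster_types,
                                                         ctype), 1L))),
                       collapse = ",")
      }
      cl_rows[[length(cl_rows) + 1L]] <- data.frame(
        species_id = sp, cluster_index = ci, cluster_type = ctype,
        stringsAsFactors = FALSE)
      n_genes <- sample(3:6, 1L)
      pos <- cumsum(sample(1500:2500, n_genes))
      for (gi in seq_len(n_genes)) {
        gid <- if (ci == plant_cluster && gi == 1L) {
          sample_from(p450_ids, 1L)
        } else {
          sprintf("%s_c%02d_g%d", sp, ci, gi)
        }
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          species_id = sp, cluster_index = ci, gene_id = gid,
          start = pos[gi] - sample(900:1400, 1L), end = pos[gi],
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
        if (ci == plant_cluster && gi == 1L) {
          xref_rows[[length(xref_rows) + 1L]] <- data.frame(
            species_id = sp, cluster_index = ci, cluster_type = ctype,
            gene_id = gid, stringsAsFactors = FALSE)
        }
      }
    }
  }
  clusters <- bgc_clusters(do.call(rbind, cl_rows), do.call(rbind, gene_rows))
  truth_xrefs <- if (length(xref_rows) > 0L) {
    do.call(rbind, xref_rows)
  } else {
    data.frame(species_id = character(0), cluster_index = integer(0),
               cluster_type = character(0), gene_id = character(0),
               stringsAsFactors = FALSE)
  }

  structure(
    list(species = species, references = refs, proteins = proteins,
         truth = truth, clusters = clusters, truth_xrefs = truth_xrefs,
         spec = spec),
    class = "cypome_cohort"
  )
}

#' @export
print.cypome_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d species, %d proteins (%d planted P450s), %d BGCs\n",
    nrow(x$species), nrow(x$proteins),
    sum(x$truth$category == "P450"), nrow(x$clusters$clusters)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one amino-acid FASTA per species, the reference FASTA (headers
#' carry the CYP names), the species metadata TSV, the BGC cluster TSV,
#' and the truth tables.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cypome_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in cohort$species$species_id) {
    write_fasta(cohort$proteins[cohort$proteins$species_id == sp, ],
                file.path(dir, paste0(sp, ".fasta")))
  }
  write_fasta(data.frame(id = cohort$references$cyp_name,
                         sequence = cohort$references$sequence,
                         stringsAsFactors = FALSE),
              file.path(dir, "references.fasta"))
  write.table(cohort$species, file.path(dir, "species.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cl <- merge(cohort$clusters$genes, cohort$clusters$clusters,
              by = c("species_id", "cluster_index"))
  write.table(cl[, c("species_id", "cluster_index", "cluster_type",
                     "gene_id", "start", "end", "strand")],
              file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth_xrefs, file.path(dir, "truth_xrefs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
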