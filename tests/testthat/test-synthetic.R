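test_that("spec validation rejects inconsistent setups", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(fragment_rate = 1.5), "rates")
  expect_error(
    synthetic_spec(identity_bands = list(same_subfamily = c(54, 75),
                                         same_family = c(42, 53),
                                         new_family = c(20, 35))),
    "threshold")
  expect_error(
    synthetic_spec(identity_bands = list(same_subfamily = c(60, 75),
                                         same_family = c(42, 54),
                                         new_family = c(30, 53))),
    "disjoint|threshold")
  expect_error(synthetic_spec(n_species = 3, p450_per_species = c(5, 5)),
               "one entry per species")
})

test_that("founder references are divergent, motif-bearing and deterministic", {
  spec <- synthetic_spec(seed = 701, n_founder_families = 5)
  refs <- make_reference_set(spec)
  expect_identical(nrow(refs), 5L)
  expect_identical(refs$cyp_name[1], "CYP9001A1")

  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_lt(percent_identity(refs$sequence[i], refs$sequence[j]), 35)
    }
  }
  for (i in 1:5) {
    tr <- triage(list(id = refs$cyp_name[i], sequence = refs$sequence[i]))
    expect_identical(tr$category, "P450")
  }
  expect_identical(make_reference_set(spec), refs)
})

test_that("band-targeted mutation lands inside the requested identity band", {
  set.seed(702)
  src <- rand_aa(500)
  near <- mutate_to_band(src, c(99, 100))
  expect_gte(percent_identity(src, near), 99)

  mid <- mutate_to_band(src, c(60, 75))
  pid <- percent_identity(src, mid)
  expect_gte(pid, 60)
  expect_lte(pid, 75)
  expect_identical(nchar(mid), 500L)

  expect_error(mutate_to_band(src, c(0, 0), protected = c(1L, 2L)),
               "unreachable")
})

test_that("protected motif positions survive band mutation", {
  spec <- synthetic_spec(seed = 703, n_founder_families = 2)
  refs <- make_reference_set(spec)
  prot <- attr(refs, "protected")[[1]]
  mut <- mutate_to_band(refs$sequence[1], c(42, 54), protected = prot)
  src_chars <- strsplit(refs$sequence[1], "")[[1]]
  mut_chars <- strsplit(mut, "")[[1]]
  expect_identical(mut_chars[prot], src_chars[prot])
  expect_identical(triage(list(id = "m", sequence = mut))$category, "P450")
})

test_that("cohorts are reproducible under a fixed seed", {
  spec <- synthetic_spec(seed = 704, n_species = 3,
                         n_founder_families = 3)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$proteins, c2$proteins)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$clusters$genes, c2$clusters$genes)

  c3 <- generate_cohort(synthetic_spec(seed = 999, n_species = 3,
                                       n_founder_families = 3))
  expect_false(identical(c1$proteins$sequence, c3$proteins$sequence))
})

test_that("a zero fragment rate plants no fragments", {
  coh <- generate_cohort(synthetic_spec(seed = 705, n_species = 3,
                                        n_founder_families = 3,
                                        fragment_rate = 0))
  expect_identical(sum(coh$truth$category == "FRAGMENT"), 0L)
})

test_that("the universally planted family is recovered as conserved", {
  coh <- generate_cohort(synthetic_spec(seed = 706, n_species = 4,
                                        n_founder_families = 3))
  asg <- coh$truth[coh$truth$category == "P450" &
                     !coh$truth$is_new_family, ]
  pm <- presence_matrix(asg[, c("species_id", "family")],
                        all_species = coh$species$species_id)
  expect_true("CYP9001" %in% conserved_families(pm, k = 4))
})

test_that("cohort truth labels agree with the triage of every sequence", {
  spec <- synthetic_spec(seed = 707, n_species = 3, n_founder_families = 3,
                         fragment_rate = 0.25, decoy_rate = 0.25,
                         false_positive_rate = 0.15)
  coh <- generate_cohort(spec)
  expect_true(all(c("FRAGMENT", "NO_HIT", "FALSE_POSITIVE") %in%
                    coh$truth$category))
  res <- do.call(rbind, lapply(split(coh$proteins, coh$proteins$species_id),
                               function(p) {
    triage_proteome(p, references = coh$references)$results
  }))
  m <- merge(res, coh$truth, by.x = "protein_id", by.y = "id")
  expect_identical(m$category.x, m$category.y)
})

test_that("cohorts round-trip to disk as plain-text artifacts", {
  coh <- generate_cohort(synthetic_spec(seed = 708, n_species = 2,
                                        n_founder_families = 2))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "SP01.fasta")))
  back <- read_fasta(file.path(dir, "SP01.fasta"), species_id = "SP01")
  orig <- coh$proteins[coh$proteins$species_id == "SP01", ]
  expect_identical(back$sequence, orig$sequence)
  cl <- parse_cluster_table(file.path(dir, "clusters.tsv"))
  expect_identical(nrow(cl$clusters), nrow(coh$clusters$clusters))
  refs <- read_reference_fasta(file.path(dir, "references.fasta"))
  expect_identical(refs$cyp_name, coh$references$cyp_name)
})
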