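test_that("motif scanning finds EXXR anywhere and CXG in the C-terminal third", {
  hits <- scan_motifs("MAAAEALRAAAAAAAAAFGAGPRNCIG")
  expect_identical(hits$match[hits$motif == "EXXR"], "EALR")
  expect_identical(hits$match[hits$motif == "CXG"], "CIG")

  expect_identical(nrow(scan_motifs(strrep("A", 400))), 0L)

  # residues of EXXR present but out of order never match
  expect_identical(nrow(scan_motifs(paste0("RLLE", strrep("A", 30)))), 0L)

  # a Cys-x-Gly outside the final third is not a heme-motif hit
  s <- paste0(strrep("A", 5), "CAG", strrep("A", 292))
  expect_identical(nrow(scan_motifs(s)), 0L)

  # X never satisfies a fixed motif position
  expect_identical(nrow(scan_motifs(paste0("XAAR", strrep("A", 30)))), 0L)

  expect_error(scan_motifs(""), "empty")
})

test_that("overlapping motif matches are all reported with their positions", {
  # EEARR holds two overlapping Glu-x-x-Arg matches, starts 1 and 2
  s <- paste0("EEARR", strrep("A", 25))
  hits <- scan_motifs(s)
  exxr <- hits[hits$motif == "EXXR", ]
  expect_identical(exxr$start, c(1L, 2L))
  expect_identical(exxr$match, c("EEAR", "EARR"))
  expect_identical(substr(s, exxr$start[1], exxr$start[1] + 3L),
                   exxr$match[1])
})

test_that("triage follows the published curation decision table", {
  rules <- cypome_rules()
  cases <- expand.grid(
    motifs = c("none", "exxr", "both"),
    long = c(TRUE, FALSE),
    identity = c(NA, 10, 25),
    stringsAsFactors = FALSE
  )
  expected <- function(motifs, long, identity) {
    if (motifs == "both" && long) return("P450")
    if (motifs %in% c("exxr", "both")) return("FRAGMENT")
    if (!is.na(identity) && identity >= 20) return("FALSE_POSITIVE")
    "NO_HIT"
  }
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    n <- if (cs$long) 450L else 300L
    s <- motif_seq(n, exxr = cs$motifs %in% c("exxr", "both"),
                   cxg = cs$motifs == "both")
    got <- triage(list(id = "q", sequence = s), rules,
                  best_reference_identity = cs$identity)
    expect_identical(
      got$category, expected(cs$motifs, cs$long, cs$identity),
      info = sprintf("motifs=%s long=%s identity=%s",
                     cs$motifs, cs$long, cs$identity))
  }
})

test_that("triage categories partition every proteome", {
  set.seed(202)
  for (rep in 1:5) {
    seqs <- lapply(1:12, function(i) {
      motif_seq(sample(250:500, 1),
                exxr = runif(1) < 0.7, cxg = runif(1) < 0.7)
    })
    recs <- records_of(seqs)
    out <- triage_proteome(recs)
    expect_identical(unname(out$counts["total_hits"]), nrow(recs))
    expect_identical(
      unname(out$counts["total_hits"]),
      unname(sum(out$counts[c("p450s", "fragments", "false_positives",
                              "no_hits")])))
  }
})

test_that("truncation below the length cutoff never leaves a P450 call", {
  set.seed(203)
  full <- motif_seq(480, exxr = TRUE, cxg = TRUE)
  expect_identical(triage(list(id = "q", sequence = full))$category, "P450")
  for (len in sample(30:349, 10)) {
    tr <- triage(list(id = "q", sequence = substr(full, 1, len)))
    expect_true(tr$category != "P450", info = paste("len", len))
  }
})

test_that("ablating the EXXR glutamate demotes a P450 to fragment", {
  s <- motif_seq(450, exxr = TRUE, cxg = TRUE)
  expect_identical(triage(list(id = "q", sequence = s))$category, "P450")
  hits <- scan_motifs(s)
  e_pos <- hits$start[hits$motif == "EXXR"][1]
  substr(s, e_pos, e_pos) <- "A"
  expect_identical(triage(list(id = "q", sequence = s))$category,
                   "FRAGMENT")
})

test_that("proteome triage reproduces planted compositions and guards species mixing", {
  # planted 5 P450s, 2 fragments, 1 decoy, no references
  seqs <- c(
    lapply(1:5, function(i) motif_seq(400 + i)),
    lapply(1:2, function(i) motif_seq(400, cxg = FALSE)),
    list(strrep("A", 420))
  )
  recs <- records_of(seqs)
  out <- triage_proteome(recs)
  expect_identical(unname(out$counts),
                   c(8L, 5L, 2L, 0L, 1L))

  empty <- records_of(list())
  out0 <- triage_proteome(empty)
  expect_true(all(out0$counts == 0L))

  mixed <- rbind(records_of(list(motif_seq(400)), "SP01"),
                 records_of(list(motif_seq(400)), "SP02"))
  expect_error(triage_proteome(mixed), "mix")
})

test_that("a proteome mirroring the Ascobolus immersus composition is recovered", {
  # 58 P450s, 4 no-hits (decoys), 1 false positive (degenerate, needs a
  # reference above the identity heuristic), 0 fragments
  set.seed(204)
  rules <- cypome_rules()
  p450 <- lapply(1:58, function(i) motif_seq(sample(360:500, 1)))
  decoys <- lapply(1:4, function(i) {
    rand_aa(400, alphabet = setdiff(AA20, c("E", "C")))
  })
  base <- motif_seq(420)
  degen <- mutate_to_band(base, c(60, 75))
  degen <- cypome:::ablate_motif(degen, "EXXR")
  degen <- cypome:::ablate_motif(degen, "CXG")
  recs <- records_of(c(p450, decoys, list(degen)))
  refs <- data.frame(cyp_name = "CYP9001A1", sequence = base,
                     stringsAsFactors = FALSE)
  out <- triage_proteome(recs, rules, references = refs)
  expect_identical(unname(out$counts),
                   c(63L, 58L, 0L, 1L, 4L))
})
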