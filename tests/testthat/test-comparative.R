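test_that("presence matrix encodes family occurrence with the +/-3 codes", {
  asg <- data.frame(species_id = c("S1", "S2", "S2"),
                    family = c("CYP51", "CYP51", "CYP52"),
                    stringsAsFactors = FALSE)
  pm <- presence_matrix(asg, all_species = c("S1", "S2"))
  expect_identical(pm, matrix(c(3, 3, -3, 3), 2, 2,
                              dimnames = list(c("S1", "S2"),
                                              c("CYP51", "CYP52"))))

  empty <- presence_matrix(asg[0, ], all_species = c("S1", "S2"),
                           all_families = c("CYP51", "CYP52"))
  expect_true(all(empty == -3))

  expect_error(presence_matrix(
    data.frame(species_id = "S9", family = "CYP51"),
    all_species = c("S1", "S2")), "unknown species")
})

test_that("presence-matrix column sums carry the per-family species counts", {
  set.seed(501)
  for (rep in 1:5) {
    n_sp <- sample(3:6, 1)
    fams <- paste0("CYP", 9000 + 1:4)
    sp <- paste0("S", seq_len(n_sp))
    asg <- data.frame(
      species_id = sample(sp, 30, replace = TRUE),
      family = sample(fams, 30, replace = TRUE),
      stringsAsFactors = FALSE
    )
    pm <- presence_matrix(asg, sp, fams)
    decoded <- as.integer(colSums(pm == 3))
    names(decoded) <- colnames(pm)
    truth <- vapply(fams, function(f) {
      length(unique(asg$species_id[asg$family == f]))
    }, integer(1))
    expect_identical(decoded, truth)
  }
})

test_that("conserved families are thresholded on species counts", {
  asg <- data.frame(species_id = c("S1", "S2", "S2"),
                    family = c("CYP51", "CYP51", "CYP52"),
                    stringsAsFactors = FALSE)
  pm <- presence_matrix(asg, all_species = c("S1", "S2"))
  expect_identical(conserved_families(pm, k = 2), "CYP51")
  expect_identical(conserved_families(pm, k = 1), c("CYP51", "CYP52"))
  expect_error(conserved_families(pm, k = 0), "at least 1")
  expect_error(conserved_families(pm, k = 3), "exceeds")
})

test_that("row/column clustering groups identical profiles first", {
  pm <- rbind(S1 = c(3, 3, -3), S2 = c(-3, -3, 3), S3 = c(3, 3, -3))
  colnames(pm) <- c("F1", "F2", "F3")
  cl <- cluster_rows_cols(pm)
  first_merge <- cl$row_tree$merge[1, ]
  expect_setequal(-first_merge, c(1, 3))     # S1 and S3 merge at height 0
  expect_identical(cl$row_tree$height[1], 0)
  # degenerate 1xN input keeps identity ordering without error
  one <- pm[1, , drop = FALSE]
  cl1 <- cluster_rows_cols(one)
  expect_identical(cl1$row_order, "S1")
  expect_null(cl1$row_tree)
})

test_that("average-linkage merge heights match a brute-force oracle", {
  set.seed(502)
  for (rep in 1:8) {
    nr <- sample(4:8, 1)
    nc <- sample(4:8, 1)
    pm <- matrix(sample(c(-3, 3), nr * nc, replace = TRUE), nr, nc,
                 dimnames = list(paste0("s", 1:nr), paste0("f", 1:nc)))
    cl <- cluster_rows_cols(pm)
    for (axis in list(list(tree = cl$row_tree, m = pm),
                      list(tree = cl$col_tree, m = t(pm)))) {
      D <- as.matrix(dist(axis$m, method = "euclidean"))
      expect_equal(axis$tree$height, avg_linkage_heights(D))
    }
  }
})

test_that("venn partition performs exact set algebra", {
  v <- venn_partition(list(SAP = c("A", "B"), ECM = c("B", "C")))
  expect_identical(v$shared, "B")
  expect_identical(v$unique_to_group$SAP, "A")
  expect_identical(v$unique_to_group$ECM, "C")
  expect_identical(v$union_size, 3L)

  same <- venn_partition(list(g1 = c("A", "B"), g2 = c("B", "A")))
  expect_identical(length(same$unique_to_group$g1), 0L)
  expect_identical(length(same$unique_to_group$g2), 0L)

  expect_error(venn_partition(list()), "non-empty")
})

test_that("venn counts obey the two-group identity on random set pairs", {
  set.seed(503)
  universe <- paste0("CYP", 1:40)
  for (i in 1:100) {
    s1 <- sample(universe, sample(1:30, 1))
    s2 <- sample(universe, sample(1:30, 1))
    v <- venn_partition(list(a = s1, b = s2))
    expect_identical(v$union_size,
                     unname(sum(v$group_totals) - length(v$shared)))
    expect_identical(length(intersect(v$shared, v$unique_to_group$a)), 0L)
    expect_identical(
      v$group_totals[["a"]],
      length(v$shared) + length(v$unique_to_group$a) +
        length(setdiff(intersect(s1, s2), v$shared)))
  }
})

test_that("venn arithmetic from printed totals is exact", {
  v <- venn_from_counts(c(SAP = 103, ECM = 89), shared = 39)
  expect_identical(v$union_size, 153)
  expect_identical(unname(v$unique_to_group["SAP"]), 64)
  expect_identical(unname(v$unique_to_group["ECM"]), 50)
  expect_error(venn_from_counts(c(a = 5, b = 3), shared = 4), "shared")
})

test_that("summary statistics reproduce the fixture aggregates", {
  tbl4 <- load_fixture("table4")
  s <- summary_stats(tbl4, count_col = "p450s",
                     family_counts = load_fixture("table5"))
  expect_identical(s$total, 668L)
  expect_identical(s$mean, 35)
  expect_identical(s$max, 58L)
  expect_identical(s$argmax, "Ascobolus immersus RN42")
  expect_identical(s$min, 17L)
  expect_identical(s$argmin, "Terfezia claveryi T7")
  expect_identical(s$per_group$SAP$mean, 41)
  expect_identical(s$per_group$ECM$mean, 33)
  expect_setequal(s$bloom_families,
                  c("CYP567", "CYP6001", "CYP52", "CYP5959"))

  single <- tbl4[1, ]
  s1 <- summary_stats(single, count_col = "p450s")
  expect_identical(s1$min, s1$max)
  expect_identical(s1$mean, 58)

  broken <- tbl4
  broken$lifestyle[3] <- NA
  expect_error(summary_stats(broken, count_col = "p450s"),
               "missing lifestyle")
})
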