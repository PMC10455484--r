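# Independent oracles and small builders shared across the test files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

b62 <- local({
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

rand_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force Gotoh global alignment score; a gap of length L costs
# open + L * ext. Independent of the package's alignment path.
nw_affine_score <- function(a, b, mat = b62(), open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1L) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in seq_len(m) + 1L) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Quadratic brute-force average-linkage (UPGMA) agglomeration: returns
# the merge heights in merge order. Inter-cluster distance is recomputed
# from scratch at every step as the mean over all cross pairs of
# original point distances (no recursive updates). Ties within eps are
# resolved towards the clusters holding the smallest original indices,
# the same deterministic rule the package contracts.
avg_linkage_heights <- function(D, eps = 1e-9) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    cand <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        key <- c(min(min(clusters[[i]]), min(clusters[[j]])),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        cand <- rbind(cand, c(i, j, d, key))
      }
    }
    dmin <- min(cand[, 3])
    tied <- cand[cand[, 3] <= dmin + eps, , drop = FALSE]
    best <- tied[order(tied[, 4], tied[, 5]), , drop = FALSE][1L, ]
    heights <- c(heights, best[3])
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-c(best[1], best[2])], list(merged))
  }
  heights
}

# A-backbone sequence of length n carrying exactly the requested motifs:
# EXXR as "EAAR" near the N-terminus, CXG as "CAG" in the C-terminal
# third. The alanine backbone contains no E, C or R, so no spurious
# matches can arise.
motif_seq <- function(n, exxr = TRUE, cxg = TRUE) {
  s <- rep("A", n)
  if (exxr) {
    s[10:13] <- c("E", "A", "A", "R")
  }
  if (cxg) {
    p <- n - 5L
    s[p:(p + 2L)] <- c("C", "A", "G")
  }
  paste(s, collapse = "")
}

# Small proteome data.frame builder.
records_of <- function(seqs, species = "SP01") {
  s <- as.character(unlist(seqs))
  data.frame(
    id = sprintf("%s_p%02d", rep_len(species, length(s)), seq_along(s)),
    species_id = rep_len(species, length(s)),
    sequence = s,
    length = nchar(s),
    stringsAsFactors = FALSE
  )
}
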