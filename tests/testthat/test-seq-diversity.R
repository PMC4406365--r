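test_that("diversity statistics match closed forms on constructed alignments", {
  # five identical sequences
  st <- diversityStats(makeAln(setNames(rep("ACGTACGT", 5),
                                        paste0("s", 1:5))))
  expect_equal(st$S, 0L)
  expect_equal(st$K, 1L)
  expect_equal(st$H, 0)
  expect_equal(st$theta_w_locus, 0)
  expect_equal(st$theta_pi_site, 0)
  expect_true(is.na(st$tajima_d))

  # n = 4, S = 3: theta_W = 3 / (1 + 1/2 + 1/3)
  aln <- makeAln(c(a = "AAAAC", b = "AAATC", c = "ATAAC",
                   d = "AAAAG"))
  st <- diversityStats(aln)
  expect_equal(st$S, 3L)
  expect_equal(st$theta_w_locus, 3 / (1 + 1/2 + 1/3),
               tolerance = 1e-6)
  expect_equal(st$theta_w_locus, 1.6364, tolerance = 1e-4)

  # all sequences distinct: H = 1
  aln <- makeAln(c(a = "AAAA", b = "TAAA", c = "ATAA", d = "AATA"))
  expect_equal(diversityStats(aln)$H, 1)
  expect_equal(diversityStats(aln)$K, 4L)

  expect_error(diversityStats(makeAln(c(a = "ACGT"))), "2 sequences")
})

test_that("Tajima's D has the correct sign for skewed frequency spectra", {
  # every segregating site a singleton in n = 10: excess rare variants
  base <- strrep("A", 20)
  seqs <- rep(base, 10)
  for (i in 1:5) substr(seqs[i], i, i) <- "T"
  names(seqs) <- paste0("s", 1:10)
  expect_lt(tajimasD(SequenceAlignment(seqs)), 0)

  # only intermediate-frequency (5/5) variants: positive D
  seqs <- c(rep(paste0(strrep("T", 4), strrep("A", 16)), 5),
            rep(strrep("A", 20), 5))
  names(seqs) <- paste0("s", 1:10)
  expect_gt(tajimasD(SequenceAlignment(seqs)), 0)
})

test_that("Tajima's D and theta_pi equal independent naive implementations", {
  for (seed in c(1, 2, 3)) {
    aln <- randomCoalAln(n = 12, theta = 5, nSites = 600, seed = seed)
    m <- alignmentMatrix(aln)
    expect_equal(tajimasD(aln), oracleTajimaD(m), tolerance = 1e-10)
    expect_equal(diversityStats(aln)$theta_pi_site, oraclePiPerSite(m),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D is invariant to sequence order", {
  aln <- randomCoalAln(n = 10, theta = 6, seed = 4)
  m <- alignmentMatrix(aln)
  set.seed(1)
  perm <- m[sample(nrow(m)), ]
  seqs <- apply(perm, 1, paste, collapse = "")
  expect_equal(tajimasD(SequenceAlignment(seqs)), tajimasD(aln),
               tolerance = 1e-12)
})

test_that("gap/N columns are dropped for S but pairwise-deleted for pi", {
  aln <- makeAln(c(a = "ACGTA", b = "ACG-A", c = "TCGTA"))
  st <- diversityStats(aln)
  expect_equal(st$L_complete, 4L)   # gapped column excluded
  expect_equal(st$S, 1L)            # only the first column segregates
  # pairwise deletion: pair (a,c) still compares all 5 sites
  expect_equal(st$theta_pi_site, mean(c(0 / 4, 1 / 5, 1 / 4)),
               tolerance = 1e-12)
})

test_that("sequence F_ST separates differentiated and identical populations", {
  # internally monomorphic populations with a fixed difference
  a <- makeAln(setNames(rep("AAAA", 4), paste0("a", 1:4)))
  b <- makeAln(setNames(rep("AAAT", 4), paste0("b", 1:4)))
  res <- pairwiseFstSeq(a, b)
  expect_equal(res$fst, 1)

  # identical and monomorphic: undefined
  expect_false(pairwiseFstSeq(a, a)$defined)

  expect_error(pairwiseFstSeq(a, makeAln(c(x = "AAAAA"))), "width")

  # random halves of one panmictic sample: mean F_ST near 0
  fsts <- vapply(1:40, function(s) {
    aln <- randomCoalAln(n = 16, theta = 8, seed = 100 + s)
    m <- alignmentMatrix(aln)
    set.seed(s)
    idx <- sample(16, 8)
    A <- SequenceAlignment(apply(m[idx, ], 1, paste, collapse = ""))
    B <- SequenceAlignment(apply(m[-idx, ], 1, paste, collapse = ""))
    pairwiseFstSeq(A, B)$fst
  }, numeric(1))
  expect_lt(abs(mean(fsts, na.rm = TRUE)), 0.05)
})

test_that("Tajima constant formulas agree with direct summation", {
  for (n in c(4, 12, 30)) {
    cst <- tajimaConstants(n)
    expect_equal(cst$a1, sum(1 / seq_len(n - 1)))
    expect_gt(cst$e1, 0)
    expect_gt(cst$e2, 0)
  }
})
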