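mkPanel <- function(m, pos = NULL, pops = "pop") {
  if (is.null(pos)) pos <- seq_len(ncol(m)) * 100
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  rownames(m) <- paste0("h", seq_len(nrow(m)))
  HaplotypeMatrix(m, pos, chromosome = "chr1", populations = pops)
}

test_that("MAF filtering is inclusive at the boundary and idempotent", {
  # 20 haplotypes: frequencies 0.05, 0.10, 0.50, 0 (monomorphic)
  m <- cbind(c(1, rep(0, 19)),
             c(1, 1, rep(0, 18)),
             rep(c(0, 1), 10),
             rep(0, 20))
  hm <- mkPanel(m)
  filt <- mafFilter(hm, minMaf = 0.1)
  expect_equal(colnames(alleleMatrix(filt)), c("s2", "s3"))
  expect_equal(attr(filt, "nRetained"), 2L)
  again <- mafFilter(filt, minMaf = 0.1)
  expect_equal(alleleMatrix(again), alleleMatrix(filt))

  # constructed panel: 7 of 20 SNPs below threshold
  set.seed(3)
  freqs <- c(rep(0.05, 7), rep(0.3, 13))
  m <- sapply(freqs, function(f)
    c(rep(1, round(f * 40)), rep(0, 40 - round(f * 40))))
  filt <- mafFilter(mkPanel(m), minMaf = 0.1)
  expect_equal(ncol(alleleMatrix(filt)), 13L)

  expect_warning(mafFilter(mkPanel(matrix(0L, 10, 2))), "no SNPs")
})

test_that("r2 matches closed forms and the contingency-table oracle", {
  x <- c(1, 1, 0, 0, 1, 0, 1, 0)
  hm <- mkPanel(cbind(x, x, 1 - x))
  pr <- pairwiseR2(hm)
  expect_equal(pr$r2[pr$snp_i == "s1" & pr$snp_j == "s2"], 1)
  # complementary (relabelled) column also has r2 = 1
  expect_equal(pr$r2[pr$snp_i == "s1" & pr$snp_j == "s3"], 1)

  # one copy of each gamete: D = 0, r2 = 0
  hm <- mkPanel(cbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  pr <- pairwiseR2(hm)
  expect_equal(pr$D, 0)
  expect_equal(pr$r2, 0)

  # random panel with missing data: agree with the 2x2 oracle
  set.seed(12)
  m <- matrix(rbinom(30 * 8, 1, 0.4), nrow = 30)
  m[sample(length(m), 20)] <- NA
  hm <- mkPanel(m)
  pr <- pairwiseR2(hm)
  a <- alleleMatrix(hm)
  for (r in seq_len(nrow(pr))) {
    i <- match(pr$snp_i[r], colnames(a))
    j <- match(pr$snp_j[r], colnames(a))
    expect_equal(pr$r2[r], oracleR2(a[, i], a[, j]),
                 tolerance = 1e-12)
  }

  # monomorphic columns are skipped and counted
  hm <- mkPanel(cbind(c(1, 0, 1, 0), rep(1, 4)))
  pr <- pairwiseR2(hm)
  expect_equal(nrow(pr), 0L)
  expect_equal(attr(pr, "nSkipped"), 1L)
})

test_that("region LD summaries partition pairs and flag empty classes", {
  # 10 SNPs: 5 inside [0, 1000), 5 outside; strong LD inside, weak out
  set.seed(8)
  inBlock <- rbinom(40, 1, 0.5)
  m <- cbind(sapply(1:5, function(i) {
    x <- inBlock
    flip <- sample(40, 2)
    x[flip] <- 1 - x[flip]
    x
  }), matrix(rbinom(40 * 5, 1, 0.5), nrow = 40))
  hm <- mkPanel(m, pos = c(seq(100, 900, length.out = 5),
                           seq(2000, 6000, length.out = 5)))
  pr <- pairwiseR2(hm)
  sm <- regionLdSummary(pr, 0, 1000)
  expect_equal(sm$n_pairs_in, 10L)
  expect_equal(sm$n_pairs_rest, 10L)
  expect_equal(sm$n_pairs_straddling, 25L)
  expect_gt(sm$mean_r2_in_region, sm$mean_r2_rest_of_chromosome)
  # oracle: recompute the in-region mean directly
  direct <- mean(pr$r2[pr$bp_i < 1000 & pr$bp_j < 1000])
  expect_equal(sm$mean_r2_in_region, direct)

  sm <- regionLdSummary(pr, 0, 10000)
  expect_true(sm$undefined[["rest"]])
  expect_true(is.na(sm$mean_r2_rest_of_chromosome))
  sm <- regionLdSummary(pr, 50000, 60000)
  expect_true(sm$undefined[["in_region"]])
})

test_that("haplotype blocks tile the chromosome and recode losslessly", {
  m <- matrix(c(0, 0, 0,
                0, 0, 1,
                0, 1, 0,
                1, 1, 1), nrow = 4, byrow = TRUE)
  hm <- mkPanel(m, pos = c(1000, 4000, 7000))
  bl <- buildHaplotypeBlocks(hm, blockSize = 5000)
  expect_equal(bl$blocks$start, c(0, 5000))
  expect_equal(bl$blocks$end, c(5000, 10000))
  expect_equal(bl$blocks$n_snps, c(2L, 1L))
  expect_equal(bl$members[[1]], c("s1", "s2"))

  # window with strings {00, 00, 01, 11}: 3 dense allele codes
  codes <- bl$alleles[, 1]
  expect_equal(sort(unique(codes)), 0:2)
  expect_equal(as.numeric(table(codes)[as.character(codes[1])]), 2)

  # expanding codes back to strings reproduces the window content
  recon <- bl$strings[[1]][codes + 1]
  orig <- apply(m[, 1:2], 1, paste, collapse = "")
  expect_equal(unname(recon), unname(orig))
})

test_that("mean r2 decays with distance on recombining coalescent panels", {
  binMeans <- matrix(NA_real_, nrow = 60, ncol = 3)
  sims <- simulateCoalescent(n = 20, theta = 15, rho = 30,
                             nSites = 1000, reps = 60, seed = 404)
  for (k in seq_along(sims)) {
    hm <- sims[[k]]
    if (ncol(alleleMatrix(hm)) < 6) next
    hm <- mafFilter(hm, 0.1)
    if (ncol(alleleMatrix(hm)) < 6) next
    pr <- pairwiseR2(hm)
    d <- abs(pr$bp_j - pr$bp_i) / 1000
    bins <- cut(d, c(0, 0.1, 0.3, 0.5), include.lowest = TRUE)
    mm <- tapply(pr$r2, bins, mean)
    binMeans[k, ] <- mm
  }
  avg <- colMeans(binMeans, na.rm = TRUE)
  expect_true(all(diff(avg) < 0))
})
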