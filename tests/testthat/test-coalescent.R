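test_that("identical seeds give byte-identical replicate sets", {
  s1 <- simulateCoalescent(n = 8, theta = 4, rho = 2, reps = 5,
                           seed = 33)
  s2 <- simulateCoalescent(n = 8, theta = 4, rho = 2, reps = 5,
                           seed = 33)
  expect_identical(msLikeText(s1), msLikeText(s2))
  s3 <- simulateCoalescent(n = 8, theta = 4, rho = 2, reps = 5,
                           seed = 34)
  expect_false(identical(msLikeText(s1), msLikeText(s3)))
})

test_that("mean segregating sites matches E[S] = theta * a1", {
  reps <- 800
  sims <- simulateCoalescent(n = 10, theta = 5, rho = 0, reps = reps,
                             seed = 101)
  S <- vapply(sims, function(x) ncol(alleleMatrix(x)), numeric(1))
  a1 <- sum(1 / (1:9))
  se <- sd(S) / sqrt(reps)
  expect_lt(abs(mean(S) - 5 * a1), 3 * se)
})

test_that("mean pairwise difference matches E[pi] = theta for n = 2", {
  reps <- 800
  sims <- simulateCoalescent(n = 2, theta = 2, rho = 0, reps = reps,
                             seed = 102)
  # for n = 2 every segregating site is a pairwise difference
  pi <- vapply(sims, function(x) ncol(alleleMatrix(x)), numeric(1))
  se <- sd(pi) / sqrt(reps)
  expect_lt(abs(mean(pi) - 2), 3 * se)
})

test_that("Watterson's theta from alignments matches diversityStats across fixtures", {
  for (seed in 1:10) {
    aln <- randomCoalAln(n = sample(4:12, 1), theta = runif(1, 1, 8),
                         seed = 200 + seed)
    expect_identical(wattersonTheta(aln),
                     diversityStats(aln)$theta_w_locus)
  }
})

test_that("the neutral D distribution is weakly negatively skewed and tightens with rho", {
  set.seed(55)
  vars <- vapply(c(0, 5, 50), function(rho) {
    d <- teopop:::.simTajimaDCpp(12L, 5, rho, 1500L)
    d <- d[!is.na(d)]
    c(mean(d), var(d))
  }, numeric(2))
  # null mean of D for n = 12, theta = 5
  expect_gt(vars[1, 1], -0.5)
  expect_lt(vars[1, 1], 0.2)
  # variance of D decreases monotonically with recombination
  expect_true(all(diff(vars[2, ]) < 0))
})

test_that("the Tajima null test flags extreme D and accepts central D", {
  # an alignment with a strongly negative D (many singletons)
  base <- strrep("A", 40)
  seqs <- rep(base, 12)
  for (i in 1:11) substr(seqs[i], i, i) <- "T"
  names(seqs) <- paste0("s", 1:12)
  aln <- SequenceAlignment(seqs)
  expect_lt(tajimasD(aln), -1.8)
  nt <- tajimaNullTest(aln, reps = 1000, seed = 77)
  expect_true(nt$significant)
  expect_lte(nt$ci_low, nt$ci_high)

  # D = 0 can never fall outside a central 95% interval
  expect_false(with(nt, 0 < ci_low || 0 > ci_high))

  # determinism of the null test
  nt2 <- tajimaNullTest(aln, reps = 1000, seed = 77)
  expect_identical(nt$ci_low, nt2$ci_low)

  # monomorphic input is an error
  mono <- SequenceAlignment(setNames(rep("ACGT", 6), paste0("m", 1:6)))
  expect_error(tajimaNullTest(mono), "no segregating sites")
})

test_that("ms-style text export lists segsites and positions per replicate", {
  sims <- simulateCoalescent(n = 4, theta = 3, reps = 2, seed = 9)
  txt <- msLikeText(sims)
  expect_equal(sum(txt == "//"), 2L)
  expect_true(any(grepl("^segsites:", txt)))
})
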