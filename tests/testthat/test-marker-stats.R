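mkGeno <- function(calls, pop = "P1", taxon = "parviglumis") {
  n <- length(calls)
  MarkerGenotypes(sprintf("%s_i%02d", rep_len(pop, n), seq_len(n)),
                  rep_len(pop, n), rep_len(taxon, n), calls)
}

test_that("allele frequencies follow the half-call chromosome accounting", {
  f <- alleleFrequencies(mkGeno(c("HH", "HH", "Hh", "Hh", "hh")))
  expect_equal(f$p_hat, 0.6)
  expect_true(f$segregating)

  f <- alleleFrequencies(mkGeno(c("HH", "HH", "HH")))
  expect_equal(f$p_hat, 1)
  expect_false(f$segregating)

  f <- alleleFrequencies(mkGeno(c("HH", "H_half")))
  expect_equal(f$n_chromosomes, 3L)
  expect_equal(f$p_hat, 1)

  # missing calls keep their row but contribute no chromosomes
  f <- alleleFrequencies(mkGeno(c("Hh", "missing", "h_half")))
  expect_equal(f$n_chromosomes, 3L)
  expect_equal(f$n_H, 1L)
})

test_that("the Hardy-Weinberg chi-square test matches a hand-computed oracle", {
  # the phenotyping panel: 82 HH, 104 Hh, 20 hh
  res <- hweTest(82, 104, 20)
  N <- 206
  p <- (2 * 82 + 104) / (2 * N)
  expd <- c(N * p^2, 2 * N * p * (1 - p), N * (1 - p)^2)
  chiOracle <- sum((c(82, 104, 20) - expd)^2 / expd)
  expect_equal(res$chi_square, chiOracle, tolerance = 1e-12)
  expect_gt(res$p_value, 0.05)   # does not deviate from HWE

  # exact HWE proportions
  expect_equal(hweTest(25, 50, 25)$chi_square, 0)

  # no heterozygotes at p = q = 1/2: chi-square = N
  res <- hweTest(50, 0, 50)
  expect_equal(res$chi_square, 100)
  expect_lt(res$p_value, 1e-10)

  # monomorphic sample is flagged undefined
  expect_false(hweTest(10, 0, 0)$defined)
})

test_that("hierarchical F-statistics behave at the boundaries", {
  # two populations with identical allele frequencies, large n
  calls <- c(rep("HH", 25), rep("Hh", 50), rep("hh", 25))
  df <- rbind(genotypeCalls(mkGeno(calls, "A")),
              genotypeCalls(mkGeno(calls, "B")))
  mg <- MarkerGenotypes(paste0(df$population, "_", df$individual),
                        df$population, df$taxon, df$call)
  fs <- hierFstats(mg)
  expect_lt(abs(fs$fst), 0.02)

  # fixed difference
  df <- rbind(genotypeCalls(mkGeno(rep("HH", 20), "A")),
              genotypeCalls(mkGeno(rep("hh", 20), "B")))
  mg <- MarkerGenotypes(paste0(df$population, "_", df$individual),
                        df$population, df$taxon, df$call)
  expect_equal(hierFstats(mg)$fst, 1)
  expect_equal(pairwiseFstMarker(mg, "A", "B"), 1)

  # all populations monomorphic for the same allele: undefined
  df <- rbind(genotypeCalls(mkGeno(rep("HH", 10), "A")),
              genotypeCalls(mkGeno(rep("HH", 10), "B")))
  mg <- MarkerGenotypes(paste0(df$population, "_", df$individual),
                        df$population, df$taxon, df$call)
  expect_false(hierFstats(mg)$defined)

  # a single population cannot be analysed
  expect_error(hierFstats(mkGeno(rep(c("HH", "hh"), 10))),
               ">= 2 populations")
})

test_that("pairwise marker F_ST handles thresholds and unknown ids", {
  calls <- c(rep("HH", 10), rep("hh", 10))
  df <- rbind(genotypeCalls(mkGeno(calls, "A")),
              genotypeCalls(mkGeno(calls, "B")))
  mg <- MarkerGenotypes(paste0(df$population, "_", df$individual),
                        df$population, df$taxon, df$call)
  expect_lt(abs(pairwiseFstMarker(mg, "A", "B")), 0.03)
  expect_error(pairwiseFstMarker(mg, "A", "Z"), "unknown population")

  small <- MarkerGenotypes(c("a1", "a2", "b1", "b2"),
                           c("A", "A", "B", "B"),
                           rep("parviglumis", 4),
                           c("HH", "hh", "Hh", "Hh"))
  expect_error(pairwiseFstMarker(small, "A", "B"), "threshold")
})

test_that("F-statistics are invariant to relabelling individuals within populations", {
  mg <- simulateIslandGenotypes(nTaxa = 2, popsPerTaxon = 4,
                                individualsPerPop = 15, seed = 21)
  fs1 <- hierFstats(mg)
  df <- genotypeCalls(mg)
  set.seed(1)
  for (p in unique(df$population)) {
    sel <- which(df$population == p)
    df$call[sel] <- df$call[sample(sel)]
  }
  mg2 <- MarkerGenotypes(df$individual, df$population, df$taxon,
                         df$call)
  fs2 <- hierFstats(mg2)
  expect_equal(fs2$fst, fs1$fst, tolerance = 1e-12)
  expect_equal(fs2$fct, fs1$fct, tolerance = 1e-12)
  expect_equal(fs2$fsc, fs1$fsc, tolerance = 1e-12)
})

test_that("population frequency tables read and derive counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("population\ttaxon\tn_chromosomes\tfreq_H",
               "SLO\tparviglumis\t50\t0.44",
               "MAIZE1\tmaize\t20\t1.0"), f)
  df <- readFrequencyTable(f)
  expect_equal(df$n_H, c(22L, 20L))
  expect_equal(df$n_h, c(28L, 0L))
})
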