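test_that("the tillering index is the tiller-length sum over height", {
  expect_equal(tilleringIndex(c(10, 20, 30), 60), 1)
  expect_equal(tilleringIndex(numeric(0), 80), 0)
  expect_equal(tilleringIndex(5, 50), 0.1)
  expect_error(tilleringIndex(c(1, 2), 0), "> 0")
  expect_error(tilleringIndex(c(-1, 2), 10), ">= 0")
})

test_that("the Box-Cox transform matches its closed forms and is monotone", {
  expect_equal(boxcoxTransform(0, lambda = 0, offset = 1), 0)
  expect_equal(boxcoxTransform(c(2, 5), lambda = 1, offset = 0),
               c(1, 4))
  set.seed(4)
  y <- runif(50, 0, 3)
  expect_equal(order(boxcoxTransform(y, 0, 1)), order(y))
  expect_error(boxcoxTransform(c(1, -2, 3), 0, 1), "index: 2")
})

test_that("the split-plot decomposition matches a hand-worked balanced oracle", {
  # 2 genotypes x 3 subjects x 2 days, integer responses
  df <- expand.grid(plant = paste0("p", 1:6), day = c(15, 20))
  df$genotype <- ifelse(df$plant %in% paste0("p", 1:3), "hh", "HH")
  df$y <- c(3, 4, 5, 6, 7, 9,   # day 15
            5, 5, 7, 8, 9, 10)  # day 20
  pt <- PhenotypeTable(data.frame(
    plant_id = df$plant, sampling_site = "s1",
    genotype_call = df$genotype, day = df$day,
    tiller_lengths = "", plant_height = 100,
    tiller_number = df$y, culm_diameter = NA_real_))
  # identity-scale transform (lambda = 1, offset 0 shifts by -1 only)
  tab <- repeatedMeasuresAnova(pt, response = "tiller_number",
                               config = assocConfig(boxcoxLambda = 1,
                                                    boxcoxOffset = 1e-9))
  or <- oracleSplitPlot(df$y, df$genotype, df$plant, df$day)
  expect_equal(tab["genotype", "F"], or$F_genotype, tolerance = 1e-8)
  expect_equal(tab["day", "F"], or$F_day, tolerance = 1e-8)
  expect_equal(tab["genotype:day", "F"], or$F_interaction,
               tolerance = 1e-8)
  expect_equal(tab$df, or$df)
  # degrees of freedom are additive to the total
  expect_equal(sum(tab$df), nrow(df) - 1)
})

test_that("split-plot preconditions are enforced", {
  pt <- simulatePhenotypes(nPerGenotype = c(1, 3, 3), seed = 2)
  expect_error(repeatedMeasuresAnova(pt), ">= 2 plants")
  pt <- simulatePhenotypes(nPerGenotype = c(3, 3, 3), seed = 2)
  rec <- phenotypeRecords(pt)
  rec$genotype_call <- "H_half"
  expect_error(repeatedMeasuresAnova(PhenotypeTable(rec)),
               "full diploid")
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  expect_equal(onewayAnova(c(1, 2, 3, 1, 2, 3),
                           rep(c("a", "b"), each = 3))$F, 0)
  set.seed(10)
  v <- rnorm(60)
  g <- sample(c("x", "y", "z"), 60, replace = TRUE)
  got <- onewayAnova(v, g)
  or <- oracleOneway(v, g)
  expect_equal(got$F, or$F, tolerance = 1e-10)
  expect_equal(got$p, or$p, tolerance = 1e-10)
  expect_equal(got$ss_between, or$ss_between, tolerance = 1e-10)
  expect_error(onewayAnova(1:5, rep("a", 5)), "2 groups")
})

test_that("a null genotype effect is usually non-significant at the phenotyping panel's sample sizes", {
  ps <- vapply(1:25, function(s) {
    pt <- simulatePhenotypes(nPerGenotype = c(20, 104, 82),
                             genotypeEffect = 0, seed = 1000 + s)
    repeatedMeasuresAnova(pt)["genotype", "p"]
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})
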