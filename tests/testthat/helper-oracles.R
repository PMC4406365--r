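# Independent reference implementations used as oracles. These are
# deliberately naive (direct per-site counting, explicit loops, 2x2
# contingency tables) and share no code with the package internals.

# mean pairwise difference per site, naive O(n^2 L) double loop with
# pairwise deletion of '-'/'N'
oraclePiPerSite <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- 0; comp <- 0
      for (s in seq_len(ncol(m))) {
        a <- m[i, s]; b <- m[j, s]
        if (a %in% c("-", "N") || b %in% c("-", "N")) next
        comp <- comp + 1
        if (a != b) diffs <- diffs + 1
      }
      vals <- c(vals, if (comp > 0) diffs / comp else NA)
    }
  }
  mean(vals, na.rm = TRUE)
}

# Tajima's D recomputed from first principles on complete-deletion
# columns: direct per-site allele counting for pi, explicit constant
# formulas
oracleTajimaD <- function(m) {
  n <- nrow(m)
  keep <- apply(m, 2, function(col) !any(col %in% c("-", "N")))
  mc <- m[, keep, drop = FALSE]
  segregating <- apply(mc, 2, function(col) length(unique(col)) > 1)
  S <- sum(segregating)
  if (S == 0) return(NA_real_)
  # locus-scale pi: sum over sites of pairwise mismatch counts
  piSum <- 0
  for (s in which(segregating)) {
    counts <- table(mc[, s])
    hom <- sum(counts * (counts - 1) / 2)
    piSum <- piSum + (n * (n - 1) / 2 - hom)
  }
  piLocus <- piSum / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piLocus - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# r^2 between two 0/1 vectors via an explicit 2x2 contingency table
oracleR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# one-way ANOVA by brute-force sums of squares
oracleOneway <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p = pf(Fv, dfb, dfw, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

# balanced split-plot decomposition by explicit means (subjects nested
# in genotype, crossed with day)
oracleSplitPlot <- function(y, genotype, subject, day) {
  N <- length(y)
  gm <- mean(y)
  genotype <- factor(genotype); subject <- factor(subject)
  day <- factor(day)
  nDay <- nlevels(day)
  subjMean <- tapply(y, subject, mean)
  genoOfSubj <- tapply(as.character(genotype), subject, unique)
  genoMean <- tapply(y, genotype, mean)
  dayMean <- tapply(y, day, mean)
  cellMean <- tapply(y, list(genotype, day), mean)
  ssGeno <- sum(table(genotype) * (genoMean - gm)^2)
  ssSubj <- nDay * sum((subjMean - genoMean[genoOfSubj])^2)
  ssDay <- sum(table(day) * (dayMean - gm)^2)
  ssInt <- 0
  for (g in levels(genotype)) for (d in levels(day)) {
    nf <- sum(genotype == g & day == d)
    ssInt <- ssInt + nf * (cellMean[g, d] - genoMean[g] -
                             dayMean[d] + gm)^2
  }
  ssTot <- sum((y - gm)^2)
  ssRes <- ssTot - ssGeno - ssSubj - ssDay - ssInt
  dfG <- nlevels(genotype) - 1
  dfS <- nlevels(subject) - nlevels(genotype)
  dfD <- nDay - 1
  dfI <- dfG * dfD
  dfR <- N - 1 - dfG - dfS - dfD - dfI
  list(F_genotype = as.numeric((ssGeno / dfG) / (ssSubj / dfS)),
       F_day = as.numeric((ssDay / dfD) / (ssRes / dfR)),
       F_interaction = as.numeric((ssInt / dfI) / (ssRes / dfR)),
       ss = as.numeric(c(ssGeno, ssSubj, ssDay, ssInt, ssRes)),
       df = c(dfG, dfS, dfD, dfI, dfR))
}

# random additive distance matrix from a random tree; returns the tree
# and its cophenetic distances
randomAdditiveCase <- function(k) {
  tr <- ape::unroot(ape::rtree(k, br = function(n) runif(n, 0.5, 2)))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# quick alignment builders
makeAln <- function(seqs, ...) SequenceAlignment(seqs, ...)

randomCoalAln <- function(n = 12, theta = 5, nSites = 600, seed = 1) {
  sims <- simulateCoalescent(n = n, theta = theta, reps = 1,
                             seed = seed)
  coalescentToAlignment(sims[[1]], nSites = nSites)
}
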