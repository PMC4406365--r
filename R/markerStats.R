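## Allele frequencies, Hardy-Weinberg tests and hierarchical
## Weir-Cockerham-type F-statistics for the biallelic Hopscotch marker.
##
## F-statistics use moment (ANOVA) variance components computed at the
## chromosome (allele) level on the three-level hierarchy
## taxon / population / chromosome, with the standard unbalanced-design
## coefficients. Half-calls contribute their single scored chromosome;
## they are excluded from Hardy-Weinberg tests, where no diploid
## genotype is defined for them.

## chromosome-level expansion: one row per scored chromosome with its
## H (1) / h (0) state
.chromosomeTable <- function(genotypes) {
  df <- genotypeCalls(genotypes)
  nChrom <- .CALL_CHROMOSOMES[df$call]
  nH <- .CALL_H_COUNT[df$call]
  keep <- nChrom > 0L
  df <- df[keep, , drop = FALSE]
  nChrom <- nChrom[keep]
  nH <- nH[keep]
  idx <- rep.int(seq_len(nrow(df)), nChrom)
  y <- integer(length(idx))
  ## first nH[i] chromosomes of individual i carry H
  pos <- sequence(nChrom)
  y[pos <= nH[idx]] <- 1L
  data.frame(population = df$population[idx], taxon = df$taxon[idx],
             y = y, stringsAsFactors = FALSE)
}

#' Per-population Hopscotch allele frequencies
#'
#' Chromosome accounting follows the assay's half-call rule: full
#' diploid calls contribute two chromosomes, half-calls one, missing
#' none. Populations with zero scored chromosomes are excluded (with a
#' message).
#'
#' @param genotypes A \linkS4class{MarkerGenotypes}.
#' @return Data.frame with one row per population: \code{population},
#'   \code{taxon}, \code{n_H}, \code{n_h}, \code{n_chromosomes},
#'   \code{p_hat} (frequency of the insertion allele H) and
#'   \code{segregating} (\code{0 < p_hat < 1}).
#' @examples
#' mg <- MarkerGenotypes(paste0("i", 1:5), "SLO", "parviglumis",
#'                       c("HH", "HH", "Hh", "Hh", "hh"))
#' alleleFrequencies(mg)  # p_hat = 0.6
#' @export
alleleFrequencies <- function(genotypes) {
  stopifnot(is(genotypes, "MarkerGenotypes"))
  df <- genotypeCalls(genotypes)
  if (nrow(df) < 1L) stop("no genotype records")
  nChrom <- .CALL_CHROMOSOMES[df$call]
  nH <- .CALL_H_COUNT[df$call]
  pops <- unique(df[, c("population", "taxon")])
  out <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    sel <- df$population == pops$population[i] &
      df$taxon == pops$taxon[i]
    data.frame(population = pops$population[i], taxon = pops$taxon[i],
               n_H = sum(nH[sel]),
               n_chromosomes = sum(nChrom[sel]),
               stringsAsFactors = FALSE)
  }))
  empty <- out$n_chromosomes == 0L
  if (any(empty)) {
    message("excluding population(s) with 0 scored chromosomes: ",
            paste(out$population[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  out$n_h <- out$n_chromosomes - out$n_H
  out$p_hat <- out$n_H / out$n_chromosomes
  out$segregating <- out$p_hat > 0 & out$p_hat < 1
  rownames(out) <- NULL
  out[, c("population", "taxon", "n_H", "n_h", "n_chromosomes",
          "p_hat", "segregating")]
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts at a biallelic marker with the
#' Hardy-Weinberg expectations \eqn{(N\hat p^2, 2N\hat p\hat q,
#' N\hat q^2)} using a chi-square statistic with 1 degree of freedom
#' (one allele frequency estimated). Half-calls must be excluded by the
#' caller.
#'
#' @param nHH,nHh,nhh Observed counts of the three genotype classes
#'   (HH = homozygous for the insertion).
#' @return List with \code{observed}, \code{expected}, \code{chi_square},
#'   \code{df}, \code{p_value}, \code{p_hat} and \code{defined}
#'   (\code{FALSE} for monomorphic samples, where the test is
#'   undefined and statistics are NA).
#' @examples
#' hweTest(82, 104, 20)  # the phenotyping panel: non-significant
#' @export
hweTest <- function(nHH, nHh, nhh) {
  stopifnot(nHH >= 0, nHh >= 0, nhh >= 0)
  N <- nHH + nHh + nhh
  if (N < 1L) stop("total genotype count must be >= 1")
  obs <- c(HH = nHH, Hh = nHh, hh = nhh)
  p <- (2 * nHH + nHh) / (2 * N)
  q <- 1 - p
  if (p == 0 || p == 1) {
    return(list(observed = obs, expected = obs, chi_square = NA_real_,
                df = 1L, p_value = NA_real_, p_hat = p,
                defined = FALSE))
  }
  expd <- c(HH = N * p^2, Hh = 2 * N * p * q, hh = N * q^2)
  chi <- sum((obs - expd)^2 / expd)
  list(observed = obs, expected = expd, chi_square = chi, df = 1L,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       p_hat = p, defined = TRUE)
}

## Unbalanced nested random-effects ANOVA on a binary allele indicator.
## groups: outer level (taxon), subgroups: inner level (population).
## Returns moment estimates of the variance components
## (among-groups, among-subgroups-within-groups, within-subgroups).
.nestedComponents <- function(y, group, subgroup) {
  N <- length(y)
  grandMean <- mean(y)
  tab <- data.frame(group = group, subgroup = subgroup, y = y,
                    stringsAsFactors = FALSE)
  sub <- unique(tab[, c("group", "subgroup")])
  nij <- mapply(function(g, s) sum(group == g & subgroup == s),
                sub$group, sub$subgroup)
  pij <- mapply(function(g, s) mean(y[group == g & subgroup == s]),
                sub$group, sub$subgroup)
  grp <- unique(sub$group)
  ni <- vapply(grp, function(g) sum(nij[sub$group == g]), numeric(1))
  pi <- vapply(grp, function(g) {
    sel <- sub$group == g
    sum(nij[sel] * pij[sel]) / ni[match(g, grp)]
  }, numeric(1))
  TT <- length(grp)           # number of groups (taxa)
  P <- nrow(sub)              # total number of subgroups (populations)
  SSW <- sum(nij * pij * (1 - pij))
  SSB <- sum(nij * (pij - pi[match(sub$group, grp)])^2)
  SSA <- sum(ni * (pi - grandMean)^2)
  MSW <- if (N - P > 0) SSW / (N - P) else NA_real_
  MSB <- if (P - TT > 0) SSB / (P - TT) else NA_real_
  MSA <- if (TT - 1 > 0) SSA / (TT - 1) else NA_real_
  sumNij2ByGroup <- vapply(grp, function(g) {
    sel <- sub$group == g
    sum(nij[sel]^2) / ni[match(g, grp)]
  }, numeric(1))
  ## coefficients for the expected mean squares (unbalanced design)
  nB <- if (P - TT > 0) (N - sum(sumNij2ByGroup)) / (P - TT) else NA_real_
  cB <- if (TT > 1) (sum(sumNij2ByGroup) - sum(nij^2) / N) / (TT - 1)
        else NA_real_
  cA <- if (TT > 1) (N - sum(ni^2) / N) / (TT - 1) else NA_real_
  sw <- MSW
  sb <- if (!is.na(MSB) && !is.na(nB) && nB > 0) (MSB - MSW) / nB
        else NA_real_
  sa <- if (!is.na(MSA) && !is.na(cA) && cA > 0)
          (MSA - MSW - cB * ifelse(is.na(sb), 0, sb)) / cA
        else NA_real_
  list(sigma_a = sa, sigma_b = sb, sigma_w = sw,
       n_groups = TT, n_subgroups = P, n_units = N)
}

#' Hierarchical F-statistics for the Hopscotch marker
#'
#' Weir-Cockerham-type moment estimates of the variance components of
#' the allele indicator on the three-level hierarchy taxon /
#' population / chromosome, with the standard coefficients for unequal
#' sample sizes. Only populations contributing at least
#' \code{minChromosomes} scored chromosomes enter the analysis.
#'
#' F_CT measures differentiation among taxa relative to the total,
#' F_SC among populations within taxa, F_ST among populations relative
#' to the total. Negative moment estimates are reported raw and in
#' truncated-at-zero form. A two-level F_ST ignoring the taxon level
#' (\code{fst_pooled}) is also reported.
#'
#' @param genotypes A \linkS4class{MarkerGenotypes}.
#' @param minChromosomes Minimum scored chromosomes per population
#'   (default 8).
#' @return List with \code{components} (variance components),
#'   \code{fct}, \code{fsc}, \code{fst}, \code{fst_pooled} (raw),
#'   \code{fct_trunc}, \code{fsc_trunc}, \code{fst_trunc},
#'   \code{populations_used}, \code{min_chromosomes} and
#'   \code{defined}.
#' @export
hierFstats <- function(genotypes, minChromosomes = 8) {
  stopifnot(is(genotypes, "MarkerGenotypes"))
  chrom <- .chromosomeTable(genotypes)
  counts <- table(chrom$population)
  keep <- names(counts)[counts >= minChromosomes]
  chrom <- chrom[chrom$population %in% keep, , drop = FALSE]
  if (length(unique(chrom$population)) < 2L)
    stop("need >= 2 populations passing the chromosome threshold")
  if (length(unique(chrom$y)) < 2L) {
    return(list(components = NULL, fct = NA_real_, fsc = NA_real_,
                fst = NA_real_, fst_pooled = NA_real_,
                fct_trunc = NA_real_, fsc_trunc = NA_real_,
                fst_trunc = NA_real_,
                populations_used = sort(keep),
                min_chromosomes = minChromosomes, defined = FALSE))
  }
  vc <- .nestedComponents(chrom$y, chrom$taxon, chrom$population)
  tot <- vc$sigma_a + vc$sigma_b + vc$sigma_w
  fct <- vc$sigma_a / tot
  fsc <- vc$sigma_b / (vc$sigma_b + vc$sigma_w)
  fst <- (vc$sigma_a + vc$sigma_b) / tot
  ## two-level version: single dummy top level so sigma_a drops out
  vc2 <- .nestedComponents(chrom$y, rep("all", nrow(chrom)),
                           chrom$population)
  fstPooled <- vc2$sigma_b / (vc2$sigma_b + vc2$sigma_w)
  if (vc$n_groups < 2L) { fct <- NA_real_; fst <- fstPooled }
  list(components = vc,
       fct = fct, fsc = fsc, fst = fst, fst_pooled = fstPooled,
       fct_trunc = if (is.na(fct)) NA_real_ else max(0, fct),
       fsc_trunc = if (is.na(fsc)) NA_real_ else max(0, fsc),
       fst_trunc = if (is.na(fst)) NA_real_ else max(0, fst),
       populations_used = sort(unique(chrom$population)),
       min_chromosomes = minChromosomes, defined = TRUE)
}

#' Pairwise F_ST between two populations at the marker
#'
#' Two-population Weir-Cockerham moment estimator at the chromosome
#' level; negative estimates are reported raw.
#'
#' @param genotypes A \linkS4class{MarkerGenotypes}.
#' @param popA,popB Population ids.
#' @param minChromosomes Minimum scored chromosomes per population.
#' @return Single numeric F_ST estimate (may be negative; NA when both
#'   populations are monomorphic for the same allele).
#' @export
pairwiseFstMarker <- function(genotypes, popA, popB, minChromosomes = 8) {
  stopifnot(is(genotypes, "MarkerGenotypes"))
  chrom <- .chromosomeTable(genotypes)
  pops <- unique(chrom$population)
  for (p in c(popA, popB))
    if (!p %in% pops) stop("unknown population id: ", p)
  chrom <- chrom[chrom$population %in% c(popA, popB), , drop = FALSE]
  counts <- table(chrom$population)
  if (any(counts[c(popA, popB)] < minChromosomes))
    stop("population below the chromosome threshold")
  if (length(unique(chrom$y)) < 2L) return(NA_real_)
  vc <- .nestedComponents(chrom$y, rep("all", nrow(chrom)),
                          chrom$population)
  vc$sigma_b / (vc$sigma_b + vc$sigma_w)
}
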