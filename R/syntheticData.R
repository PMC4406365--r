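## Seeded generators for every input class the analysis consumes:
## hierarchically structured marker genotypes (Balding-Nichols island
## model), coalescent-derived sequence alignments and SNP panels, and
## repeated-measures tillering phenotypes. Every generator is a pure
## function of its seed.

## Balding-Nichols draw: subpopulation frequency around p with
## differentiation F; F = 0 returns p unchanged
.baldingNichols <- function(k, p, F) {
  if (F <= 0) return(rep(p, k))
  stats::rbeta(k, shape1 = p * (1 - F) / F,
               shape2 = (1 - p) * (1 - F) / F)
}

#' Simulate hierarchically structured marker genotypes
#'
#' Taxon-level allele frequencies are drawn from a Balding-Nichols
#' distribution with parameter \code{fctTarget} around
#' \code{ancestralP}; population frequencies are drawn around their
#' taxon frequency with parameter \eqn{F_{SC} = (F_{ST} - F_{CT}) /
#' (1 - F_{CT})}, so that the total population-vs-ancestral
#' differentiation is \code{fstTarget}. Diploid genotypes are binomial
#' (Hardy-Weinberg within populations); half-calls and missing calls
#' are injected at the stated rates.
#'
#' @param nTaxa Number of taxa (groups); taxa are labelled from the
#'   \code{parviglumis,mexicana,maize} vocabulary.
#' @param popsPerTaxon Populations per taxon.
#' @param individualsPerPop Individuals per population.
#' @param ancestralP Ancestral frequency of the insertion allele H.
#' @param fstTarget Target population-vs-total differentiation.
#' @param fctTarget Target taxon-vs-total differentiation.
#' @param halfCallRate,missingRate Per-individual rates of half-calls
#'   and missing calls.
#' @param seed Optional integer seed.
#' @return A \linkS4class{MarkerGenotypes}.
#' @examples
#' mg <- simulateIslandGenotypes(seed = 1)
#' hierFstats(mg)$fst
#' @export
simulateIslandGenotypes <- function(nTaxa = 2, popsPerTaxon = 16,
                                    individualsPerPop = 20,
                                    ancestralP = 0.5,
                                    fstTarget = 0.22, fctTarget = 0,
                                    halfCallRate = 0.02,
                                    missingRate = 0.02, seed = NULL) {
  stopifnot(ancestralP > 0, ancestralP < 1,
            fstTarget >= 0, fstTarget < 1,
            fctTarget >= 0, fctTarget < 1, fctTarget <= fstTarget,
            halfCallRate >= 0, halfCallRate < 1,
            missingRate >= 0, missingRate < 1,
            nTaxa >= 1, nTaxa <= length(.TAXON_VOCAB))
  if (!is.null(seed)) set.seed(seed)
  fsc <- (fstTarget - fctTarget) / (1 - fctTarget)
  taxa <- .TAXON_VOCAB[seq_len(nTaxa)]
  pTaxon <- .baldingNichols(nTaxa, ancestralP, fctTarget)
  rows <- list()
  for (t in seq_len(nTaxa)) {
    pPop <- .baldingNichols(popsPerTaxon, pTaxon[t], fsc)
    pPop <- pmin(pmax(pPop, 1e-12), 1 - 1e-12)
    for (p in seq_len(popsPerTaxon)) {
      dosage <- stats::rbinom(individualsPerPop, 2L, pPop[p])
      call <- c("hh", "Hh", "HH")[dosage + 1L]
      u <- stats::runif(individualsPerPop)
      half <- u < halfCallRate
      miss <- !half & u < halfCallRate + missingRate
      ## half-call: one of the two chromosomes scored at random
      oneAllele <- ifelse(stats::rbinom(individualsPerPop, 1L,
                                        dosage / 2) == 1L,
                          "H_half", "h_half")
      call[half] <- oneAllele[half]
      call[miss] <- "missing"
      popId <- sprintf("%s_p%02d", substr(taxa[t], 1, 4), p)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = sprintf("%s_i%03d", popId,
                             seq_len(individualsPerPop)),
        population = popId, taxon = taxa[t], call = call,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  MarkerGenotypes(df$individual, df$population, df$taxon, df$call)
}

#' Convert a coalescent replicate to a nucleotide alignment
#'
#' Maps the infinite-sites 0/1 segregating-site representation onto a
#' nucleotide alignment of length \code{nSites}: a monomorphic C
#' background with the ancestral allele as A and the derived allele as
#' T at each segregating column, which keeps p-distances and diversity
#' statistics exactly equal to their 0/1 counterparts.
#'
#' @param hm A \linkS4class{HaplotypeMatrix} replicate from
#'   \code{\link{simulateCoalescent}}.
#' @param nSites Alignment length in bp.
#' @param idPrefix Prefix for sequence ids.
#' @param locusLabel,populationLabel Labels for the alignment.
#' @return A \linkS4class{SequenceAlignment}.
#' @export
coalescentToAlignment <- function(hm, nSites = 600, idPrefix = "seq",
                                  locusLabel = "sim",
                                  populationLabel = "sim") {
  stopifnot(is(hm, "HaplotypeMatrix"))
  a <- alleleMatrix(hm)
  n <- nrow(a)
  S <- ncol(a)
  if (S > nSites)
    stop("more segregating sites than alignment columns")
  m <- matrix("C", nrow = n, ncol = nSites)
  if (S > 0) {
    ## map continuous positions to distinct integer columns
    frac <- snpPositions(hm) / max(snpPositions(hm)[S], 1)
    colIdx <- pmin(pmax(ceiling(frac * nSites), 1L), nSites)
    while (anyDuplicated(colIdx)) {
      dup <- which(duplicated(colIdx))
      colIdx[dup] <- colIdx[dup] %% nSites + 1L
    }
    colIdx <- sort(colIdx)
    for (s in seq_len(S))
      m[, colIdx[s]] <- ifelse(a[, s] == 1L, "T", "A")
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- sprintf("%s%02d", idPrefix, seq_len(n))
  SequenceAlignment(seqs, locusLabel = locusLabel,
                    populationLabel = populationLabel)
}

#' Simulate a chromosome-scale phased SNP panel
#'
#' Runs the neutral coalescent at a large per-locus recombination rate
#' and rescales segregating-site positions to a bp interval, emulating
#' a phased chromosome panel with tunable LD decay (larger \code{rho}
#' means faster decay).
#'
#' @param n Haploid sample size (two per individual).
#' @param theta,rho Per-locus population mutation and recombination
#'   rates.
#' @param chromLength Chromosome length in bp.
#' @param chromosome Chromosome label.
#' @param population Population label for all haplotypes.
#' @param seed Optional integer seed.
#' @return A \linkS4class{HaplotypeMatrix} with integer bp positions.
#' @export
simulateSnpPanel <- function(n = 24, theta = 50, rho = 50,
                             chromLength = 3e8, chromosome = "chr1",
                             population = "pop", seed = NULL) {
  sims <- simulateCoalescent(n, theta, rho, nSites = chromLength,
                             reps = 1, seed = seed)
  hm <- sims[[1L]]
  pos <- unique(pmax(1, round(snpPositions(hm))))
  a <- alleleMatrix(hm)[, seq_along(pos), drop = FALSE]
  keep <- c(TRUE, diff(pos) > 0)
  HaplotypeMatrix(a[, keep, drop = FALSE], pos[keep],
                  chromosome = chromosome, populations = population)
}

#' Simulate repeated-measures tillering phenotypes
#'
#' Genotype classes are either fixed (\code{nPerGenotype}, ordered
#' hh/Hh/HH) or drawn at Hardy-Weinberg proportions from
#' \code{hopscotchFreq}. On the analysis (log) scale the response is
#' grand day mean + genotype effect x H dosage + subject random
#' intercept + residual; tiller lengths are back-constructed so the
#' tillering index reproduces the simulated response at the plant's
#' height. Culm diameter is simulated independently of genotype, as an
#' independent control trait.
#'
#' The default day means follow a growth curve on which the tillering
#' index rises from about 0.5 to 2, keeping the log-scale response well
#' away from the zero-tiller boundary; the rare negative draws are
#' clamped to an untillered plant.
#'
#' @param nPerGenotype Integer triple of plants per genotype class
#'   (hh, Hh, HH), or \code{NULL} to draw classes from
#'   \code{hopscotchFreq}.
#' @param nPlants Number of plants when drawing genotype classes.
#' @param hopscotchFreq Frequency of the insertion allele H used for
#'   the Hardy-Weinberg genotype draw.
#' @param genotypeEffect Additive shift per H allele on the log scale,
#'   in units of \code{residualSd}.
#' @param subjectSd,residualSd Random-intercept and residual SDs on
#'   the log scale.
#' @param dayEffects Named numeric vector of log-scale day means
#'   (names = days).
#' @param heightMean,heightSd Plant height distribution (cm).
#' @param seed Optional integer seed.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
simulatePhenotypes <- function(nPerGenotype = NULL, nPlants = 206,
                               hopscotchFreq = 0.65,
                               genotypeEffect = 0,
                               subjectSd = 0.10, residualSd = 0.12,
                               dayEffects = NULL,
                               heightMean = 150, heightSd = 10,
                               seed = NULL) {
  stopifnot(subjectSd > 0, residualSd > 0,
            hopscotchFreq > 0, hopscotchFreq < 1)
  if (!is.null(seed)) set.seed(seed)
  days <- .MEASUREMENT_DAYS
  if (is.null(dayEffects)) {
    ## log(1 + index) means for an index growing ~0.5 -> 2.0
    idx <- seq(0.5, 2.0, length.out = length(days))
    dayEffects <- stats::setNames(log(1 + idx), days)
  }
  stopifnot(length(dayEffects) == length(days))
  if (!is.null(nPerGenotype)) {
    stopifnot(length(nPerGenotype) == 3L)
    dosage <- rep(0:2, times = nPerGenotype)
  } else {
    p <- hopscotchFreq
    dosage <- sample(0:2, nPlants, replace = TRUE,
                     prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }
  nP <- length(dosage)
  call <- c("hh", "Hh", "HH")[dosage + 1L]
  height <- stats::rnorm(nP, heightMean, heightSd)
  height <- pmax(height, 50)
  subj <- stats::rnorm(nP, 0, subjectSd)
  beta <- genotypeEffect * residualSd
  rows <- list()
  for (i in seq_len(nP)) {
    z <- dayEffects + beta * dosage[i] + subj[i] +
      stats::rnorm(length(days), 0, residualSd)
    index <- pmax(exp(z) - 1, 0)
    nTill <- pmax(1L, stats::rpois(length(days), 3))
    nTill[index == 0] <- 0L
    tl <- vapply(seq_along(days), function(d) {
      if (index[d] == 0) return("")
      w <- stats::runif(nTill[d])
      paste(sprintf("%.3f", index[d] * height[i] * w / sum(w)),
            collapse = ",")
    }, character(1))
    culm <- c(rep(NA_real_, length(days) - 1L),
              stats::rnorm(1, 7, 0.8))
    rows[[i]] <- data.frame(
      plant_id = sprintf("plant%03d", i),
      sampling_site = sprintf("site%02d", (i %% 23L) + 1L),
      genotype_call = call[i], day = days,
      tiller_lengths = tl, plant_height = round(height[i], 1),
      tiller_number = nTill,
      culm_diameter = round(culm, 2),
      stringsAsFactors = FALSE)
  }
  PhenotypeTable(do.call(rbind, rows))
}
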