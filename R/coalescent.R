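## Neutral coalescent simulation and the simulation-based significance
## test for Tajima's D. The event engine (ancestral recombination graph
## with infinite-sites mutation) is implemented in C++ and driven by
## R's RNG, so set.seed() gives byte-identical replicate sets.

#' Simulate neutral coalescent samples
#'
#' Hudson-style simulation of \code{n} haploid sequences under the
#' standard neutral model: coalescence at rate \eqn{k(k-1)/2},
#' recombination at rate \eqn{(\rho/2)} per unit of ancestral span,
#' mutations Poisson with rate \eqn{\theta/2} per unit of ancestral
#' branch length, placed under the infinite-sites model on the unit
#' interval. \code{theta} and \code{rho} are per-locus population rates
#' (\eqn{4N\mu} and \eqn{4Nr}).
#'
#' @param n Sample size (haploid sequences), \code{>= 2}.
#' @param theta Population mutation rate per locus, \code{>= 0}.
#' @param rho Population recombination rate per locus, \code{>= 0}.
#' @param nSites Discretisation length: segregating-site positions in
#'   (0,1) are scaled to \code{(0, nSites]} bp.
#' @param reps Number of independent replicates.
#' @param seed Optional integer seed (calls \code{set.seed}).
#' @return List of \code{reps} \linkS4class{HaplotypeMatrix} objects
#'   (segregating-sites representation; replicates with no mutations
#'   have zero SNP columns).
#' @examples
#' sims <- simulateCoalescent(n = 6, theta = 3, reps = 2, seed = 1)
#' ncol(alleleMatrix(sims[[1]]))
#' @export
simulateCoalescent <- function(n, theta, rho = 0, nSites = 1000,
                               reps = 1, seed = NULL) {
  stopifnot(n >= 2, theta >= 0, rho >= 0, reps >= 1, nSites >= 1)
  if (!is.null(seed)) set.seed(seed)
  raw <- .simCoalescentCpp(as.integer(n), theta, rho, as.integer(reps))
  lapply(raw, function(rep) {
    S <- length(rep$positions)
    m <- rep$haplotypes
    if (S > 0) {
      colnames(m) <- paste0("snp", seq_len(S))
      rownames(m) <- paste0("hap", seq_len(n))
      pos <- rep$positions * nSites
    } else {
      m <- matrix(integer(0), nrow = n, ncol = 0,
                  dimnames = list(paste0("hap", seq_len(n)), NULL))
      pos <- numeric(0)
    }
    HaplotypeMatrix(m, pos, chromosome = "sim", populations = "sim")
  })
}

#' Watterson's theta from an observed alignment
#'
#' \eqn{\hat\theta_W = S/a_1} per locus, on complete-deletion sites
#' (shared definition with \code{\link{diversityStats}}).
#'
#' @param aln A \linkS4class{SequenceAlignment} with \code{n >= 2}.
#' @return Numeric theta per locus.
#' @export
wattersonTheta <- function(aln) {
  diversityStats(aln)$theta_w_locus
}

#' Coalescent-simulation significance test for Tajima's D
#'
#' Simulates \code{reps} neutral replicates at the alignment's sample
#' size with \code{theta} set to the observed Watterson estimate and,
#' by default, an identical per-locus recombination rate
#' (\code{rho = theta}). The observed D is compared with the empirical
#' equal-tailed 95\% interval of the simulated D distribution;
#' replicates with no segregating sites yield undefined D and are
#' excluded from the quantiles but counted.
#'
#' @param aln A \linkS4class{SequenceAlignment} with at least one
#'   segregating site and \code{n >= 4}.
#' @param reps Number of coalescent replicates (default 10000).
#' @param seed Optional integer seed.
#' @param rho Per-locus recombination rate for the null; default
#'   \code{NULL} means equal to the observed theta.
#' @param level Interval coverage (default 0.95, equal-tailed).
#' @return List with \code{observed_d}, \code{null_mean},
#'   \code{null_sd}, \code{ci_low}, \code{ci_high},
#'   \code{significant}, \code{reps_used}, \code{reps_undefined},
#'   \code{theta}, \code{rho}.
#' @export
tajimaNullTest <- function(aln, reps = 10000, seed = NULL, rho = NULL,
                           level = 0.95) {
  stopifnot(is(aln, "SequenceAlignment"), reps >= 1)
  n <- nSequences(aln)
  if (n < 4L) stop("need n >= 4")
  st <- diversityStats(aln)
  if (st$S < 1L || st$theta_w_locus <= 0)
    stop("no segregating sites: neutrality test impossible")
  theta <- st$theta_w_locus
  if (is.null(rho)) rho <- theta
  obsD <- st$tajima_d
  if (!is.null(seed)) set.seed(seed)
  d <- .simTajimaDCpp(as.integer(n), theta, rho, as.integer(reps))
  undef <- sum(is.na(d))
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("all null replicates had S = 0")
  alpha <- (1 - level) / 2
  ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(observed_d = obsD, null_mean = mean(d), null_sd = stats::sd(d),
       ci_low = ci[1L], ci_high = ci[2L],
       significant = obsD < ci[1L] || obsD > ci[2L],
       reps_used = length(d), reps_undefined = undef,
       theta = theta, rho = rho)
}

#' Format replicates as ms-style text
#'
#' Writes the classic segregating-sites text block (\code{//},
#' \code{segsites:}, \code{positions:} and 0/1 haplotype rows) for
#' cross-validation against external coalescent simulators.
#'
#' @param sims List of \linkS4class{HaplotypeMatrix} replicates from
#'   \code{\link{simulateCoalescent}}.
#' @param nSites The \code{nSites} used at simulation time (positions
#'   are rescaled back to (0,1)).
#' @return Character vector of output lines.
#' @export
msLikeText <- function(sims, nSites = 1000) {
  out <- character(0)
  for (rep in sims) {
    a <- alleleMatrix(rep)
    pos <- snpPositions(rep) / nSites
    out <- c(out, "//", paste("segsites:", ncol(a)))
    if (ncol(a) > 0) {
      out <- c(out,
               paste("positions:", paste(sprintf("%.5f", pos),
                                         collapse = " ")),
               apply(a, 1L, paste, collapse = ""))
    }
  }
  out
}
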