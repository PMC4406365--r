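## Standard per-population sequence diversity statistics and a
## pi-based pairwise F_ST between population alignments.
##
## Site filtering: segregating-site based statistics (S, Watterson's
## theta, Tajima's D, haplotype counts) use complete deletion - columns
## containing "-" or "N" in any sequence are dropped. Per-site pairwise
## diversity (theta_pi) and distances use pairwise deletion with their
## own comparable-site denominators. Both effective lengths are
## reported.

.MISSING_RESIDUES <- c("-", "N")

## columns free of gaps/N in every row
.completeColumns <- function(m) {
  colSums(matrix(m %in% .MISSING_RESIDUES, nrow = nrow(m))) == 0L
}

## number of distinct residues per column (complete columns assumed)
.statesPerColumn <- function(m) {
  apply(m, 2L, function(col) length(unique(col)))
}

#' Tajima's D normalisation constants
#'
#' The sample-size dependent constants used to normalise the difference
#' between pairwise diversity and Watterson's estimator:
#' \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}, \eqn{a_2 = \sum 1/i^2},
#' \eqn{b_1 = (n+1)/(3(n-1))}, \eqn{b_2 = 2(n^2+n+3)/(9n(n-1))},
#' \eqn{c_1 = b_1 - 1/a_1}, \eqn{c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2},
#' \eqn{e_1 = c_1/a_1}, \eqn{e_2 = c_2/(a_1^2 + a_2)}.
#'
#' @param n Sample size (number of sequences), \code{n >= 2}.
#' @return Named list \code{a1, a2, b1, b2, c1, c2, e1, e2}.
#' @export
tajimaConstants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

## mean pairwise difference per site with pairwise deletion;
## returns list(per_site, n_pairs, mean_comparable)
.pairwisePi <- function(m) {
  n <- nrow(m)
  miss <- matrix(m %in% .MISSING_RESIDUES, nrow = n)
  perSite <- numeric(0)
  comp <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- !miss[i, ] & !miss[j, ]
      nc <- sum(ok)
      d <- if (nc > 0) sum(m[i, ok] != m[j, ok]) / nc else NA_real_
      perSite <- c(perSite, d)
      comp <- c(comp, nc)
    }
  }
  list(per_site = mean(perSite, na.rm = TRUE),
       n_pairs = length(perSite),
       mean_comparable = mean(comp))
}

#' Diversity statistics for one population alignment
#'
#' Computes the segregating-site count S, number of distinct haplotypes
#' K, haplotype diversity \eqn{H = \frac{n}{n-1}(1 - \sum_k p_k^2)},
#' Watterson's \eqn{\hat\theta_W = S/a_1} (per locus and per
#' complete-deletion site), per-site pairwise nucleotide diversity
#' \eqn{\hat\theta_\pi} (pairwise deletion), and Tajima's D.
#'
#' @param aln A \linkS4class{SequenceAlignment} with \code{n >= 2}
#'   sequences.
#' @return Named list: \code{n}, \code{L} (alignment width),
#'   \code{L_complete} (complete-deletion sites), \code{L_pairwise}
#'   (mean comparable sites per pair), \code{S}, \code{K}, \code{H},
#'   \code{theta_w_locus}, \code{theta_w_site}, \code{theta_pi_site},
#'   \code{theta_pi_locus} (complete-deletion mean pairwise
#'   differences, the scale entering Tajima's D), \code{tajima_d}
#'   (NA when \code{S = 0} or \code{n < 4}).
#' @examples
#' aln <- SequenceAlignment(c(a = "ACGT", b = "ACGA", c = "ACTT",
#'                            d = "ACGT"))
#' diversityStats(aln)$S
#' @export
diversityStats <- function(aln) {
  stopifnot(is(aln, "SequenceAlignment"))
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  cc <- .completeColumns(m)
  mc <- m[, cc, drop = FALSE]
  S <- if (ncol(mc)) sum(.statesPerColumn(mc) >= 2L) else 0L
  hapStrings <- apply(mc, 1L, paste, collapse = "")
  K <- length(unique(hapStrings))
  pk <- as.numeric(table(hapStrings)) / n
  H <- if (n > 1) (n / (n - 1)) * (1 - sum(pk^2)) else 0
  cst <- tajimaConstants(n)
  thetaWLocus <- S / cst$a1
  Lc <- ncol(mc)
  pw <- .pairwisePi(m)
  ## complete-deletion mean pairwise differences (locus scale), the
  ## quantity compared with S/a1 in Tajima's D
  piLocus <- if (Lc > 0) {
    tot <- 0
    for (i in seq_len(n - 1))
      for (j in seq.int(i + 1, n))
        tot <- tot + sum(mc[i, ] != mc[j, ])
    tot / (n * (n - 1) / 2)
  } else 0
  D <- NA_real_
  if (S >= 1L && n >= 4L) {
    varD <- cst$e1 * S + cst$e2 * S * (S - 1)
    D <- (piLocus - thetaWLocus) / sqrt(varD)
  }
  list(n = n, L = ncol(m), L_complete = Lc,
       L_pairwise = pw$mean_comparable,
       S = S, K = K, H = H,
       theta_w_locus = thetaWLocus,
       theta_w_site = if (Lc > 0) thetaWLocus / Lc else NA_real_,
       theta_pi_site = pw$per_site,
       theta_pi_locus = piLocus,
       tajima_d = D)
}

#' Tajima's D for an alignment
#'
#' \eqn{D = (\hat\theta_\pi^{locus} - \hat\theta_W^{locus}) /
#' \sqrt{e_1 S + e_2 S(S-1)}} on complete-deletion sites. Negative
#' values indicate an excess of rare variants, positive values an
#' excess of intermediate-frequency variants.
#'
#' @param aln A \linkS4class{SequenceAlignment} with \code{n >= 4}.
#' @return Numeric D; NA (with a warning) when \code{S = 0}.
#' @export
tajimasD <- function(aln) {
  stopifnot(is(aln, "SequenceAlignment"))
  if (nSequences(aln) < 4L) stop("Tajima's D requires n >= 4")
  st <- diversityStats(aln)
  if (st$S == 0L) {
    warning("no segregating sites: Tajima's D undefined")
    return(NA_real_)
  }
  st$tajima_d
}

#' Pairwise sequence F_ST between two population alignments
#'
#' \eqn{F_{ST} = 1 - \pi_w/\pi_b}, where \eqn{\pi_w} is the unweighted
#' mean of the two within-population per-site diversities and
#' \eqn{\pi_b} the mean per-site divergence across all between-
#' population sequence pairs (pairwise deletion throughout). Reported
#' raw; may be negative.
#'
#' @param alnA,alnB \linkS4class{SequenceAlignment}s of equal width
#'   (the same locus region).
#' @return List with \code{pi_within}, \code{pi_between}, \code{fst}
#'   and \code{defined} (\code{FALSE} when \eqn{\pi_b = 0}).
#' @export
pairwiseFstSeq <- function(alnA, alnB) {
  stopifnot(is(alnA, "SequenceAlignment"), is(alnB, "SequenceAlignment"))
  if (alignmentWidth(alnA) != alignmentWidth(alnB))
    stop("alignments must have equal width (same locus region)")
  piA <- .pairwisePi(alignmentMatrix(alnA))$per_site
  piB <- .pairwisePi(alignmentMatrix(alnB))$per_site
  mA <- alignmentMatrix(alnA)
  mB <- alignmentMatrix(alnB)
  missA <- matrix(mA %in% .MISSING_RESIDUES, nrow = nrow(mA))
  missB <- matrix(mB %in% .MISSING_RESIDUES, nrow = nrow(mB))
  db <- numeric(0)
  for (i in seq_len(nrow(mA))) {
    for (j in seq_len(nrow(mB))) {
      ok <- !missA[i, ] & !missB[j, ]
      nc <- sum(ok)
      db <- c(db, if (nc > 0) sum(mA[i, ok] != mB[j, ok]) / nc
              else NA_real_)
    }
  }
  piW <- mean(c(piA, piB))
  piBtw <- mean(db, na.rm = TRUE)
  if (!is.finite(piBtw) || piBtw == 0)
    return(list(pi_within = piW, pi_between = piBtw, fst = NA_real_,
                defined = FALSE))
  list(pi_within = piW, pi_between = piBtw, fst = 1 - piW / piBtw,
       defined = TRUE)
}
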