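## MAF filtering, pairwise LD (r2) on phased haplotypes,
## region-vs-chromosome LD summaries and fixed-window haplotype-block
## recoding. r2 requires phased input; unphased data must be phased
## upstream.

#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs whose minor-allele frequency among non-missing haplotypes
#' is at least \code{minMaf} (boundary inclusive); monomorphic SNPs are
#' always removed. Idempotent.
#'
#' @param hm A \linkS4class{HaplotypeMatrix}.
#' @param minMaf Minimum minor allele frequency (default 0.1).
#' @return A filtered \linkS4class{HaplotypeMatrix}; the number of
#'   retained SNPs is attached as attribute \code{"nRetained"}. An
#'   empty result triggers a warning, not an error.
#' @export
mafFilter <- function(hm, minMaf = 0.1) {
  stopifnot(is(hm, "HaplotypeMatrix"), minMaf >= 0, minMaf <= 0.5)
  a <- alleleMatrix(hm)
  p <- colMeans(a, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= minMaf & maf > 0
  if (!any(keep))
    warning("no SNPs pass the MAF filter")
  out <- HaplotypeMatrix(a[, keep, drop = FALSE],
                         snpPositions(hm)[keep],
                         chromosome = hm@chromosome,
                         populations = haplotypePopulations(hm))
  attr(out, "nRetained") <- sum(keep)
  out
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' For every unordered SNP pair, haplotype counts over jointly
#' non-missing haplotypes give \eqn{D = p_{AB} - p_A p_B} and
#' \eqn{r^2 = D^2/(p_A p_a p_B p_b)}, with \eqn{\chi^2 = n r^2}
#' (df = 1). Pairs in which either SNP is monomorphic among the jointly
#' non-missing haplotypes are skipped and counted.
#'
#' @param hm A phased \linkS4class{HaplotypeMatrix} with >= 2 SNPs.
#' @param maxPairs Optional cap on the number of pairs (closest pairs
#'   by column order kept); default all pairs.
#' @return Data.frame with one row per retained pair: \code{snp_i},
#'   \code{snp_j}, \code{bp_i}, \code{bp_j}, \code{n}, \code{D},
#'   \code{r2}, \code{chi_square}, \code{p_value}. The number of
#'   skipped monomorphic pairs is attached as attribute
#'   \code{"nSkipped"}.
#' @export
pairwiseR2 <- function(hm, maxPairs = NULL) {
  stopifnot(is(hm, "HaplotypeMatrix"))
  X <- alleleMatrix(hm)
  if (ncol(X) < 2L) stop("need >= 2 SNPs")
  M <- !is.na(X)
  X0 <- X
  X0[!M] <- 0L
  storage.mode(X0) <- "numeric"
  storage.mode(M) <- "numeric"
  nn <- crossprod(M)            # jointly non-missing haplotypes
  n11 <- crossprod(X0)          # both derived
  nA <- crossprod(X0, M)        # SNP i derived among joint non-missing
  pA <- nA / nn
  pB <- t(nA) / nn
  pAB <- n11 / nn
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- D^2 / denom
  ut <- which(upper.tri(nn), arr.ind = TRUE)
  i <- ut[, 1L]
  j <- ut[, 2L]
  ok <- denom[ut] > 0 & nn[ut] > 0
  nSkipped <- sum(!ok)
  i <- i[ok]; j <- j[ok]
  pos <- snpPositions(hm)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(X)))
  out <- data.frame(snp_i = ids[i], snp_j = ids[j],
                    bp_i = pos[i], bp_j = pos[j],
                    n = nn[cbind(i, j)], D = D[cbind(i, j)],
                    r2 = r2[cbind(i, j)], stringsAsFactors = FALSE)
  out$chi_square <- out$n * out$r2
  out$p_value <- stats::pchisq(out$chi_square, df = 1,
                               lower.tail = FALSE)
  if (!is.null(maxPairs) && nrow(out) > maxPairs) {
    out <- out[order(abs(out$bp_j - out$bp_i)), , drop = FALSE]
    out <- out[seq_len(maxPairs), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "nSkipped") <- nSkipped
  out
}

#' Mean LD inside a region versus the rest of the chromosome
#'
#' A pair is "in region" iff both SNPs lie in the half-open interval
#' \code{[start, end)}; "rest" iff both lie outside. Straddling pairs
#' (one in, one out) are excluded from both means and counted.
#'
#' @param pairs LD pair table from \code{\link{pairwiseR2}} (one
#'   chromosome).
#' @param start,end Region bounds in bp, half-open \code{[start, end)}.
#' @return List with \code{mean_r2_in_region},
#'   \code{mean_r2_rest_of_chromosome}, \code{n_pairs_in},
#'   \code{n_pairs_rest}, \code{n_pairs_straddling}; an empty class
#'   yields an NA mean with a flag in \code{undefined}.
#' @export
regionLdSummary <- function(pairs, start, end) {
  stopifnot(is.data.frame(pairs), end > start)
  inI <- pairs$bp_i >= start & pairs$bp_i < end
  inJ <- pairs$bp_j >= start & pairs$bp_j < end
  both <- inI & inJ
  neither <- !inI & !inJ
  straddle <- !both & !neither
  mIn <- if (any(both)) mean(pairs$r2[both]) else NA_real_
  mRest <- if (any(neither)) mean(pairs$r2[neither]) else NA_real_
  list(mean_r2_in_region = mIn,
       mean_r2_rest_of_chromosome = mRest,
       n_pairs_in = sum(both), n_pairs_rest = sum(neither),
       n_pairs_straddling = sum(straddle),
       undefined = c(in_region = !any(both), rest = !any(neither)))
}

#' Recode a SNP panel into fixed-size haplotype blocks
#'
#' Tiles the chromosome into non-overlapping windows of
#' \code{blockSize} bp anchored at multiples of \code{blockSize} (the
#' first window starts at \code{floor(min_bp/blockSize)*blockSize});
#' within each window every distinct haplotype string becomes one
#' multi-allelic code (dense integers from 0, in order of first
#' appearance). Empty windows are dropped. Haplotype strings containing
#' missing alleles get their own codes per distinct pattern.
#'
#' @param hm A phased \linkS4class{HaplotypeMatrix}.
#' @param blockSize Window size in bp (default 5000, a conservative
#'   size given teosinte's rapid LD decay).
#' @return List with \code{blocks} (data.frame: \code{chromosome},
#'   \code{start}, \code{end}, \code{n_snps}), \code{members} (list of
#'   SNP ids per block), \code{alleles} (integer matrix haplotypes x
#'   blocks of allele codes) and \code{strings} (list of the distinct
#'   haplotype strings per block, indexed by code + 1, enabling exact
#'   reconstruction of the window content).
#' @export
buildHaplotypeBlocks <- function(hm, blockSize = 5000) {
  stopifnot(is(hm, "HaplotypeMatrix"), blockSize >= 1)
  a <- alleleMatrix(hm)
  pos <- snpPositions(hm)
  ids <- colnames(a)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(a)))
  win <- floor(pos / blockSize)
  wins <- sort(unique(win))
  blocks <- data.frame(chromosome = hm@chromosome,
                       start = wins * blockSize,
                       end = (wins + 1) * blockSize)
  members <- lapply(wins, function(w) ids[win == w])
  blocks$n_snps <- lengths(members)
  codeMat <- matrix(NA_integer_, nrow = nrow(a), ncol = length(wins),
                    dimnames = list(rownames(a),
                                    paste0("block", wins)))
  strings <- vector("list", length(wins))
  for (k in seq_along(wins)) {
    sub <- a[, win == wins[k], drop = FALSE]
    sub[is.na(sub)] <- -1L  # distinct token for missing
    hs <- apply(sub, 1L, paste, collapse = "")
    lev <- unique(hs)
    codeMat[, k] <- match(hs, lev) - 1L
    strings[[k]] <- lev
  }
  list(blocks = blocks, members = members, alleles = codeMat,
       strings = strings)
}
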