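## Translation of the two-PCR band-pattern assay into co-dominant
## Hopscotch genotype calls.
##
## The assay runs two PCRs per individual:
##   * flanking (HopF/HopR): 300 bp band = allele without the insertion
##     (h), 5 kb band = allele carrying the Hopscotch (H); heterozygotes
##     show both bands;
##   * internal (HopF/HopIntR): 1.1 kb band iff an H allele is present
##     (the reverse primer sits inside the element's LTR).
## "failed" means the reaction did not resolve; "none" means it resolved
## with no band, which the flanking PCR cannot legitimately produce.

.FLANK_VOCAB <- c("300bp", "5kb", "both", "none", "failed")
.INTERNAL_VOCAB <- c("1.1kb", "none", "failed")

#' Call a Hopscotch genotype from a band pattern
#'
#' Deterministic, total map from the two-PCR band pattern to a genotype
#' call. When both PCRs resolve and agree, a full diploid call is made;
#' when only one PCR resolved well, a single allele is scored
#' (\code{H_half} / \code{h_half}) rather than inferring the diploid
#' genotype. Patterns in which the two PCRs contradict each other (e.g.
#' an internal 1.1 kb band with a flanking 300 bp band only) are scored
#' \code{missing} with the conflict recorded in the result's
#' \code{"reason"} attribute.
#'
#' @param flanking Flanking-PCR result: \code{"300bp"}, \code{"5kb"},
#'   \code{"both"}, \code{"none"} (resolved, no band) or \code{"failed"}.
#' @param internal Internal-PCR result: \code{"1.1kb"}, \code{"none"} or
#'   \code{"failed"}.
#' @return A genotype call string in
#'   \code{HH, Hh, hh, H_half, h_half, missing}, with attribute
#'   \code{"reason"} explaining missing calls.
#' @examples
#' callGenotypeFromBands("both", "1.1kb")   # Hh
#' callGenotypeFromBands("300bp", "none")   # hh
#' callGenotypeFromBands("failed", "1.1kb") # H_half
#' @export
callGenotypeFromBands <- function(flanking, internal) {
  flanking <- match.arg(flanking, .FLANK_VOCAB)
  internal <- match.arg(internal, .INTERNAL_VOCAB)
  reason <- NA_character_
  call <- switch(flanking,
    "300bp" = switch(internal,
      "1.1kb"  = { reason <- "internal H band contradicts hh flanking"
                   "missing" },
      "none"   = "hh",
      "failed" = "h_half"),
    "5kb" = switch(internal,
      "1.1kb"  = "HH",
      "none"   = { reason <- "internal PCR lacks the H band the flanking 5 kb band requires"
                   "missing" },
      "failed" = "H_half"),
    "both" = switch(internal,
      "1.1kb"  = "Hh",
      "none"   = { reason <- "internal PCR lacks the H band the flanking het pattern requires"
                   "missing" },
      ## only the flanking PCR resolved: score one allele, taking the
      ## 5 kb product as direct evidence for H
      "failed" = "H_half"),
    "none" = {
      ## flanking resolved with no band is inconsistent with every
      ## genotype (both alleles amplify in this PCR)
      reason <- "flanking PCR resolved with no band"
      "missing"
    },
    "failed" = switch(internal,
      "1.1kb"  = "H_half",
      "none"   = "h_half",
      "failed" = { reason <- "neither PCR resolved"
                   "missing" }))
  structure(call, reason = reason)
}

#' Convert a band-pattern table to genotype calls
#'
#' @param patterns Data.frame with columns \code{individual},
#'   \code{population}, \code{taxon}, \code{flanking}, \code{internal}.
#' @return A \linkS4class{MarkerGenotypes}; conflicting patterns that
#'   were scored missing are itemised in attribute \code{"conflicts"}.
#' @export
bandPatternsToGenotypes <- function(patterns) {
  need <- c("individual", "population", "taxon", "flanking", "internal")
  if (!all(need %in% names(patterns)))
    stop("band-pattern table must have columns: ",
         paste(need, collapse = ", "))
  calls <- character(nrow(patterns))
  reasons <- character(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    cl <- callGenotypeFromBands(patterns$flanking[i], patterns$internal[i])
    calls[i] <- as.character(cl)
    reasons[i] <- attr(cl, "reason") %||% NA_character_
  }
  mg <- MarkerGenotypes(patterns$individual, patterns$population,
                        patterns$taxon, calls)
  conflicts <- data.frame(individual = patterns$individual,
                          reason = reasons,
                          stringsAsFactors = FALSE)
  attr(mg, "conflicts") <- conflicts[!is.na(conflicts$reason), ,
                                     drop = FALSE]
  mg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
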