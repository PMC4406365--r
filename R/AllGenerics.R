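#' Number of sequences in an alignment
#' @param x A \code{SequenceAlignment}.
#' @return Integer count.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Aligned width (number of columns)
#' @param x A \code{SequenceAlignment}.
#' @return Integer number of aligned sites.
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' Alignment as a character matrix
#' @param x A \code{SequenceAlignment}.
#' @return Character matrix, rows = sequences (named), columns = sites.
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' Sequence identifiers
#' @param x A \code{SequenceAlignment}.
#' @return Character vector of ids.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Genotype call records
#' @param x A \code{MarkerGenotypes}.
#' @return The underlying data.frame of call records.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' Allele matrix of a haplotype panel
#' @param x A \code{HaplotypeMatrix}.
#' @return Integer 0/1/NA matrix (haplotypes x SNPs).
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' SNP base-pair positions
#' @param x A \code{HaplotypeMatrix}.
#' @return Numeric vector of 1-based bp positions.
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))

#' Phenotype records
#' @param x A \code{PhenotypeTable}.
#' @return The underlying data.frame of longitudinal records.
#' @export
setGeneric("phenotypeRecords",
           function(x) standardGeneric("phenotypeRecords"))

#' @rdname nSequences
setMethod("nSequences", "SequenceAlignment",
          function(x) length(x@sequences))

#' @rdname alignmentWidth
setMethod("alignmentWidth", "SequenceAlignment",
          function(x) Biostrings::width(x@sequences)[1L])

#' @rdname alignmentMatrix
setMethod("alignmentMatrix", "SequenceAlignment", function(x) {
  m <- do.call(rbind, strsplit(as.character(x@sequences), "", fixed = TRUE))
  rownames(m) <- names(x@sequences)
  m
})

#' @rdname seqIds
setMethod("seqIds", "SequenceAlignment", function(x) names(x@sequences))

#' @rdname genotypeCalls
setMethod("genotypeCalls", "MarkerGenotypes", function(x) x@calls)

#' @rdname alleleMatrix
setMethod("alleleMatrix", "HaplotypeMatrix", function(x) x@alleles)

#' @rdname snpPositions
setMethod("snpPositions", "HaplotypeMatrix", function(x) x@positions)

#' @rdname phenotypeRecords
setMethod("phenotypeRecords", "PhenotypeTable", function(x) x@records)

#' Population label of each haplotype row
#' @param x A \code{HaplotypeMatrix}.
#' @return Character vector, one entry per haplotype.
#' @export
haplotypePopulations <- function(x) {
  stopifnot(is(x, "HaplotypeMatrix"))
  x@populations
}
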