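#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet width
NULL

.CALL_VOCAB <- c("HH", "Hh", "hh", "H_half", "h_half", "missing")
.TAXON_VOCAB <- c("parviglumis", "mexicana", "maize")

## chromosomes contributed and Hopscotch-allele (H) dosage per call
.CALL_CHROMOSOMES <- c(HH = 2L, Hh = 2L, hh = 2L,
                       H_half = 1L, h_half = 1L, missing = 0L)
.CALL_H_COUNT <- c(HH = 2L, Hh = 1L, hh = 0L,
                   H_half = 1L, h_half = 0L, missing = 0L)

#' SequenceAlignment: an aligned set of sequences for one locus region
#'
#' Container for an equal-length nucleotide alignment (e.g. the ~600 bp
#' regions within the tb1 5' UTR and 66 kb upstream of the tb1 ORF), for
#' one population or a pooled sample. Residues are restricted to
#' \code{A,C,G,T,N,-} after upper-case normalisation.
#'
#' @slot sequences A \code{DNAStringSet} of equal widths with unique names.
#' @slot locusLabel Single string naming the locus region.
#' @slot populationLabel Single string naming the population (may be "").
#' @export
setClass("SequenceAlignment",
         representation(sequences = "DNAStringSet",
                        locusLabel = "character",
                        populationLabel = "character"))

setValidity("SequenceAlignment", function(object) {
  s <- object@sequences
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    bad <- names(s)[which(w != w[1L])[1L]]
    return(sprintf("unequal sequence lengths (offending id: %s)", bad))
  }
  if (w[1L] < 1L) return("alignment width must be >= 1")
  ids <- names(s)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("all sequences must be named")
  if (anyDuplicated(ids))
    return(sprintf("duplicate sequence id: %s", ids[duplicated(ids)][1L]))
  if (length(object@locusLabel) != 1L || length(object@populationLabel) != 1L)
    return("locusLabel and populationLabel must be single strings")
  TRUE
})

#' Construct a SequenceAlignment
#'
#' @param sequences A named character vector or \code{DNAStringSet} of
#'   aligned, equal-length sequences. Lower case is normalised to upper
#'   case; only \code{A,C,G,T,N,-} are accepted.
#' @param locusLabel,populationLabel Optional labels.
#' @return A \code{SequenceAlignment}.
#' @examples
#' aln <- SequenceAlignment(c(s1 = "ACGTAC", s2 = "ACGTAT"))
#' nSequences(aln)
#' @export
SequenceAlignment <- function(sequences, locusLabel = "",
                              populationLabel = "") {
  if (is.character(sequences)) {
    seqs <- toupper(sequences)
    bad <- grepl("[^ACGTN-]", seqs)
    if (any(bad))
      stop("disallowed residue characters in sequence(s): ",
           paste(names(seqs)[bad], collapse = ", "))
    sequences <- Biostrings::DNAStringSet(seqs)
  } else {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  new("SequenceAlignment", sequences = sequences,
      locusLabel = as.character(locusLabel),
      populationLabel = as.character(populationLabel))
}

#' MarkerGenotypes: co-dominant Hopscotch genotype calls
#'
#' Per-individual calls at the biallelic Hopscotch insertion marker
#' (H = insertion present, h = absent), nested within population and
#' taxon. Half-calls (\code{H_half}, \code{h_half}) record a single
#' scored chromosome when only one of the two PCRs resolved;
#' \code{missing} contributes no chromosomes but keeps the record
#' auditable.
#'
#' @slot calls A data.frame with columns \code{individual},
#'   \code{population}, \code{taxon}, \code{call}.
#' @export
setClass("MarkerGenotypes", representation(calls = "data.frame"))

setValidity("MarkerGenotypes", function(object) {
  df <- object@calls
  need <- c("individual", "population", "taxon", "call")
  if (!all(need %in% names(df)))
    return(paste("calls data.frame must have columns:",
                 paste(need, collapse = ", ")))
  if (nrow(df) > 0L) {
    if (anyDuplicated(df$individual))
      return(sprintf("duplicate individual id: %s",
                     df$individual[duplicated(df$individual)][1L]))
    badTaxon <- !df$taxon %in% .TAXON_VOCAB
    if (any(badTaxon))
      return(sprintf("unknown taxon '%s'", df$taxon[badTaxon][1L]))
    badCall <- !df$call %in% .CALL_VOCAB
    if (any(badCall))
      return(sprintf("unknown genotype call '%s'", df$call[badCall][1L]))
  }
  TRUE
})

#' Construct a MarkerGenotypes object
#'
#' @param individual,population,taxon,call Equal-length character vectors;
#'   \code{taxon} in \code{parviglumis,mexicana,maize}; \code{call} in
#'   \code{HH,Hh,hh,H_half,h_half,missing}.
#' @return A \code{MarkerGenotypes}.
#' @export
MarkerGenotypes <- function(individual, population, taxon, call) {
  new("MarkerGenotypes",
      calls = data.frame(individual = as.character(individual),
                         population = as.character(population),
                         taxon = as.character(taxon),
                         call = as.character(call),
                         stringsAsFactors = FALSE))
}

#' HaplotypeMatrix: phased binary SNP haplotypes with a bp map
#'
#' Rows are phased haplotypes (two per individual), columns are biallelic
#' SNPs coded 0/1 with \code{NA} for missing, ordered by strictly
#' increasing base-pair position on one chromosome.
#'
#' @slot alleles Integer matrix (haplotypes x SNPs) with entries 0, 1, NA.
#' @slot positions Numeric vector of 1-based bp positions, strictly
#'   increasing, one per SNP column.
#' @slot chromosome Single chromosome label.
#' @slot populations Character vector, population of each haplotype row.
#' @export
setClass("HaplotypeMatrix",
         representation(alleles = "matrix", positions = "numeric",
                        chromosome = "character", populations = "character"))

setValidity("HaplotypeMatrix", function(object) {
  a <- object@alleles
  if (ncol(a) != length(object@positions))
    return("positions length must equal number of SNP columns")
  if (ncol(a) > 1L && any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  vals <- a[!is.na(a)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    return("allele entries must be 0, 1 or NA")
  if (length(object@populations) != nrow(a))
    return("populations length must equal number of haplotype rows")
  if (length(object@chromosome) != 1L)
    return("chromosome must be a single label")
  TRUE
})

#' Construct a HaplotypeMatrix
#'
#' @param alleles Matrix of 0/1/NA (haplotypes x SNPs); row and column
#'   names identify haplotypes and SNPs.
#' @param positions bp position per SNP column (1-based). Columns are
#'   reordered so positions ascend.
#' @param chromosome Chromosome label.
#' @param populations Population label per haplotype row (recycled if
#'   length 1).
#' @return A \code{HaplotypeMatrix}.
#' @export
HaplotypeMatrix <- function(alleles, positions, chromosome = "chr",
                            populations = "pop") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  o <- order(positions)
  alleles <- alleles[, o, drop = FALSE]
  positions <- positions[o]
  populations <- rep_len(as.character(populations), nrow(alleles))
  new("HaplotypeMatrix", alleles = alleles, positions = positions,
      chromosome = as.character(chromosome), populations = populations)
}

#' PhenotypeTable: longitudinal tillering phenotype records
#'
#' One row per plant per measurement day. Tiller lengths are stored as a
#' comma-separated cm list so the tillering index (sum of tiller lengths /
#' plant height) can be recomputed; culm diameter is measured once per
#' plant (NA on other rows).
#'
#' @slot records A data.frame with columns \code{plant_id},
#'   \code{sampling_site}, \code{genotype_call}, \code{day},
#'   \code{tiller_lengths}, \code{plant_height}, \code{tiller_number},
#'   \code{culm_diameter}.
#' @export
setClass("PhenotypeTable", representation(records = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  df <- object@records
  need <- c("plant_id", "sampling_site", "genotype_call", "day",
            "tiller_lengths", "plant_height", "tiller_number",
            "culm_diameter")
  if (!all(need %in% names(df)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) > 0L) {
    if (any(df$plant_height <= 0, na.rm = TRUE))
      return("plant heights must be > 0")
    if (any(df$tiller_number < 0, na.rm = TRUE))
      return("tiller numbers must be >= 0")
    nCulm <- tapply(!is.na(df$culm_diameter), df$plant_id, sum)
    if (any(nCulm > 1L))
      return("culm_diameter may be recorded at most once per plant")
    if (!all(df$genotype_call %in% .CALL_VOCAB))
      return("genotype_call outside call vocabulary")
  }
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param records Data.frame with the columns documented in
#'   \linkS4class{PhenotypeTable}.
#' @return A \code{PhenotypeTable}.
#' @export
PhenotypeTable <- function(records) {
  new("PhenotypeTable", records = as.data.frame(records))
}

## ---- show methods -------------------------------------------------------

setMethod("show", "SequenceAlignment", function(object) {
  cat(sprintf("SequenceAlignment: %d sequences x %d sites",
              length(object@sequences),
              Biostrings::width(object@sequences)[1L]))
  if (nzchar(object@locusLabel)) cat("  locus:", object@locusLabel)
  if (nzchar(object@populationLabel)) cat("  pop:", object@populationLabel)
  cat("\n")
})

setMethod("show", "MarkerGenotypes", function(object) {
  df <- object@calls
  cat(sprintf("MarkerGenotypes: %d individuals, %d populations, %d taxa\n",
              nrow(df), length(unique(df$population)),
              length(unique(df$taxon))))
  if (nrow(df)) print(table(call = df$call))
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf(
    "HaplotypeMatrix: %d haplotypes x %d SNPs on %s (bp %s-%s)\n",
    nrow(object@alleles), ncol(object@alleles), object@chromosome,
    format(min(object@positions)), format(max(object@positions))))
})

setMethod("show", "PhenotypeTable", function(object) {
  df <- object@records
  cat(sprintf("PhenotypeTable: %d plants, %d records, days %s\n",
              length(unique(df$plant_id)), nrow(df),
              paste(sort(unique(df$day)), collapse = ",")))
})
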