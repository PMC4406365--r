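## Readers and writers for the plain-text formats used across the package.
## All bp coordinates are 1-based; block intervals downstream are
## half-open [start, end). Missing marker genotypes are explicit
## ("missing"), never absent rows, so denominators stay auditable.

#' Read an aligned FASTA file
#'
#' Reads a FASTA alignment, normalises residues to upper case and
#' enforces the alignment invariants: equal lengths, unique ids, and the
#' residue alphabet \code{A,C,G,T,N,-}.
#'
#' @param path Path to a FASTA file.
#' @param locusLabel,populationLabel Optional labels attached to the
#'   returned object.
#' @return A \linkS4class{SequenceAlignment}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTAC", ">s2", "acgtat"), fa)
#' aln <- readFastaAlignment(fa)
#' alignmentMatrix(aln)
#' @export
readFastaAlignment <- function(path, locusLabel = "",
                               populationLabel = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  x <- toupper(as.character(seqs))
  names(x) <- ids
  w <- nchar(x)
  if (length(unique(w)) != 1L) {
    bad <- ids[which(w != w[1L])[1L]]
    stop(sprintf("unequal alignment lengths in %s (offending id: %s)",
                 path, bad))
  }
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1L])
  SequenceAlignment(x, locusLabel = locusLabel,
                    populationLabel = populationLabel)
}

#' Write an alignment as FASTA
#' @param aln A \linkS4class{SequenceAlignment}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeFastaAlignment <- function(aln, path) {
  stopifnot(is(aln, "SequenceAlignment"))
  lines <- as.vector(rbind(paste0(">", seqIds(aln)),
                           as.character(aln@sequences)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a co-dominant marker genotype table
#'
#' Tab-separated with header \code{individual, population, taxon, call}.
#' Unknown taxon or call tokens are rejected with the offending line
#' number (header = line 1).
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{MarkerGenotypes}.
#' @export
readGenotypeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("individual", "population", "taxon", "call")
  if (!all(need %in% names(df)))
    stop("genotype table must have header columns: ",
         paste(need, collapse = ", "))
  badTaxon <- which(!df$taxon %in% .TAXON_VOCAB)
  if (length(badTaxon))
    stop(sprintf("unknown taxon '%s' at line %d of %s",
                 df$taxon[badTaxon[1L]], badTaxon[1L] + 1L, path))
  badCall <- which(!df$call %in% .CALL_VOCAB)
  if (length(badCall))
    stop(sprintf("unknown genotype call '%s' at line %d of %s",
                 df$call[badCall[1L]], badCall[1L] + 1L, path))
  MarkerGenotypes(df$individual, df$population, df$taxon, df$call)
}

#' Write a marker genotype table
#' @param genotypes A \linkS4class{MarkerGenotypes}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypeTable <- function(genotypes, path) {
  stopifnot(is(genotypes, "MarkerGenotypes"))
  utils::write.table(genotypeCalls(genotypes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population-level Hopscotch frequency table
#'
#' Some survey data are published as per-population allele frequencies
#' rather than per-individual calls. The table is tab-separated with
#' header \code{population, taxon, n_chromosomes, freq_H}. Frequency
#' rows are used only for frequency-level statistics, never expanded for
#' Hardy-Weinberg testing.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with columns \code{population}, \code{taxon},
#'   \code{n_chromosomes}, \code{freq_H} plus derived integer counts
#'   \code{n_H}, \code{n_h}.
#' @export
readFrequencyTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "taxon", "n_chromosomes", "freq_H")
  if (!all(need %in% names(df)))
    stop("frequency table must have header columns: ",
         paste(need, collapse = ", "))
  bad <- which(!df$taxon %in% .TAXON_VOCAB)
  if (length(bad))
    stop(sprintf("unknown taxon '%s' at line %d of %s",
                 df$taxon[bad[1L]], bad[1L] + 1L, path))
  if (any(df$freq_H < 0 | df$freq_H > 1))
    stop("freq_H outside [0,1] in ", path)
  df$n_H <- as.integer(round(df$freq_H * df$n_chromosomes))
  df$n_h <- as.integer(df$n_chromosomes) - df$n_H
  df
}

#' Read a phased haplotype matrix with its SNP map
#'
#' The haplotype file is tab-separated with header
#' \code{haplotype, population, <snp ids...>}; entries are \code{0},
#' \code{1} or the missing code. The map file is tab-separated with
#' header \code{snp_id, chromosome, bp} and must cover every SNP column.
#' Columns are reordered by ascending bp position.
#'
#' @param genotypePath Path to the haplotype matrix TSV.
#' @param mapPath Path to the SNP map TSV.
#' @param missingCode Token encoding missing alleles (default "9").
#' @return A \linkS4class{HaplotypeMatrix}; the per-SNP missing fraction
#'   is attached as attribute \code{"missingFraction"}.
#' @export
readHaplotypeMatrix <- function(genotypePath, mapPath, missingCode = "9") {
  if (!file.exists(genotypePath)) stop("file not found: ", genotypePath)
  if (!file.exists(mapPath)) stop("file not found: ", mapPath)
  df <- utils::read.delim(genotypePath, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (!all(c("haplotype", "population") %in% names(df)))
    stop("haplotype matrix must start with columns haplotype, population")
  snpIds <- setdiff(names(df), c("haplotype", "population"))
  if (length(snpIds) == 0L) stop("haplotype matrix has no SNP columns")
  map <- utils::read.delim(mapPath, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chromosome", "bp") %in% names(map)))
    stop("SNP map must have header columns snp_id, chromosome, bp")
  absent <- setdiff(snpIds, map$snp_id)
  if (length(absent))
    stop("SNP missing from map: ", absent[1L])
  raw <- as.matrix(df[, snpIds, drop = FALSE])
  raw[raw == missingCode] <- NA
  bad <- !is.na(raw) & !raw %in% c("0", "1")
  if (any(bad))
    stop(sprintf("non-binary allele code '%s' for SNP %s",
                 raw[bad][1L], snpIds[col(raw)[bad][1L]]))
  m <- matrix(as.integer(raw), nrow = nrow(raw),
              dimnames = list(df$haplotype, snpIds))
  bp <- map$bp[match(snpIds, map$snp_id)]
  hm <- HaplotypeMatrix(m, bp,
                        chromosome = map$chromosome[match(snpIds[1L],
                                                          map$snp_id)],
                        populations = df$population)
  attr(hm, "missingFraction") <- colMeans(is.na(alleleMatrix(hm)))
  hm
}

#' Write a haplotype matrix and its SNP map
#' @param hm A \linkS4class{HaplotypeMatrix}.
#' @param genotypePath,mapPath Output TSV paths.
#' @param missingCode Token to encode missing alleles.
#' @return Invisibly, \code{genotypePath}.
#' @export
writeHaplotypeMatrix <- function(hm, genotypePath, mapPath,
                                 missingCode = "9") {
  stopifnot(is(hm, "HaplotypeMatrix"))
  a <- alleleMatrix(hm)
  out <- matrix(as.character(a), nrow = nrow(a))
  out[is.na(out)] <- missingCode
  df <- data.frame(haplotype = rownames(a),
                   population = haplotypePopulations(hm),
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("haplotype", "population", colnames(a))
  utils::write.table(df, genotypePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map <- data.frame(snp_id = colnames(a), chromosome = hm@chromosome,
                    bp = snpPositions(hm))
  utils::write.table(map, mapPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genotypePath)
}

#' Read a longitudinal phenotype table
#'
#' Tab-separated with header \code{plant_id, sampling_site,
#' genotype_call, day, tiller_lengths, plant_height, tiller_number,
#' culm_diameter}; \code{tiller_lengths} is a comma-separated list of cm
#' values (empty for untillered plants), \code{culm_diameter} is NA
#' except on the single row where it was measured.
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(tiller_lengths = "character"))
  df$tiller_lengths[is.na(df$tiller_lengths)] <- ""
  PhenotypeTable(df)
}

#' Write a phenotype table
#' @param pt A \linkS4class{PhenotypeTable}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writePhenotypeTable <- function(pt, path) {
  stopifnot(is(pt, "PhenotypeTable"))
  utils::write.table(phenotypeRecords(pt), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse comma-separated tiller lengths
#' @param x Character vector of comma-separated cm values ("" = none).
#' @return List of numeric vectors.
#' @export
parseTillerLengths <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE),
         function(v) as.numeric(v[nzchar(v)]))
}

#' Write a tree in Newick format
#'
#' Branch lengths are written as usual; bootstrap supports stored in
#' \code{node.label} are emitted as internal-node labels.
#' \code{readNewickTree(writeNewick(t))} reproduces topology, lengths
#' and supports.
#'
#' @param tree An \code{ape} \code{phylo} object.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An \code{ape} \code{phylo}; numeric internal-node labels are
#'   interpreted as bootstrap supports.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}
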