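## Genome sequence utilities. Genomes are carried as a named character vector
## of chromosome sequences (upper-case ACGTN); FASTA I/O goes through
## Biostrings.

#' Read a genome FASTA
#' @param path FASTA file.
#' @return named character vector, one upper-case sequence per chromosome.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract a genomic subsequence (0-based half-open)
#' @param genome named character vector from [read_genome_fasta()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @return character scalar.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L || start >= end)
    stop(sprintf("invalid range %s:[%s,%s) for length %s", chrom,
                 format(start, scientific = FALSE), format(end, scientific = FALSE), L))
  substr(genome[[chrom]], start + 1, end)
}

#' Reverse complement of a DNA string
#' @param s character scalar over ACGTN.
#' @return character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## encode ACGT -> 1..4, anything else NA
.encode_dna <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, 128)
  code[utf8ToInt(c("A"))] <- 1L
  code[utf8ToInt(c("C"))] <- 2L
  code[utf8ToInt(c("G"))] <- 3L
  code[utf8ToInt(c("T"))] <- 4L
  code[v]
}

.DNA_BASES <- c("A", "C", "G", "T")
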