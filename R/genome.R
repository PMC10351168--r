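#' Load a reference genome from FASTA
#'
#' Reads a (optionally bgzipped) FASTA file into an in-memory genome object.
#' Sequence names must be unique; the alphabet is restricted to A/C/G/T/N.
#'
#' @param path Path to a FASTA file.
#' @return A `GenomeSequence` object: a named [Biostrings::DNAStringSet] with
#'   accessor helpers [genome_subseq()] and [genome_revcomp()].
#' @export
load_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  nm <- sub("\\s.*$", "", nm)  # FASTA headers may carry descriptions
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(seqs) <- nm
  structure(list(seqs = seqs), class = "GenomeSequence")
}

#' Construct a genome object from named character sequences
#'
#' @param x Named character vector of nucleotide sequences.
#' @return A `GenomeSequence`.
#' @export
genome_from_strings <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)), !anyDuplicated(names(x)))
  structure(list(seqs = Biostrings::DNAStringSet(x)), class = "GenomeSequence")
}

#' @export
#' @method print GenomeSequence
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence with", length(x$seqs), "contig(s):\n")
  print(data.frame(contig = names(x$seqs), length = Biostrings::width(x$seqs)))
  invisible(x)
}

#' Contig names of a genome
#' @param genome A `GenomeSequence`.
#' @return Character vector of contig names.
#' @export
genome_names <- function(genome) names(genome$seqs)

#' Contig length
#' @param genome A `GenomeSequence`.
#' @param chrom Contig name.
#' @return Integer length in bp.
#' @export
genome_length <- function(genome, chrom) {
  i <- match(chrom, names(genome$seqs))
  if (is.na(i)) stop("unknown contig: ", chrom)
  Biostrings::width(genome$seqs)[i]
}

#' Extract a genomic subsequence
#'
#' Coordinates are 0-based half-open, the package-internal convention.
#'
#' @param genome A `GenomeSequence`.
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval.
#' @return Character scalar, the forward-strand sequence.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  i <- match(chrom, names(genome$seqs))
  if (is.na(i)) stop("unknown contig: ", chrom)
  len <- Biostrings::width(genome$seqs)[i]
  if (start < 0 || end > len || start > end) {
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, chrom, len))
  }
  if (start == end) return("")
  as.character(Biostrings::subseq(genome$seqs[[i]], start + 1L, end))
}

#' Reverse complement of a nucleotide string
#' @param x Character scalar (A/C/G/T/N).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
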