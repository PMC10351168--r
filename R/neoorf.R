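# Chimeric neo-transcript assembly and frameshift-aware translation.
#
# Conventions:
#  * Intronic breakends splice at the nearest complete exon boundary on the
#    retained side (donor 5' splice site + acceptor 3' splice site, the
#    standard fusion-transcript convention); exonic breakends truncate the
#    exon at the retained base.
#  * CDS intervals exclude the stop codon (Ensembl-style); translation of the
#    wild-type transcript from the CDS start therefore terminates at the stop
#    codon that begins the 3'UTR interval.

.codon_table <- function() Biostrings::GENETIC_CODE

# translate from `from` (0-based) in nt sequence; stops at first stop codon
# (excluded); returns list(aa, termination); codons containing N -> "X";
# trailing incomplete codon discarded
.translate_from <- function(nt, from) {
  gc <- .codon_table()
  n <- nchar(nt)
  aa <- character(0)
  i <- from
  termination <- "READ_THROUGH"
  while (i + 3L <= n) {
    codon <- toupper(substr(nt, i + 1L, i + 3L))
    r <- if (grepl("[^ACGT]", codon)) "X" else unname(gc[[codon]])
    if (identical(r, "*")) { termination <- "STOP"; break }
    aa <- c(aa, r)
    i <- i + 3L
  }
  list(aa = paste(aa, collapse = ""), termination = termination)
}

#' Wild-type protein of a transcript
#'
#' Translates the spliced transcript from its annotated CDS start to the
#' first stop codon.
#'
#' @param tx A coding `TranscriptModel`.
#' @param genome A `GenomeSequence`.
#' @return Character scalar, amino-acid sequence (stop excluded).
#' @export
wt_protein <- function(tx, genome) {
  if (!tx$coding) stop("transcript ", tx$transcript_id, " is noncoding")
  s <- transcript_sequence(tx, genome)
  .translate_from(s, tx$utr5_len)$aa
}

# donor-side retained spliced prefix length (in transcript coordinates)
# for a mapped donor breakend; NA for infeasible regions
.donor_prefix_len <- function(d) {
  tx <- d$transcript
  gpos0 <- d$breakend$pos - 1L
  t <- tx_coord(tx, gpos0)
  if (!is.na(t)) return(t + 1L)                  # retained base included
  i <- .intron_index(tx, gpos0)
  if (is.na(i)) return(NA_integer_)
  .cum_exon_len(tx, i)                           # splice after complete exon i
}

# acceptor-side retained suffix start (transcript coordinate of the first
# retained spliced base)
.acceptor_suffix_start <- function(a) {
  tx <- a$transcript
  gpos0 <- a$breakend$pos - 1L
  t <- tx_coord(tx, gpos0)
  if (!is.na(t)) return(t)
  i <- .intron_index(tx, gpos0)
  if (is.na(i)) return(NA_integer_)
  .cum_exon_len(tx, i)                           # start of exon i+1
}

#' Assemble the chimeric neo-transcript of a feasible SV
#'
#' Concatenates the donor transcript's spliced sequence from its
#' transcription start to the breakend with the acceptor transcript's
#' spliced sequence from the breakend to its 3' end. Junctions whose product
#' lacks the donor 5'UTR plus an intact start codon, or any 3' sequence, are
#' rejected with reason `NO_UTR_STRUCTURE` (unless start-codon rescue is
#' enabled, in which case start-loss events proceed and are flagged).
#'
#' @param ann A feasible `SvAnnotation` (donor/acceptor roles assigned).
#' @param txdb Transcript database.
#' @param genome A `GenomeSequence`.
#' @param start_rescue If `TRUE`, start-loss events are assembled and a
#'   downstream ATG is used at translation time.
#' @param intergenic_tail_nt For read-through into an intergenic acceptor
#'   (see [annotate_sv()]), the maximum unspliced tail length taken from the
#'   genome.
#' @return A `NeoTranscript`, or a character scalar rejection reason
#'   (`"NO_UTR_STRUCTURE"`).
#' @export
assemble_neo_transcript <- function(ann, txdb, genome, start_rescue = FALSE,
                                    intergenic_tail_nt = 10000L) {
  stopifnot(isTRUE(ann$feasible))
  d <- ann$ends[[ann$donor_end]]
  a <- ann$ends[[ann$acceptor_end]]
  dtx <- d$transcript
  dseq_full <- transcript_sequence(dtx, genome)
  dlen <- .donor_prefix_len(d)
  donor_seq <- substr(dseq_full, 1, dlen)
  start_lost <- dlen < dtx$utr5_len + 3L
  if (start_lost && !start_rescue) return("NO_UTR_STRUCTURE")
  acceptor_info <- list(u = NA_integer_, native_phase = NA_integer_,
                        has_coding = FALSE)
  if (!is.null(a$transcript)) {
    atx <- a$transcript
    aseq_full <- transcript_sequence(atx, genome)
    astart <- .acceptor_suffix_start(a)
    acc_seq <- if (astart < nchar(aseq_full))
      substr(aseq_full, astart + 1L, nchar(aseq_full)) else ""
    # native codon phase of the first acceptor-derived coding base
    if (astart < atx$utr5_len) {
      acceptor_info <- list(u = atx$utr5_len - astart, native_phase = 0L,
                            has_coding = TRUE)
    } else if (astart < atx$utr5_len + atx$cds_length) {
      acceptor_info <- list(u = 0L,
                            native_phase = (astart - atx$utr5_len) %% 3L,
                            has_coding = TRUE)
    }
    acceptor_id <- atx$transcript_id
  } else {
    # read-through into intergenic sequence: raw genomic tail
    b <- a$breakend
    clen <- genome_length(genome, b$chrom)
    if (b$orient == "RIGHT") {
      to <- min(clen, (b$pos - 1L) + intergenic_tail_nt)
      acc_seq <- genome_subseq(genome, b$chrom, b$pos - 1L, to)
    } else {
      from <- max(0L, b$pos - intergenic_tail_nt)
      acc_seq <- revcomp(genome_subseq(genome, b$chrom, from, b$pos))
    }
    acceptor_id <- NA_character_
  }
  if (!nzchar(acc_seq)) return("NO_UTR_STRUCTURE")
  structure(list(
    donor_transcript = dtx$transcript_id,
    acceptor_transcript = acceptor_id,
    donor_gene = dtx$gene_id,
    acceptor_gene = if (!is.null(a$transcript)) a$transcript$gene_id else NA_character_,
    mrna = paste0(donor_seq, acc_seq),
    junction_nt = nchar(donor_seq),
    cds_start_nt = if (start_lost) NA_integer_ else dtx$utr5_len,
    donor_cds_contribution = max(0L, dlen - dtx$utr5_len),
    acceptor_info = acceptor_info,
    single_gene = identical(dtx$gene_id,
                            if (is.null(a$transcript)) NA_character_
                            else a$transcript$gene_id),
    start_lost = start_lost
  ), class = "NeoTranscript")
}

#' @export
#' @method print NeoTranscript
print.NeoTranscript <- function(x, ...) {
  cat(sprintf("NeoTranscript %s->%s: %d nt, junction at %d, donor CDS %d nt\n",
              x$donor_transcript, x$acceptor_transcript, nchar(x$mrna),
              x$junction_nt, x$donor_cds_contribution))
  invisible(x)
}

#' Determine whether a neo-transcript is frameshifted
#'
#' A junction is in frame when the donor's retained coding length modulo 3
#' matches the native codon phase of the first acceptor-derived coding base
#' in its own wild-type transcript (with any acceptor 5'UTR remainder counted
#' toward the chimeric reading frame). Acceptor sequence with no native
#' coding context (3'UTR or intergenic tails) is frameshifted by definition.
#'
#' @param nt A `NeoTranscript`.
#' @return Logical: `TRUE` when the junction shifts the reading frame.
#' @export
determine_frame <- function(nt) {
  ai <- nt$acceptor_info
  if (!isTRUE(ai$has_coding)) return(TRUE)
  phase_in_chimera <- (nt$donor_cds_contribution + ai$u) %% 3L
  phase_in_chimera != ai$native_phase
}

#' Translate a neo-transcript into a neo-protein
#'
#' Translation starts at the donor's start codon (or, for start-loss events
#' with rescue enabled, at the first downstream ATG of the chimeric mRNA)
#' and proceeds by the standard codon table until the first stop codon
#' (`STOP`; the stop is not included) or the transcript's 3' boundary
#' (`READ_THROUGH`; a trailing incomplete codon is discarded). Codons
#' containing N translate to X.
#'
#' @param nt A `NeoTranscript`.
#' @param wt Optional donor wild-type protein sequence used to compute the
#'   mutated span (see [mutated_interval()]).
#' @return A `NeoProtein`, or the character rejection reason `"NO_START"`.
#' @export
translate_neo <- function(nt, wt = NULL) {
  start_rescued <- FALSE
  cds_start <- nt$cds_start_nt
  if (is.na(cds_start)) {
    hit <- regexpr("ATG", nt$mrna, fixed = TRUE)
    if (hit < 0) return("NO_START")
    cds_start <- as.integer(hit) - 1L
    start_rescued <- TRUE
  }
  tr <- .translate_from(nt$mrna, cds_start)
  if (!nzchar(tr$aa)) return("NO_START")
  frameshift <- determine_frame(nt)
  junction_aa <- if (nt$junction_nt <= cds_start) 0L
                 else min((nt$junction_nt - cds_start) %/% 3L,
                          nchar(tr$aa))
  np <- structure(list(
    sequence = tr$aa, junction_aa = as.integer(junction_aa),
    frameshift = frameshift, termination = tr$termination,
    start_rescued = start_rescued,
    mutated_span = NULL,
    donor_gene = nt$donor_gene, acceptor_gene = nt$acceptor_gene,
    single_gene = nt$single_gene
  ), class = "NeoProtein")
  if (!is.null(wt)) {
    np$mutated_span <- mutated_interval(np, wt)
  }
  np
}

#' @export
#' @method print NeoProtein
print.NeoProtein <- function(x, ...) {
  cat(sprintf("NeoProtein %d aa (%s, %s)%s junction_aa=%d\n",
              nchar(x$sequence),
              if (x$frameshift) "frameshift" else "in-frame", x$termination,
              if (x$start_rescued) " start-rescued" else "", x$junction_aa))
  if (!is.null(x$mutated_span))
    cat(sprintf("  mutated span [%d,%d)\n", x$mutated_span[1], x$mutated_span[2]))
  invisible(x)
}

#' Mutated residue interval of a neo-protein
#'
#' The half-open residue interval of the neo-protein that differs from the
#' donor wild-type protein. For frameshift, two-gene, and read-through
#' events the span runs from the first differing residue to the protein's
#' end. For in-frame single-gene events it is the junction-spanning window
#' where the residue context differs (common prefix and suffix with the
#' wild type removed); if the neo-protein is an exact prefix+suffix of the
#' wild type with identical junction residues the span is empty and the
#' event yields no neo-peptides.
#'
#' @param np A `NeoProtein`.
#' @param wt Donor wild-type protein sequence.
#' @return Integer vector `c(start, end)`, 0-based half-open; `start == end`
#'   denotes an empty span.
#' @export
mutated_interval <- function(np, wt) {
  s <- np$sequence
  n <- nchar(s); m <- nchar(wt)
  sv <- strsplit(s, "")[[1]]; wv <- strsplit(wt, "")[[1]]
  k <- min(n, m)
  l <- 0L
  while (l < k && sv[l + 1L] == wv[l + 1L]) l <- l + 1L
  if (l == n && n == m) return(c(0L, 0L))          # identical
  full_tail <- np$frameshift || !isTRUE(np$single_gene) ||
    identical(np$termination, "READ_THROUGH")
  if (full_tail) return(c(l, n))
  # in-frame single-gene: strip the common suffix too
  r <- 0L
  while (r < k - l && sv[n - r] == wv[m - r]) r <- r + 1L
  if (n - r <= l) return(c(l, l))                   # empty span
  c(l, n - r)
}
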