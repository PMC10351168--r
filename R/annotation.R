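# Transcript models and annotation loading.
#
# Internal convention: all intervals are 0-based half-open on the genome;
# GTF/GFF 1-based inclusive coordinates are converted at the I/O boundary.
# Exon and CDS intervals are stored in TRANSCRIPTION order (ascending genomic
# coordinates on "+", descending on "-").

#' Build a transcript model
#'
#' @param transcript_id,gene_id,gene_name,chrom,strand Identifiers; `strand`
#'   is `"+"` or `"-"`.
#' @param exons Integer matrix (n x 2, columns start/end), 0-based half-open
#'   genomic intervals, in transcription order.
#' @param cds Integer matrix like `exons` delimiting the coding region
#'   (excluding the stop codon, Ensembl-style), or `NULL` for noncoding
#'   transcripts.
#' @return A `TranscriptModel` with derived fields `tx_length`, `cds_length`,
#'   `utr5_len`, `utr3_len`, `coding`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name, chrom, strand,
                             exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2] <= exons[, 1])) stop("empty exon interval")
  ord <- order(exons[, 1])
  if (strand == "-") ord <- rev(ord)
  exons <- exons[ord, , drop = FALSE]
  # non-overlap check in genomic order
  g <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(g) > 1 && any(g[-1, 1] < g[-nrow(g), 2])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  coding <- !is.null(cds) && nrow(cds) > 0
  cds_length <- 0L
  utr5_len <- 0L
  tx_length <- sum(exons[, 2] - exons[, 1])
  if (coding) {
    cds <- matrix(as.integer(cds), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    ordc <- order(cds[, 1])
    if (strand == "-") ordc <- rev(ordc)
    cds <- cds[ordc, , drop = FALSE]
    cds_length <- sum(cds[, 2] - cds[, 1])
    # CDS must lie within exon space
    ok <- all(vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1)))
    if (!ok) stop("CDS not contained in exons for transcript ", transcript_id)
    first_cds <- cds[1, , drop = TRUE]
    utr5_len <- .tx_coord_from_exons(exons, strand,
                                     if (strand == "+") first_cds[1] else first_cds[2] - 1L)
  } else {
    cds <- matrix(integer(0), ncol = 2)
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    gene_name = if (is.null(gene_name) || is.na(gene_name)) gene_id else gene_name,
    chrom = chrom, strand = strand,
    exons = exons, cds = cds, coding = coding,
    tx_length = as.integer(tx_length), cds_length = as.integer(cds_length),
    utr5_len = as.integer(utr5_len),
    utr3_len = as.integer(tx_length - utr5_len - cds_length)
  ), class = "TranscriptModel")
}

#' @export
#' @method print TranscriptModel
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s/%s) %s:%s %d exon(s), CDS %d nt\n",
              x$transcript_id, x$gene_id, x$gene_name, x$chrom, x$strand,
              nrow(x$exons), x$cds_length))
  invisible(x)
}

# transcript coordinate (0-based, transcription order) of genomic base gpos0,
# NA if intronic / outside
.tx_coord_from_exons <- function(exons, strand, gpos0) {
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1]; e <- exons[i, 2]
    if (gpos0 >= s && gpos0 < e) {
      within <- if (strand == "+") gpos0 - s else (e - 1L) - gpos0
      return(off + within)
    }
    off <- off + (e - s)
  }
  NA_integer_
}

#' Transcript coordinate of a genomic position
#' @param tx A `TranscriptModel`.
#' @param gpos0 0-based genomic position.
#' @return 0-based transcript coordinate, or `NA` if not exonic.
#' @keywords internal
tx_coord <- function(tx, gpos0) .tx_coord_from_exons(tx$exons, tx$strand, gpos0)

# genomic 0-based position of transcript coordinate t
tx_to_genome <- function(tx, t) {
  off <- 0L
  for (i in seq_len(nrow(tx$exons))) {
    w <- tx$exons[i, 2] - tx$exons[i, 1]
    if (t < off + w) {
      within <- t - off
      return(if (tx$strand == "+") tx$exons[i, 1] + within
             else tx$exons[i, 2] - 1L - within)
    }
    off <- off + w
  }
  stop("transcript coordinate out of range")
}

# exon index (1-based, transcription order) containing gpos0, or NA
.exon_index <- function(tx, gpos0) {
  for (i in seq_len(nrow(tx$exons))) {
    if (gpos0 >= tx$exons[i, 1] && gpos0 < tx$exons[i, 2]) return(i)
  }
  NA_integer_
}

# intron index: i if gpos0 lies between exon i and exon i+1 in transcription
# order, else NA
.intron_index <- function(tx, gpos0) {
  n <- nrow(tx$exons)
  if (n < 2) return(NA_integer_)
  for (i in seq_len(n - 1)) {
    a <- tx$exons[i, , drop = TRUE]
    b <- tx$exons[i + 1, , drop = TRUE]
    lo <- min(a[2], b[2]); hi <- max(a[1], b[1])
    if (gpos0 >= lo && gpos0 < hi) return(i)
  }
  NA_integer_
}

# cumulative exonic length of exons 1..i (transcription order)
.cum_exon_len <- function(tx, i) {
  if (i == 0) return(0L)
  sum(tx$exons[seq_len(i), 2] - tx$exons[seq_len(i), 1])
}

# whether the transcript span (genomic) contains gpos0
.tx_spans <- function(tx, gpos0) {
  gpos0 >= min(tx$exons[, 1]) && gpos0 < max(tx$exons[, 2])
}

#' Spliced transcript sequence
#' @param tx A `TranscriptModel`.
#' @param genome A `GenomeSequence`.
#' @return Character scalar: exonic sequence 5' to 3'.
#' @export
transcript_sequence <- function(tx, genome) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i) {
    s <- genome_subseq(genome, tx$chrom, tx$exons[i, 1], tx$exons[i, 2])
    if (tx$strand == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

#' Load a transcript annotation (GTF/GFF)
#'
#' Reconstructs one `TranscriptModel` per transcript from exon and CDS
#' features and indexes gene loci for point queries. Transcripts whose CDS is
#' not contained in their exons are excluded and reported in `$malformed`.
#'
#' @param path Path to a GTF (Ensembl dialect) or GFF3 file.
#' @return A transcript database (`TxDb`-like list) with elements
#'   `transcripts` (named list of `TranscriptModel`), `genes` (named list with
#'   `transcript_ids`, `selected`, `gene_name`), `index` (a
#'   [GenomicRanges::GRanges] of selected coding-transcript spans), and
#'   `malformed` (data.frame of excluded transcripts).
#' @export
load_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (!nrow(df)) stop("no exon/CDS features found in ", path)
  if (is.null(df$transcript_id)) {
    # GFF3 dialect: features point at parents "transcript:<id>"
    if (!is.null(df$Parent)) {
      df$transcript_id <- sub("^transcript:", "", vapply(df$Parent, function(p)
        as.character(p)[1], character(1)))
    } else stop("annotation lacks transcript_id/Parent attributes")
  }
  if (is.null(df$gene_id)) df$gene_id <- df$transcript_id
  if (is.null(df$gene_name)) df$gene_name <- df$gene_id
  transcripts <- list()
  malformed <- data.frame(transcript_id = character(0), reason = character(0))
  for (txid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == txid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cd <- sub[sub$type == "CDS", , drop = FALSE]
    if (!nrow(ex)) {  # CDS-only records: treat CDS as exons
      ex <- cd
    }
    exm <- cbind(ex$start - 1L, ex$end)       # 1-based inclusive -> 0-based half-open
    cdm <- if (nrow(cd)) cbind(cd$start - 1L, cd$end) else NULL
    tm <- tryCatch(
      transcript_model(txid, ex$gene_id[1], ex$gene_name[1],
                       as.character(ex$seqnames[1]), as.character(ex$strand[1]),
                       exm, cdm),
      error = function(e) e)
    if (inherits(tm, "error")) {
      malformed <- rbind(malformed,
                         data.frame(transcript_id = txid,
                                    reason = conditionMessage(tm)))
      message("excluding malformed transcript ", txid, ": ",
              conditionMessage(tm))
    } else {
      transcripts[[txid]] <- tm
    }
  }
  build_txdb(transcripts, malformed)
}

#' Build a transcript database from transcript models
#' @param transcripts Named list of `TranscriptModel`s.
#' @param malformed Optional data.frame of excluded transcripts.
#' @return A transcript database; see [load_annotation()].
#' @export
build_txdb <- function(transcripts, malformed = NULL) {
  names(transcripts) <- vapply(transcripts, function(t) t$transcript_id,
                               character(1))
  genes <- list()
  for (tm in transcripts) {
    g <- genes[[tm$gene_id]]
    if (is.null(g)) g <- list(transcript_ids = character(0),
                              gene_name = tm$gene_name)
    g$transcript_ids <- c(g$transcript_ids, tm$transcript_id)
    genes[[tm$gene_id]] <- g
  }
  db <- structure(list(transcripts = transcripts, genes = genes,
                       malformed = malformed), class = "TxDb_svneo")
  # selected isoform per gene + interval index over selected coding isoforms
  idx_chrom <- character(0); idx_start <- integer(0); idx_end <- integer(0)
  idx_gene <- character(0)
  for (gid in names(genes)) {
    sel <- select_transcript(db, gid)
    db$genes[[gid]]$selected <- if (is.null(sel)) NA_character_ else sel$transcript_id
    if (!is.null(sel)) {
      idx_chrom <- c(idx_chrom, sel$chrom)
      idx_start <- c(idx_start, min(sel$exons[, 1]))
      idx_end <- c(idx_end, max(sel$exons[, 2]))
      idx_gene <- c(idx_gene, gid)
    }
  }
  db$index <- GenomicRanges::GRanges(
    seqnames = idx_chrom,
    ranges = IRanges::IRanges(start = idx_start + 1L, end = idx_end),
    gene_id = idx_gene)
  db
}

#' @export
#' @method print TxDb_svneo
print.TxDb_svneo <- function(x, ...) {
  cat(sprintf("svneo transcript database: %d gene(s), %d transcript(s), %d coding\n",
              length(x$genes), length(x$transcripts),
              sum(vapply(x$transcripts, function(t) t$coding, logical(1)))))
  invisible(x)
}

#' Select the analysis isoform of a gene
#'
#' Among a gene's coding isoforms, the one with the longest coding region is
#' used; ties break to the lexicographically smallest transcript id.
#'
#' @param txdb Transcript database.
#' @param gene_id Gene identifier.
#' @return A `TranscriptModel`, or `NULL` if the gene has no coding isoform.
#' @export
select_transcript <- function(txdb, gene_id) {
  g <- txdb$genes[[gene_id]]
  if (is.null(g)) stop("gene not in database: ", gene_id)
  if (!is.null(g$selected) && !is.na(g$selected)) {
    return(txdb$transcripts[[g$selected]])
  }
  cands <- Filter(function(t) t$coding,
                  txdb$transcripts[g$transcript_ids])
  if (!length(cands)) return(NULL)
  lens <- vapply(cands, function(t) t$cds_length, integer(1))
  ids <- vapply(cands, function(t) t$transcript_id, character(1))
  best <- order(-lens, ids)[1]
  cands[[best]]
}

#' Wild-type proteome of a transcript database
#'
#' Translates the selected (longest-CDS) isoform of every gene.
#'
#' @param txdb Transcript database.
#' @param genome A `GenomeSequence`.
#' @return Named character vector, gene_id -> protein sequence (no stop).
#' @export
txdb_proteome <- function(txdb, genome) {
  out <- character(0)
  for (gid in names(txdb$genes)) {
    sel <- select_transcript(txdb, gid)
    if (is.null(sel)) next
    out[gid] <- wt_protein(sel, genome)
  }
  out
}
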