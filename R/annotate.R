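# Breakend-to-transcript mapping, SV classification, and feasibility filters.

#' Map a breakend onto the transcript annotation
#'
#' Attaches the selected (longest-CDS) isoform of the gene overlapping the
#' breakend position, the region label (exon/intron index in transcription
#' order, UTR5/UTR3, or intergenic), and the coding offset: the number of
#' coding nucleotides of the transcript strictly 5' of the breakend.
#' When several genes overlap the position, the gene whose selected
#' transcript has the longest CDS wins; ties break to the smaller gene id.
#'
#' @param b A `Breakend`.
#' @param txdb Transcript database from [load_annotation()].
#' @return An `AnnotatedBreakend`: list with `breakend`, `transcript`
#'   (`TranscriptModel` or `NULL`), `region` (list `label`, `index`), and
#'   `cds_offset`.
#' @export
map_breakend <- function(b, txdb) {
  q <- GenomicRanges::GRanges(seqnames = b$chrom,
                              ranges = IRanges::IRanges(b$pos, b$pos))
  hits <- tryCatch(
    suppressWarnings(GenomicRanges::findOverlaps(q, txdb$index)),
    error = function(e) NULL)
  gids <- if (is.null(hits)) character(0)
          else txdb$index$gene_id[S4Vectors::subjectHits(hits)]
  gpos0 <- b$pos - 1L
  # drop genes whose selected transcript span doesn't actually contain pos
  gids <- Filter(function(g) .tx_spans(select_transcript(txdb, g), gpos0), gids)
  if (!length(gids)) {
    return(structure(list(breakend = b, transcript = NULL,
                          region = list(label = "INTERGENIC", index = NA_integer_),
                          cds_offset = NA_integer_),
                     class = "AnnotatedBreakend"))
  }
  if (length(gids) > 1) {
    lens <- vapply(gids, function(g) select_transcript(txdb, g)$cds_length,
                   integer(1))
    gids <- gids[order(-lens, gids)]
  }
  tx <- select_transcript(txdb, gids[1])
  t <- tx_coord(tx, gpos0)
  if (!is.na(t)) {
    if (t < tx$utr5_len) {
      region <- list(label = "UTR5", index = NA_integer_)
    } else if (t >= tx$utr5_len + tx$cds_length) {
      region <- list(label = "UTR3", index = NA_integer_)
    } else {
      region <- list(label = "EXON", index = .exon_index(tx, gpos0))
    }
    cds_offset <- max(0L, min(t, tx$utr5_len + tx$cds_length) - tx$utr5_len)
  } else {
    i <- .intron_index(tx, gpos0)
    region <- list(label = "INTRON", index = i)
    cds_offset <- max(0L, min(.cum_exon_len(tx, i),
                              tx$utr5_len + tx$cds_length) - tx$utr5_len)
  }
  structure(list(breakend = b, transcript = tx, region = region,
                 cds_offset = as.integer(cds_offset)),
            class = "AnnotatedBreakend")
}

#' @export
#' @method print AnnotatedBreakend
print.AnnotatedBreakend <- function(x, ...) {
  reg <- x$region$label
  if (!is.na(x$region$index)) reg <- sprintf("%s(%d)", reg, x$region$index)
  cat(sprintf("AnnotatedBreakend %s:%d(%s) %s %s cds_offset=%s\n",
              x$breakend$chrom, x$breakend$pos, x$breakend$orient,
              if (is.null(x$transcript)) "-" else x$transcript$gene_id,
              reg, x$cds_offset))
  invisible(x)
}

#' Classify an SV junction by orientation geometry
#'
#' Intrachromosomal junctions with ordered positions posA < posB map
#' (LEFT,RIGHT) to `DELETION_LIKE`, (RIGHT,LEFT) to `DUPLICATION_LIKE`,
#' (LEFT,LEFT) to `H2H_INVERSION`, (RIGHT,RIGHT) to `T2T_INVERSION`;
#' interchromosomal junctions are `TRANSLOCATION`. The result is invariant
#' under swapping the two breakends.
#'
#' @param pair An `SvBreakendPair`.
#' @return Character scalar, the SV class.
#' @export
classify_sv <- function(pair) {
  a <- pair$first; b <- pair$second
  if (a$chrom != b$chrom) return("TRANSLOCATION")
  if (a$pos > b$pos) { tmp <- a; a <- b; b <- tmp }
  key <- paste(a$orient, b$orient, sep = ",")
  switch(key,
         "LEFT,RIGHT" = "DELETION_LIKE",
         "RIGHT,LEFT" = "DUPLICATION_LIKE",
         "LEFT,LEFT" = "H2H_INVERSION",
         "RIGHT,RIGHT" = "T2T_INVERSION")
}

# promoter-retaining orientation for a strand (the side holding the 5' end)
.promoter_side <- function(strand) if (strand == "+") "LEFT" else "RIGHT"
# orientation retaining the transcript's 3' remainder
.tail_side <- function(strand) if (strand == "+") "RIGHT" else "LEFT"

#' Annotate and filter one SV junction
#'
#' Maps both breakends, classifies the junction, and applies the two
#' candidate filters: junctions with an intergenic breakend are rejected
#' (`INTERGENIC`; strictness controlled by `allow_one_intergenic`), and
#' junctions for which no donor/acceptor role assignment lets transcription
#' run continuously across the junction are rejected (`ORIENTATION`). The
#' donor's retained side must contain its transcript's promoter and the
#' acceptor's retained side its 3' remainder. A donor breakend in the 3'UTR
#' cannot alter the protein and is rejected `NO_CODING_EFFECT`.
#'
#' @param pair An `SvBreakendPair`.
#' @param txdb Transcript database.
#' @param allow_one_intergenic If `TRUE`, a junction with exactly one
#'   intergenic breakend is kept when the genic end can act as donor
#'   (read-through into intergenic sequence).
#' @return An `SvAnnotation`: list with `pair`, `ends` (two
#'   `AnnotatedBreakend`s), `sv_class`, `span`, `gene_context`, `feasible`,
#'   `reject_reason`, `donor_end`, `acceptor_end`.
#' @export
annotate_sv <- function(pair, txdb, allow_one_intergenic = FALSE) {
  ends <- list(map_breakend(pair$first, txdb), map_breakend(pair$second, txdb))
  ann <- structure(list(pair = pair, ends = ends,
                        sv_class = classify_sv(pair),
                        span = if (pair$first$chrom == pair$second$chrom)
                          abs(pair$second$pos - pair$first$pos) else NA_integer_,
                        gene_context = NA_character_,
                        feasible = FALSE, reject_reason = NA_character_,
                        donor_end = NA_integer_, acceptor_end = NA_integer_),
                   class = "SvAnnotation")
  apply_filters(ann, allow_one_intergenic = allow_one_intergenic)
}

#' Apply intergenic and orientation-feasibility filters
#'
#' See [annotate_sv()]. Exactly one of `feasible` / `reject_reason` is set on
#' return; feasibility never throws.
#'
#' @param ann An `SvAnnotation` with both ends mapped.
#' @param allow_one_intergenic See [annotate_sv()].
#' @return The updated `SvAnnotation`.
#' @export
apply_filters <- function(ann, allow_one_intergenic = FALSE) {
  intergenic <- vapply(ann$ends, function(e) is.null(e$transcript), logical(1))
  if (all(intergenic) || (any(intergenic) && !allow_one_intergenic)) {
    ann$feasible <- FALSE
    ann$reject_reason <- "INTERGENIC"
    return(ann)
  }
  # enumerate donor/acceptor role assignments
  assignments <- list(c(1L, 2L), c(2L, 1L))
  valid <- list(); utr3_donor_only <- FALSE
  for (as_ in assignments) {
    d <- ann$ends[[as_[1]]]; a <- ann$ends[[as_[2]]]
    if (is.null(d$transcript)) next          # intergenic end cannot donate
    if (d$breakend$orient != .promoter_side(d$transcript$strand)) next
    if (!is.null(a$transcript)) {
      if (a$breakend$orient != .tail_side(a$transcript$strand)) next
    }
    # orientation-valid; check coding effect of the donor side
    if (d$region$label == "UTR3") { utr3_donor_only <- TRUE; next }
    valid[[length(valid) + 1L]] <- as_
  }
  if (!length(valid)) {
    ann$feasible <- FALSE
    ann$reject_reason <- if (utr3_donor_only) "NO_CODING_EFFECT" else "ORIENTATION"
    return(ann)
  }
  as_ <- valid[[1]]
  ann$feasible <- TRUE
  ann$reject_reason <- NA_character_
  ann$donor_end <- as_[1]; ann$acceptor_end <- as_[2]
  dg <- ann$ends[[as_[1]]]$transcript$gene_id
  agt <- ann$ends[[as_[2]]]$transcript
  ann$gene_context <- if (!is.null(agt) && identical(dg, agt$gene_id))
    "SINGLE_GENE" else "TWO_GENE"
  ann
}

#' @export
#' @method print SvAnnotation
print.SvAnnotation <- function(x, ...) {
  cat(sprintf("SvAnnotation %s: %s %s\n", x$pair$id, x$sv_class,
              if (x$feasible) sprintf("feasible (%s, donor end %d)",
                                      x$gene_context, x$donor_end)
              else sprintf("rejected: %s", x$reject_reason)))
  invisible(x)
}

#' Flatten SV annotations to a table
#' @param anns List of `SvAnnotation`.
#' @return data.frame, one row per junction, including rejects.
#' @export
annotations_to_table <- function(anns) {
  region_str <- function(e) {
    if (is.na(e$region$index)) e$region$label
    else sprintf("%s(%d)", e$region$label, e$region$index)
  }
  gene_of <- function(e) if (is.null(e$transcript)) NA_character_
                         else e$transcript$gene_id
  if (!length(anns)) {
    return(data.frame(id = character(0), sv_class = character(0),
                      span = integer(0), geneA = character(0),
                      regionA = character(0), geneB = character(0),
                      regionB = character(0), gene_context = character(0),
                      feasible = logical(0), reject_reason = character(0),
                      donor_gene = character(0), acceptor_gene = character(0),
                      patient = character(0), clonality = character(0)))
  }
  do.call(rbind, lapply(anns, function(a) data.frame(
    id = a$pair$id, sv_class = a$sv_class, span = a$span,
    geneA = gene_of(a$ends[[1]]), regionA = region_str(a$ends[[1]]),
    geneB = gene_of(a$ends[[2]]), regionB = region_str(a$ends[[2]]),
    gene_context = a$gene_context, feasible = a$feasible,
    reject_reason = a$reject_reason,
    donor_gene = if (a$feasible) gene_of(a$ends[[a$donor_end]]) else NA_character_,
    acceptor_gene = if (a$feasible) gene_of(a$ends[[a$acceptor_end]]) else NA_character_,
    patient = a$pair$patient, clonality = a$pair$clonality)))
}
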