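# Naive truth oracle for the spiked fixtures.
#
# Deliberately shares NO code with the prediction pipeline: it re-reads the
# written FASTA/GTF/VCF with its own minimal parsers, splices by plain
# substring arithmetic, translates with its own codon map, and windows
# peptides by exhaustive enumeration. It exists so that end-to-end tests can
# compare the pipeline against an implementation that cannot inherit its
# bugs.

.ntr_read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  out <- character(0)
  for (i in seq_along(hdr)) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[i]])
    out[nm] <- paste(lines[(hdr[i] + 1):to], collapse = "")
  }
  out
}

.ntr_read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  getattr <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  do.call(rbind, lapply(f, function(x) data.frame(
    chrom = x[1], type = x[3], start = as.integer(x[4]),
    end = as.integer(x[5]), strand = x[7],
    gene_id = getattr(x[9], "gene_id"),
    transcript_id = getattr(x[9], "transcript_id"))))
}

.ntr_revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

.ntr_codons <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# translate from 0-based offset; returns list(aa, termination)
.ntr_translate <- function(nt, from) {
  aa <- c(); i <- from; term <- "READ_THROUGH"
  while (i + 3 <= nchar(nt)) {
    cod <- substr(nt, i + 1, i + 3)
    r <- if (cod %in% names(.ntr_codons)) unname(.ntr_codons[cod]) else "X"
    if (r == "*") { term <- "STOP"; break }
    aa <- c(aa, r); i <- i + 3
  }
  list(aa = paste(aa, collapse = ""), termination = term)
}

# BND VCF -> one row per junction (mates deduplicated via MATEID)
.ntr_read_bnd_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- list(); seen <- character(0)
  for (l in lines) {
    x <- strsplit(l, "\t", fixed = TRUE)[[1]]
    alt <- x[5]; info <- x[8]
    m <- regmatches(alt, regexec(
      "^([ACGTN]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([ACGTN]*)$",
      alt, perl = TRUE))[[1]]
    if (!length(m)) next
    o1 <- if (nchar(m[2]) > 0) "LEFT" else "RIGHT"   # t before bracket: left side kept
    o2 <- if (m[3] == "[") "RIGHT" else "LEFT"
    getinfo <- function(key) {
      mm <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
      if (length(mm) < 2) NA_character_ else mm[2]
    }
    id <- x[3]; mate <- getinfo("MATEID")
    stem <- if (!is.na(mate) &&
                sub("_[12]$", "", id) == sub("_[12]$", "", mate))
      sub("_[12]$", "", id) else paste(sort(c(id, mate)), collapse = "_")
    if (stem %in% seen) next
    seen <- c(seen, stem)
    rows[[length(rows) + 1L]] <- data.frame(
      id = stem, c1 = x[1], p1 = as.integer(x[2]), o1 = o1,
      c2 = m[4], p2 = as.integer(m[5]), o2 = o2,
      patient = getinfo("PATIENT"), clonality = getinfo("CLONALITY"))
  }
  do.call(rbind, rows)
}

# per-transcript record from GTF rows: genomically sorted exon/CDS tables
.ntr_models <- function(gtf) {
  txs <- list()
  for (tid in unique(stats::na.omit(gtf$transcript_id))) {
    sub <- gtf[!is.na(gtf$transcript_id) & gtf$transcript_id == tid, ]
    ex <- sub[sub$type == "exon", ]; ex <- ex[order(ex$start), ]
    cd <- sub[sub$type == "CDS", ];  cd <- cd[order(cd$start), ]
    if (!nrow(ex)) next
    txs[[tid]] <- list(tid = tid, gene = ex$gene_id[1], chrom = ex$chrom[1],
                       strand = ex$strand[1], ex = ex, cd = cd,
                       cds_len = sum(cd$end - cd$start + 1L))
  }
  # longest-CDS transcript per gene, tie -> smaller id
  sel <- list()
  for (t in txs) {
    cur <- sel[[t$gene]]
    if (is.null(cur) || t$cds_len > cur$cds_len ||
        (t$cds_len == cur$cds_len && t$tid < cur$tid)) sel[[t$gene]] <- t
  }
  sel
}

# transcript coordinate (0-based, transcription order) of 1-based genomic pos;
# NA if intronic
.ntr_tcoord <- function(tx, pos) {
  ex <- tx$ex
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  off <- 0L
  for (i in ord) {
    if (pos >= ex$start[i] && pos <= ex$end[i]) {
      w <- if (tx$strand == "+") pos - ex$start[i] else ex$end[i] - pos
      return(off + w)
    }
    off <- off + (ex$end[i] - ex$start[i] + 1L)
  }
  NA_integer_
}

# spliced transcript sequence (5'->3') by substring concatenation
.ntr_splice <- function(tx, fa) {
  ex <- tx$ex
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  parts <- vapply(ord, function(i) {
    s <- substr(fa[[tx$chrom]], ex$start[i], ex$end[i])
    if (tx$strand == "-") .ntr_revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

# 5'UTR length = transcript coordinate of the CDS-start base
.ntr_u5 <- function(tx) {
  cd <- tx$cd
  start_base <- if (tx$strand == "+") min(cd$start) else max(cd$end)
  .ntr_tcoord(tx, start_base)
}

# number of complete exons (transcription order) wholly 5' of an intronic pos
.ntr_exons_before <- function(tx, pos) {
  ex <- tx$ex
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  n <- 0L
  for (i in ord) {
    done5 <- if (tx$strand == "+") ex$end[i] < pos else ex$start[i] > pos
    if (done5) n <- n + 1L else break
  }
  n
}

# find the gene whose selected transcript spans pos (1-based); NULL if none
.ntr_gene_at <- function(models, chrom, pos) {
  hit <- NULL
  for (t in models) {
    if (t$chrom != chrom) next
    if (pos >= min(t$ex$start) && pos <= max(t$ex$end)) {
      if (is.null(hit) || t$cds_len > hit$cds_len ||
          (t$cds_len == hit$cds_len && t$gene < hit$gene)) hit <- t
    }
  }
  hit
}

#' Naive truth oracle for spiked SV fixtures
#'
#' Recomputes, for every junction in a BND-dialect VCF, the expected
#' feasibility or reject reason, frameshift flag, neo-protein sequence,
#' mutated span, and 8-11-mer non-self peptide set — using only string
#' operations on the written FASTA/GTF/VCF files. See the file header for
#' the independence rationale.
#'
#' @param vcf_path BND-dialect VCF written by [spike_svs()] (or
#'   [write_sv_vcf()]).
#' @param gtf_path,fasta_path The toy annotation and genome files.
#' @return Named list of truth records (per SV id): `feasible`,
#'   `reject_reason`, `frameshift`, `termination`, `protein`,
#'   `mutated_span`, `peptides` (sorted), `patient`, `clonality`.
#' @export
naive_truth <- function(vcf_path, gtf_path, fasta_path) {
  fa <- .ntr_read_fasta(fasta_path)
  gtf <- .ntr_read_gtf(gtf_path)
  models <- .ntr_models(gtf)
  juncs <- .ntr_read_bnd_vcf(vcf_path)
  # oracle proteome: translate every selected transcript from its CDS start
  proteome <- vapply(models, function(t) {
    .ntr_translate(.ntr_splice(t, fa), .ntr_u5(t))$aa
  }, character(1))

  promoter_side <- function(strand) if (strand == "+") "LEFT" else "RIGHT"
  tail_side <- function(strand) if (strand == "+") "RIGHT" else "LEFT"

  out <- list()
  for (r in seq_len(nrow(juncs))) {
    j <- juncs[r, ]
    rec <- list(id = j$id, patient = j$patient, clonality = j$clonality,
                feasible = FALSE, reject_reason = NA_character_,
                frameshift = NA, termination = NA_character_,
                protein = NA_character_, mutated_span = NULL,
                peptides = character(0))
    ends <- list(list(chrom = j$c1, pos = j$p1, orient = j$o1),
                 list(chrom = j$c2, pos = j$p2, orient = j$o2))
    gene_at <- lapply(ends, function(e) .ntr_gene_at(models, e$chrom, e$pos))
    if (any(vapply(gene_at, is.null, logical(1)))) {
      rec$reject_reason <- "INTERGENIC"
      out[[j$id]] <- rec
      next
    }
    # role assignment: donor keeps its promoter side, acceptor its 3' side
    pick <- NULL; utr3_only <- FALSE
    for (asn in list(c(1, 2), c(2, 1))) {
      d <- ends[[asn[1]]]; dt <- gene_at[[asn[1]]]
      a <- ends[[asn[2]]]; at <- gene_at[[asn[2]]]
      if (d$orient != promoter_side(dt$strand)) next
      if (a$orient != tail_side(at$strand)) next
      td <- .ntr_tcoord(dt, d$pos)
      u5d <- .ntr_u5(dt)
      donor_reg_utr3 <- !is.na(td) && td >= u5d + dt$cds_len
      if (donor_reg_utr3) { utr3_only <- TRUE; next }
      pick <- asn
      break
    }
    if (is.null(pick)) {
      rec$reject_reason <- if (utr3_only) "NO_CODING_EFFECT" else "ORIENTATION"
      out[[j$id]] <- rec
      next
    }
    d <- ends[[pick[1]]]; dt <- gene_at[[pick[1]]]
    a <- ends[[pick[2]]]; at <- gene_at[[pick[2]]]
    dseq <- .ntr_splice(dt, fa); aseq <- .ntr_splice(at, fa)
    u5d <- .ntr_u5(dt); u5a <- .ntr_u5(at)
    # donor spliced prefix
    td <- .ntr_tcoord(dt, d$pos)
    dlen <- if (!is.na(td)) td + 1L else {
      nb <- .ntr_exons_before(dt, d$pos)
      ord <- if (dt$strand == "+") seq_len(nrow(dt$ex)) else rev(seq_len(nrow(dt$ex)))
      sum(dt$ex$end[ord[seq_len(nb)]] - dt$ex$start[ord[seq_len(nb)]] + 1L)
    }
    # acceptor spliced suffix start
    ta <- .ntr_tcoord(at, a$pos)
    astart <- if (!is.na(ta)) ta else {
      nb <- .ntr_exons_before(at, a$pos)
      ord <- if (at$strand == "+") seq_len(nrow(at$ex)) else rev(seq_len(nrow(at$ex)))
      sum(at$ex$end[ord[seq_len(nb)]] - at$ex$start[ord[seq_len(nb)]] + 1L)
    }
    if (dlen < u5d + 3L || astart >= nchar(aseq)) {
      rec$feasible <- TRUE   # passed the breakpoint filters ...
      rec$reject_reason <- "NO_UTR_STRUCTURE"  # ... but not assembly
      out[[j$id]] <- rec
      next
    }
    rec$feasible <- TRUE
    mrna <- paste0(substr(dseq, 1, dlen),
                   substr(aseq, astart + 1L, nchar(aseq)))
    tr <- .ntr_translate(mrna, u5d)
    rec$protein <- tr$aa
    rec$termination <- tr$termination
    # frame: donor coding length vs native phase of first acceptor coding base
    donor_cds <- dlen - u5d
    if (astart < u5a) {
      rec$frameshift <- ((donor_cds + (u5a - astart)) %% 3) != 0
    } else if (astart < u5a + at$cds_len) {
      rec$frameshift <- (donor_cds %% 3) != ((astart - u5a) %% 3)
    } else {
      rec$frameshift <- TRUE     # no coding context in the acceptor tail
    }
    # mutated span vs donor wild-type protein
    wtp <- proteome[[dt$gene]]
    sv <- strsplit(tr$aa, "")[[1]]; wv <- strsplit(wtp, "")[[1]]
    n <- length(sv); m <- length(wv); k <- min(n, m)
    l <- 0L
    while (l < k && sv[l + 1] == wv[l + 1]) l <- l + 1L
    single_gene <- identical(dt$gene, at$gene)
    if (l == n && n == m) {
      span <- c(0L, 0L)
    } else if (rec$frameshift || !single_gene || tr$termination == "READ_THROUGH") {
      span <- c(l, n)
    } else {
      rr <- 0L
      while (rr < k - l && sv[n - rr] == wv[m - rr]) rr <- rr + 1L
      span <- if (n - rr <= l) c(l, l) else c(l, n - rr)
    }
    rec$mutated_span <- span
    # exhaustive windows overlapping the span, minus self substrings
    peps <- character(0)
    if (span[2] > span[1]) {
      for (kk in 8:11) {
        if (n < kk) next
        for (s0 in 0:(n - kk)) {
          if (s0 >= span[2] || s0 + kk <= span[1]) next
          pep <- substr(tr$aa, s0 + 1, s0 + kk)
          if (grepl("X", pep, fixed = TRUE)) next
          if (any(vapply(proteome, function(p) grepl(pep, p, fixed = TRUE),
                         logical(1)))) next
          peps <- c(peps, pep)
        }
      }
    }
    rec$peptides <- sort(unique(peps))
    out[[j$id]] <- rec
  }
  out
}
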