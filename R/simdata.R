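# Synthetic test-bed generator: toy genomes with multi-exon coding genes on
# both strands, spiked SV call sets covering every junction class with
# analytically known truth, and simulated cohort tables with known
# parameters.
#
# Gene geometry is small by design (exons ~100-160 nt, introns ~80-120 nt)
# so that the brute-force truth oracle runs in milliseconds. Exon/intron
# lengths of the designed genes are fixed; sequence content is drawn from
# the spec's seed, so the same seed reproduces byte-identical FASTA/GTF/VCF.

#' Simulation specification
#'
#' @param seed Integer seed fixing all randomness of the generator.
#' @param gap_len Intergenic gap length between gene loci (bp).
#' @param cohort List of cohort-simulation parameters: `n_patients`,
#'   `svs_per_patient` (length-2 range), `beta` (true logistic coefficients
#'   b0..b3), `subclonal_or` (true subclonal enrichment odds ratio),
#'   `p_subclonal` (baseline subclonal probability among
#'   non-neoantigenic SVs), `p_oncogenic`, `x2_mean` (mean affected
#'   amino-acid count), `p_frameshift`.
#' @return A `SimSpec` list.
#' @export
sim_spec <- function(seed = 1L, gap_len = 300L,
                     cohort = list(n_patients = 200L,
                                   svs_per_patient = c(40L, 80L),
                                   beta = c(-1.0, -1.2, 0.01, 1.5),
                                   subclonal_or = 2.0,
                                   p_subclonal = 0.4,
                                   p_oncogenic = 0.3,
                                   x2_mean = 20,
                                   p_frameshift = 0.5)) {
  structure(list(seed = as.integer(seed), gap_len = as.integer(gap_len),
                 cohort = cohort), class = "SimSpec")
}

# designed gene geometries; exon lengths are in transcription order.
# u5 = 5'UTR length; u3_rest = 3'UTR length after the stop codon.
# g6 is the read-through target: its post-stop tail is pure GGC repeats
# (no stop codon in any frame) and (exon1 - u5) is a multiple of 3.
.sim_gene_plan <- function() {
  list(
    g1 = list(chrom = "chr1", strand = "+", exons = c(120L, 114L, 120L, 150L),
              introns = c(80L, 90L, 100L), u5 = 30L, u3_rest = 24L),
    g2 = list(chrom = "chr1", strand = "+", exons = c(120L, 115L, 120L, 150L),
              introns = c(85L, 95L, 105L), u5 = 27L, u3_rest = 25L),
    g3 = list(chrom = "chr1", strand = "-", exons = c(130L, 120L, 140L),
              introns = c(90L, 110L), u5 = 33L, u3_rest = 24L),
    g4 = list(chrom = "chr1", strand = "+", exons = c(110L, 130L, 140L),
              introns = c(100L, 120L), u5 = 24L, u3_rest = 23L),
    g5 = list(chrom = "chr1", strand = "-", exons = c(140L, 110L, 130L),
              introns = c(95L, 105L), u5 = 21L, u3_rest = 23L),
    g6 = list(chrom = "chr1", strand = "+", exons = c(114L, 130L, 161L),
              introns = c(90L, 100L), u5 = 24L, u3_rest = 60L,
              ggc_tail = TRUE),
    g7 = list(chrom = "chr2", strand = "+", exons = c(125L, 120L, 135L),
              introns = c(110L, 90L), u5 = 30L, u3_rest = 23L),
    g8 = list(chrom = "chr2", strand = "-", exons = c(120L, 125L, 130L),
              introns = c(100L, 95L), u5 = 27L, u3_rest = 24L)
  )
}

.NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"), c("T","C","A","G")),
        1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

.rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                               collapse = "")

.rand_cds <- function(n_nt) {
  stopifnot(n_nt %% 3 == 0, n_nt >= 6)
  paste0("ATG", paste(sample(.NONSTOP_CODONS, n_nt / 3 - 1, replace = TRUE),
                      collapse = ""))
}

#' Generate the toy reference (genome + annotation + proteome)
#'
#' Builds multi-exon coding genes with clean start/stop codons and no
#' in-frame internal stops, on both strands of two chromosomes, and lays
#' them out with intergenic gaps. The same seed yields byte-identical
#' output.
#'
#' @param spec A `SimSpec`.
#' @param dir Optional directory; when given, `genome.fa` and
#'   `annotation.gtf` are written there.
#' @return List with `genome` (a `GenomeSequence`), `txdb`, `genes`
#'   (geometry records incl. each gene's `TranscriptModel`), `proteome`
#'   (named character vector), and `fasta_path`/`gtf_path` when `dir` is
#'   given.
#' @export
make_toy_reference <- function(spec = sim_spec(), dir = NULL) {
  set.seed(spec$seed)
  plan <- .sim_gene_plan()
  genes <- list()
  chrom_seq <- list(chr1 = "", chr2 = "")
  gtf <- character(0)
  for (gid in names(plan)) {
    g <- plan[[gid]]
    tx_len <- sum(g$exons)
    cds_len <- tx_len - g$u5 - 3L - g$u3_rest
    if (cds_len %% 3 != 0 || cds_len < 30) {
      stop("infeasible geometry for ", gid,
           ": CDS length ", cds_len, " must be a positive multiple of 3")
    }
    if (g$u5 + 3L > g$exons[1]) {
      stop("infeasible geometry for ", gid, ": 5'UTR + start codon must fit in exon 1")
    }
    if (g$u3_rest + 3L > g$exons[length(g$exons)]) {
      stop("infeasible geometry for ", gid, ": 3'UTR must fit in the last exon")
    }
    utr5 <- .rand_dna(g$u5)
    cds <- .rand_cds(cds_len)
    stop_codon <- "TAA"
    utr3 <- if (isTRUE(g$ggc_tail)) strrep("GGC", g$u3_rest / 3L)
            else .rand_dna(g$u3_rest)
    spliced <- paste0(utr5, cds, stop_codon, utr3)
    # lay exons and introns in transcription space
    locus_tx <- character(0)
    off <- 0L
    for (i in seq_along(g$exons)) {
      locus_tx <- c(locus_tx, substr(spliced, off + 1L, off + g$exons[i]))
      off <- off + g$exons[i]
      if (i < length(g$exons)) {
        intron <- paste0("GT", .rand_dna(g$introns[i] - 4L), "AG")
        locus_tx <- c(locus_tx, intron)
      }
    }
    locus_tx <- paste(locus_tx, collapse = "")
    locus_len <- nchar(locus_tx)
    locus_genomic <- if (g$strand == "+") locus_tx else revcomp(locus_tx)
    gap <- .rand_dna(spec$gap_len)
    locus_start <- nchar(chrom_seq[[g$chrom]]) + spec$gap_len   # 0-based
    chrom_seq[[g$chrom]] <- paste0(chrom_seq[[g$chrom]], gap, locus_genomic)
    # exon intervals: transcription-space cumulative -> genomic
    exon_g <- matrix(0L, nrow = length(g$exons), ncol = 2)
    cum <- 0L
    for (i in seq_along(g$exons)) {
      s_tx <- cum; e_tx <- cum + g$exons[i]
      if (g$strand == "+") {
        exon_g[i, ] <- c(locus_start + s_tx, locus_start + e_tx)
      } else {
        exon_g[i, ] <- c(locus_start + locus_len - e_tx,
                         locus_start + locus_len - s_tx)
      }
      cum <- e_tx
      if (i < length(g$exons)) cum <- cum + g$introns[i]
    }
    # CDS genomic intervals: transcript coords [u5, u5+cds_len) per exon
    cds_g <- NULL
    exon_cum <- c(0L, cumsum(g$exons))
    for (i in seq_along(g$exons)) {
      a <- max(exon_cum[i], g$u5)
      b <- min(exon_cum[i + 1], g$u5 + cds_len)
      if (a >= b) next
      if (g$strand == "+") {
        gs <- exon_g[i, 1] + (a - exon_cum[i])
        cds_g <- rbind(cds_g, c(gs, gs + (b - a)))
      } else {
        ge <- exon_g[i, 2] - (a - exon_cum[i])
        cds_g <- rbind(cds_g, c(ge - (b - a), ge))
      }
    }
    tm <- transcript_model(paste0(gid, ".t1"), gid, toupper(gid), g$chrom,
                           g$strand, exon_g, cds_g)
    genes[[gid]] <- list(gene_id = gid, tx = tm, plan = g,
                         spliced = spliced, u5 = g$u5, cds_len = cds_len,
                         locus_start = locus_start, locus_len = locus_len)
    # GTF rows (1-based inclusive)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                     gid, gid, toupper(gid))
    span <- range(c(exon_g))
    gtf <- c(gtf,
             paste(g$chrom, "svneo_sim", "gene", span[1] + 1L, span[2], ".",
                   g$strand, ".", sprintf('gene_id "%s"; gene_name "%s";',
                                          gid, toupper(gid)), sep = "\t"),
             paste(g$chrom, "svneo_sim", "transcript", span[1] + 1L, span[2],
                   ".", g$strand, ".", attrs, sep = "\t"))
    for (i in order(exon_g[, 1])) {
      gtf <- c(gtf, paste(g$chrom, "svneo_sim", "exon", exon_g[i, 1] + 1L,
                          exon_g[i, 2], ".", g$strand, ".", attrs, sep = "\t"))
    }
    for (i in order(cds_g[, 1])) {
      gtf <- c(gtf, paste(g$chrom, "svneo_sim", "CDS", cds_g[i, 1] + 1L,
                          cds_g[i, 2], ".", g$strand, ".", attrs, sep = "\t"))
    }
  }
  # trailing gaps
  for (cn in names(chrom_seq)) {
    chrom_seq[[cn]] <- paste0(chrom_seq[[cn]], .rand_dna(spec$gap_len))
  }
  genome <- genome_from_strings(unlist(chrom_seq))
  txdb <- build_txdb(lapply(genes, function(g) g$tx))
  proteome <- txdb_proteome(txdb, genome)
  out <- list(genome = genome, txdb = txdb, genes = genes,
              proteome = proteome, gtf_lines = gtf, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta_path <- file.path(dir, "genome.fa")
    con <- file(fasta_path, "w")
    for (cn in names(chrom_seq)) {
      writeLines(paste0(">", cn), con)
      s <- chrom_seq[[cn]]
      starts <- seq(1, nchar(s), by = 60)
      writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
    }
    close(con)
    gtf_path <- file.path(dir, "annotation.gtf")
    writeLines(gtf, gtf_path)
    out$fasta_path <- fasta_path
    out$gtf_path <- gtf_path
  }
  out
}

# genomic 1-based position of transcript coordinate t for a sim gene
.sim_pos <- function(ref, gid, t) {
  tx_to_genome(ref$genes[[gid]]$tx, as.integer(t)) + 1L
}

# 1-based genomic midpoint of intron i (transcription order) of a sim gene
.sim_intron_mid <- function(ref, gid, i) {
  tx <- ref$genes[[gid]]$tx
  a <- tx$exons[i, , drop = TRUE]; b <- tx$exons[i + 1, , drop = TRUE]
  lo <- min(a[2], b[2]); hi <- max(a[1], b[1])
  as.integer((lo + hi) %/% 2) + 1L
}

# breakend at donor retained-coding-length d (the last retained coding base)
.sim_donor_be <- function(ref, gid, d) {
  g <- ref$genes[[gid]]
  stopifnot(d >= 1, d <= g$cds_len)
  breakend(g$tx$chrom, .sim_pos(ref, gid, g$u5 + d - 1L),
           .promoter_side(g$tx$strand))
}

# breakend at acceptor coding offset c (the first retained coding base)
.sim_acceptor_be <- function(ref, gid, c_) {
  g <- ref$genes[[gid]]
  stopifnot(c_ >= 0, c_ < g$cds_len)
  breakend(g$tx$chrom, .sim_pos(ref, gid, g$u5 + c_),
           .tail_side(g$tx$strand))
}

#' Spike a designed SV set into the toy reference
#'
#' Emits at least one SV per junction class (deletion-like,
#' duplication-like, head-to-head and tail-to-tail inversion,
#' translocation), each with in-frame and frameshift variants and in
#' single-gene and two-gene contexts where geometrically possible, plus
#' designed rejects (intergenic, incompatible orientation, 3'UTR donor,
#' start-codon loss) and a read-through event. Every spike gets its own
#' patient so per-patient and per-SV truth peptide sets coincide.
#'
#' The VCF is written in two dialects: pure bracket-BND (`svs_bnd.vcf`) and
#' mixed symbolic (`svs_symbolic.vcf`; `<DEL>`/`<DUP>` records for the
#' deletion/duplication-like junctions, BND for the rest). Truth records are
#' computed by the independent naive oracle ([naive_truth()]) from the
#' written files, never from the pipeline's internal objects.
#'
#' @param ref Reference from [make_toy_reference()] (built with `dir` set).
#' @param dir Directory for the VCFs (defaults to the reference directory).
#' @return List with `pairs`, `vcf_bnd`, `vcf_symbolic`, `truth` (list of
#'   truth records keyed by SV id), and `alleles_path`.
#' @export
spike_svs <- function(ref, dir = dirname(ref$fasta_path)) {
  if (is.null(ref$fasta_path)) stop("make_toy_reference() must be run with `dir` to write files")
  mk <- function(id, first, second, type = NA_character_) {
    sv_pair(id, first, second, declared_type = type,
            clonality = c("CLONAL", "SUBCLONAL")[(length(pairs) %% 2) + 1L],
            patient = sprintf("P%02d", length(pairs) + 1L))
  }
  pairs <- list()
  add <- function(p) pairs[[length(pairs) + 1L]] <<- p
  gap_pos <- function(chrom, before_gid) {
    # midpoint of the intergenic gap upstream of a gene locus
    ls <- ref$genes[[before_gid]]$locus_start
    as.integer(ls - ref$spec$gap_len / 2) + 1L
  }

  # deletion-like, single gene, intronic breakends (exon skip)
  add(mk("del_sg_if_intronic",
         breakend("chr1", .sim_intron_mid(ref, "g1", 1), "LEFT"),
         breakend("chr1", .sim_intron_mid(ref, "g1", 2), "RIGHT"), "DEL"))
  add(mk("del_sg_fs_intronic",
         breakend("chr1", .sim_intron_mid(ref, "g2", 1), "LEFT"),
         breakend("chr1", .sim_intron_mid(ref, "g2", 2), "RIGHT"), "DEL"))
  # deletion-like, single gene, exonic breakends (junction-derived codons)
  add(mk("del_sg_if_exonic", .sim_donor_be(ref, "g1", 103L),
         .sim_acceptor_be(ref, "g1", 205L), "DEL"))
  add(mk("del_sg_fs_exonic", .sim_donor_be(ref, "g2", 100L),
         .sim_acceptor_be(ref, "g2", 204L), "DEL"))
  # deletion-like, two genes
  add(mk("del_tg_if", .sim_donor_be(ref, "g1", 90L),
         .sim_acceptor_be(ref, "g2", 201L), "DEL"))
  add(mk("del_tg_fs", .sim_donor_be(ref, "g1", 91L),
         .sim_acceptor_be(ref, "g2", 201L), "DEL"))
  # duplication-like, single gene (tandem exon-2 duplication)
  add(mk("dup_sg_if",
         breakend("chr1", .sim_intron_mid(ref, "g1", 1), "RIGHT"),
         breakend("chr1", .sim_intron_mid(ref, "g1", 2), "LEFT"), "DUP"))
  add(mk("dup_sg_fs",
         breakend("chr1", .sim_intron_mid(ref, "g2", 1), "RIGHT"),
         breakend("chr1", .sim_intron_mid(ref, "g2", 2), "LEFT"), "DUP"))
  # duplication-like, two genes (donor downstream, acceptor upstream)
  add(mk("dup_tg_if", .sim_acceptor_be(ref, "g1", 120L),
         .sim_donor_be(ref, "g4", 90L), "DUP"))
  add(mk("dup_tg_fs", .sim_acceptor_be(ref, "g1", 121L),
         .sim_donor_be(ref, "g4", 90L), "DUP"))
  # head-to-head inversions (plus donor, minus acceptor)
  add(mk("h2h_tg_if", .sim_donor_be(ref, "g1", 60L),
         .sim_acceptor_be(ref, "g3", 150L)))
  add(mk("h2h_tg_fs", .sim_donor_be(ref, "g2", 61L),
         .sim_acceptor_be(ref, "g3", 153L)))
  # tail-to-tail inversions (minus donor, plus acceptor)
  add(mk("t2t_tg_if", .sim_donor_be(ref, "g5", 99L),
         .sim_acceptor_be(ref, "g4", 150L)))
  add(mk("t2t_tg_fs", .sim_donor_be(ref, "g5", 100L),
         .sim_acceptor_be(ref, "g4", 153L)))
  # translocations
  add(mk("tra_if", .sim_donor_be(ref, "g1", 120L),
         .sim_acceptor_be(ref, "g7", 90L)))
  add(mk("tra_fs", .sim_donor_be(ref, "g2", 103L),
         .sim_acceptor_be(ref, "g7", 90L)))
  add(mk("tra_minus_fs", .sim_donor_be(ref, "g8", 90L),
         .sim_acceptor_be(ref, "g3", 100L)))
  # read-through: junction removes g6's stop codon; the retained tail is
  # GGC-only, so translation runs to the transcript 3' boundary
  g6 <- ref$genes[["g6"]]
  add(mk("rt_sg",
         breakend("chr1", .sim_intron_mid(ref, "g6", 1), "LEFT"),
         breakend("chr1", .sim_pos(ref, "g6", g6$u5 + g6$cds_len + 3L + 6L),
                  "RIGHT"), "DEL"))
  # designed rejects
  add(mk("reject_intergenic_both",
         breakend("chr1", gap_pos("chr1", "g2"), "LEFT"),
         breakend("chr1", gap_pos("chr1", "g3"), "RIGHT"), "DEL"))
  add(mk("reject_intergenic_one", .sim_donor_be(ref, "g1", 50L),
         breakend("chr1", gap_pos("chr1", "g3"), "RIGHT"), "DEL"))
  add(mk("reject_orientation", .sim_donor_be(ref, "g1", 50L),
         breakend("chr1", .sim_pos(ref, "g2",
                                   ref$genes[["g2"]]$u5 + 60L), "LEFT")))
  g1 <- ref$genes[["g1"]]
  add(mk("reject_utr3_donor",
         breakend("chr1", .sim_pos(ref, "g1", g1$u5 + g1$cds_len + 10L), "LEFT"),
         .sim_acceptor_be(ref, "g2", 90L), "DEL"))
  add(mk("reject_startloss",
         breakend("chr1", .sim_pos(ref, "g1", 10L), "LEFT"),
         breakend("chr1", .sim_intron_mid(ref, "g1", 2), "RIGHT"), "DEL"))

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf_bnd <- file.path(dir, "svs_bnd.vcf")
  write_sv_vcf(pairs, vcf_bnd)
  vcf_symbolic <- file.path(dir, "svs_symbolic.vcf")
  .write_symbolic_vcf(pairs, vcf_symbolic)
  alleles_path <- file.path(dir, "alleles.txt")
  writeLines(c("HLA-A*02:01", "HLA-B*07:02"), alleles_path)
  truth <- naive_truth(vcf_bnd, ref$gtf_path, ref$fasta_path)
  list(pairs = pairs, vcf_bnd = vcf_bnd, vcf_symbolic = vcf_symbolic,
       truth = truth, alleles_path = alleles_path)
}

# symbolic dialect: DEL/DUP junctions as <DEL>/<DUP>+END, the rest as BND
.write_symbolic_vcf <- function(pairs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
           "##INFO=<ID=CLONALITY,Number=1,Type=String,Description=\"Clonality label\">",
           "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  rows <- character(0)
  leftover <- list()
  for (p in pairs) {
    a <- p$first; b <- p$second
    extra <- sprintf(";CLONALITY=%s;PATIENT=%s", p$clonality, p$patient)
    same <- a$chrom == b$chrom
    lo <- if (same && a$pos > b$pos) b else a
    hi <- if (same && a$pos > b$pos) a else b
    if (same && lo$orient == "LEFT" && hi$orient == "RIGHT") {
      rows <- c(rows, paste(lo$chrom, lo$pos, p$id, "N", "<DEL>", ".", "PASS",
                            paste0("SVTYPE=DEL;END=", hi$pos, extra), sep = "\t"))
    } else if (same && lo$orient == "RIGHT" && hi$orient == "LEFT") {
      rows <- c(rows, paste(lo$chrom, lo$pos, p$id, "N", "<DUP>", ".", "PASS",
                            paste0("SVTYPE=DUP;END=", hi$pos, extra), sep = "\t"))
    } else {
      leftover[[length(leftover) + 1L]] <- p
    }
  }
  tmp <- tempfile()
  write_sv_vcf(leftover, tmp)
  bnd_rows <- readLines(tmp)
  unlink(tmp)
  bnd_rows <- bnd_rows[!startsWith(bnd_rows, "#")]
  writeLines(c(hdr, rows, bnd_rows), path)
  invisible(path)
}

#' Simulate cohort tables with known parameters
#'
#' Per-SV covariates and outcomes are drawn from the logistic depletion
#' model at the spec's true coefficients; clonality labels are drawn so
#' that the odds of being subclonal differ between neoantigenic and
#' non-neoantigenic SVs by the spec's true enrichment odds ratio.
#'
#' @param spec A `SimSpec` (the `cohort` element supplies the parameters).
#' @param seed Optional override of `spec$seed`.
#' @return List with `sv_table` (patient, X1, X2, X3, y, clonality,
#'   neoantigenic) and `patients` (per-patient aggregated counts).
#' @export
simulate_cohort <- function(spec = sim_spec(), seed = NULL) {
  p <- spec$cohort
  set.seed(if (is.null(seed)) spec$seed else seed)
  rows <- list()
  for (i in seq_len(p$n_patients)) {
    n <- sample(seq(p$svs_per_patient[1], p$svs_per_patient[2]), 1)
    X1 <- stats::rbinom(n, 1, p$p_oncogenic)
    X2 <- stats::rpois(n, p$x2_mean)
    X3 <- stats::rbinom(n, 1, p$p_frameshift)
    eta <- p$beta[1] + p$beta[2] * X1 + p$beta[3] * X2 + p$beta[4] * X3
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    odds0 <- p$p_subclonal / (1 - p$p_subclonal)
    odds1 <- odds0 * p$subclonal_or
    p_sub <- ifelse(y == 1, odds1 / (1 + odds1), odds0 / (1 + odds0))
    clon <- ifelse(stats::runif(n) < p_sub, "SUBCLONAL", "CLONAL")
    rows[[i]] <- data.frame(patient = sprintf("SIM%03d", i),
                            X1 = X1, X2 = X2, X3 = X3, y = y,
                            clonality = clon, neoantigenic = y == 1)
  }
  sv_table <- do.call(rbind, rows)
  patients <- do.call(rbind, lapply(split(sv_table, sv_table$patient),
    function(d) data.frame(patient = d$patient[1], n_sv = nrow(d),
                           n_neoantigenic = sum(d$y),
                           n_subclonal = sum(d$clonality == "SUBCLONAL"))))
  rownames(patients) <- NULL
  list(sv_table = sv_table, patients = patients)
}
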