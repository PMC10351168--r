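# Hand-built fixtures, independent of the simdata generator, with geometry
# chosen so that coding offsets and spliced products can be verified by hand.

# Plus-strand 3-exon gene "P" on contig cA:
#   exon1 [100,220)  (120 nt; 30 nt 5'UTR + 90 coding)
#   exon2 [300,420)  (120 nt, fully coding)
#   exon3 [500,620)  (120 nt; 60 coding + stop + 57 nt 3'UTR)
# CDS: [130,220) + [300,420) + [500,560); cds_len = 270 (stop codon excluded,
# sits at [560,563)).
hand_gene_plus <- function() {
  transcript_model("P.t1", "P", "PGENE", "cA", "+",
                   exons = rbind(c(100L, 220L), c(300L, 420L), c(500L, 620L)),
                   cds = rbind(c(130L, 220L), c(300L, 420L), c(500L, 560L)))
}

# Minus-strand 2-exon gene "M" on contig cB (transcription order):
#   exon1 [400,520) (120 nt; 20 nt 5'UTR + 100 coding)
#   exon2 [200,320) (120 nt; 50 coding + stop + 67 nt 3'UTR)
# CDS: genomic [400,500) (exon1) + [270,320) (exon2); cds_len = 150,
# stop codon at genomic [267,270).
hand_gene_minus <- function() {
  transcript_model("M.t1", "M", "MGENE", "cB", "-",
                   exons = rbind(c(400L, 520L), c(200L, 320L)),
                   cds = rbind(c(400L, 500L), c(270L, 320L)))
}

# genome whose exonic content makes both genes translate cleanly: the coding
# sequence is written directly into the exon intervals (ATG ... stop)
hand_genome <- function(seed = 42L) {
  set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  codons <- setdiff(apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                                      c("T","C","A","G")), 1, paste,
                          collapse = ""), c("TAA", "TAG", "TGA"))
  cds_of <- function(n_nt) paste0("ATG", paste(sample(codons, n_nt / 3 - 1,
                                                      replace = TRUE),
                                               collapse = ""))
  # contig cA: gene P (plus strand): spliced = 30 UTR5 + 270 CDS + TAA + 56
  p_cds <- cds_of(270L)
  p_spliced <- paste0(rand(30), p_cds, "TAA", rand(57))
  cA <- paste0(rand(100),
               substr(p_spliced, 1, 120),        # exon1
               rand(80),
               substr(p_spliced, 121, 240),      # exon2
               rand(80),
               substr(p_spliced, 241, 360),      # exon3
               rand(80))
  # contig cB: gene M (minus strand): spliced = 20 UTR5 + 150 CDS + TAA + 67
  m_cds <- cds_of(150L)
  m_spliced <- paste0(rand(20), m_cds, "TAA", rand(67))
  locus <- paste0(substr(m_spliced, 1, 120),     # exon1 (transcription order)
                  rand(80),
                  substr(m_spliced, 121, 240))   # exon2
  cB <- paste0(rand(200), revcomp(locus), rand(180))
  genome_from_strings(c(cA = cA, cB = cB))
}

hand_txdb <- function() build_txdb(list(hand_gene_plus(), hand_gene_minus()))

# standard spiked toy data set used across tests; cached per session
toy_fixture_env <- new.env()
toy_fixture <- function(seed = 7L) {
  key <- paste0("fx", seed)
  if (is.null(toy_fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("svneo_fx_", seed))
    ref <- make_toy_reference(sim_spec(seed = seed), dir = dir)
    sp <- spike_svs(ref)
    toy_fixture_env[[key]] <- list(ref = ref, sp = sp)
  }
  toy_fixture_env[[key]]
}

# random exonic-breakend SV pairs over the toy genes, with valid
# donor/acceptor orientations (used by the translation/frame oracle tests)
random_sv_pairs <- function(ref, n, seed = 1L) {
  set.seed(seed)
  gids <- names(ref$genes)
  pairs <- list()
  seen <- character(0)
  while (length(pairs) < n) {
    dg <- sample(gids, 1); ag <- sample(gids, 1)
    d_cds <- ref$genes[[dg]]$cds_len
    a_cds <- ref$genes[[ag]]$cds_len
    d <- sample(seq(3L, d_cds - 3L), 1)
    a <- sample(seq(0L, a_cds - 9L), 1)
    b1 <- svneo:::.sim_donor_be(ref, dg, d)
    b2 <- svneo:::.sim_acceptor_be(ref, ag, a)
    if (b1$chrom == b2$chrom && b1$pos == b2$pos) next
    p <- sv_pair(sprintf("rand%03d", length(pairs) + 1L), b1, b2,
                 patient = sprintf("RP%03d", length(pairs) + 1L))
    key <- svneo:::.pair_key(p)
    if (key %in% seen) next     # parser deduplicates junctions; avoid clashes
    seen <- c(seen, key)
    pairs[[length(pairs) + 1L]] <- p
  }
  pairs
}
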