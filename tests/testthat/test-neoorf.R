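# Neo-transcript assembly, frame determination, translation, mutated span.

hand_assembly_fixture <- function() {
  db <- hand_txdb()
  genome <- hand_genome()
  list(db = db, genome = genome, tx = db$transcripts[["P.t1"]])
}

test_that("intronic breakends splice at complete exon boundaries", {
  fx <- hand_assembly_fixture()
  # deletion: donor in intron 1 (genomic [220,300)), acceptor in intron 2
  # ([420,500)) of gene P -> mrna = exon1 + exon3
  ann <- annotate_sv(sv_pair("del", breakend("cA", 261L, "LEFT"),
                             breakend("cA", 461L, "RIGHT")), fx$db)
  nt <- assemble_neo_transcript(ann, fx$db, fx$genome)
  full <- transcript_sequence(fx$tx, fx$genome)
  expect_s3_class(nt, "NeoTranscript")
  expect_equal(nt$junction_nt, 120L)
  expect_equal(nt$mrna, paste0(substr(full, 1, 120), substr(full, 241, 360)))
  expect_equal(nt$donor_cds_contribution, 90L)   # exon1 minus 30 nt 5'UTR
  # exon 2 is 120 nt (multiple of 3): skipping it keeps the frame
  expect_false(determine_frame(nt))
})

test_that("exonic breakends truncate the exon at the retained base", {
  fx <- hand_assembly_fixture()
  ann <- annotate_sv(sv_pair("delx", breakend("cA", 341L, "LEFT"),
                             breakend("cA", 520L, "RIGHT")), fx$db)
  nt <- assemble_neo_transcript(ann, fx$db, fx$genome)
  full <- transcript_sequence(fx$tx, fx$genome)
  # donor: exon1 + 41 retained bases of exon2 (transcript coords [0,161))
  # acceptor: exon3 from its 20th base, pos 520 included (transcript coord 259)
  expect_equal(nt$junction_nt, 161L)
  expect_equal(nt$mrna, paste0(substr(full, 1, 161), substr(full, 260, 360)))
})

test_that("frame arithmetic follows donor coding length and acceptor phase", {
  mk_nt <- function(donor_cds, native_phase, u = 0L, has_coding = TRUE) {
    structure(list(donor_cds_contribution = donor_cds,
                   acceptor_info = list(u = u, native_phase = native_phase,
                                        has_coding = has_coding)),
              class = "NeoTranscript")
  }
  expect_false(determine_frame(mk_nt(120L, 0L)))   # 120 mod 3 == 0
  expect_true(determine_frame(mk_nt(121L, 0L)))    # 121 mod 3 == 1
  expect_false(determine_frame(mk_nt(121L, 1L)))
  # acceptor 5'UTR remainder counts toward the chimeric frame
  expect_false(determine_frame(mk_nt(120L, 0L, u = 9L)))
  expect_true(determine_frame(mk_nt(120L, 0L, u = 10L)))
  # no coding context downstream -> frameshift by definition
  expect_true(determine_frame(mk_nt(120L, NA_integer_, has_coding = FALSE)))
})

test_that("single-gene tandem duplication of a 3n exon stays in frame", {
  fx <- hand_assembly_fixture()
  # duplication-like junction around exon 2 (120 nt): donor = copy ending in
  # intron 2, acceptor = copy starting in intron 1
  ann <- annotate_sv(sv_pair("dup", breakend("cA", 261L, "RIGHT"),
                             breakend("cA", 461L, "LEFT")), fx$db)
  expect_true(ann$feasible)
  nt <- assemble_neo_transcript(ann, fx$db, fx$genome)
  full <- transcript_sequence(fx$tx, fx$genome)
  # mrna = exon1 + exon2 + exon2 + exon3
  expect_equal(nt$mrna, paste0(substr(full, 1, 240), substr(full, 121, 360)))
  expect_false(determine_frame(nt))
  # brute-force check: translating the duplicated mRNA diverges from the
  # wild type only by an inserted in-frame block
  np <- translate_neo(nt, wt = wt_protein(fx$tx, fx$genome))
  expect_false(np$frameshift)
  expect_equal(np$termination, "STOP")
  expect_equal(nchar(np$sequence), nchar(wt_protein(fx$tx, fx$genome)) + 40L)
})

test_that("translation stops at the first stop codon or runs through", {
  mk <- function(mrna, cds_start = 0L) {
    structure(list(mrna = mrna, junction_nt = nchar(mrna),
                   cds_start_nt = cds_start, donor_cds_contribution = 0L,
                   acceptor_info = list(u = 0L, native_phase = 0L,
                                        has_coding = TRUE),
                   donor_gene = "d", acceptor_gene = "a",
                   single_gene = FALSE, start_lost = FALSE),
              class = "NeoTranscript")
  }
  np <- translate_neo(mk("ATGGCCTAAGGG"))
  expect_equal(np$sequence, "MA")
  expect_equal(np$termination, "STOP")
  np2 <- translate_neo(mk("ATGGCCGGA"))
  expect_equal(np2$sequence, "MAG")
  expect_equal(np2$termination, "READ_THROUGH")
  # trailing incomplete codon is discarded
  np3 <- translate_neo(mk("ATGGCCGGAGG"))
  expect_equal(np3$sequence, "MAG")
  expect_equal(np3$termination, "READ_THROUGH")
  # codons containing N translate to X
  np4 <- translate_neo(mk("ATGGNCAAA"))
  expect_equal(np4$sequence, "MXK")
})

test_that("frameshift toy equals brute-force one-frame translation", {
  # donor prefix ATGGC joined to acceptor CAGGTAA...: translate the plain
  # concatenation with an independent translator (Biostrings)
  mrna <- paste0("ATGGC", "CAGGTAAGGCTGA")
  nt <- structure(list(mrna = mrna, junction_nt = 5L, cds_start_nt = 0L,
                       donor_cds_contribution = 5L,
                       acceptor_info = list(u = 0L, native_phase = 0L,
                                            has_coding = TRUE),
                       donor_gene = "d", acceptor_gene = "a",
                       single_gene = FALSE, start_lost = FALSE),
                  class = "NeoTranscript")
  np <- translate_neo(nt)
  oracle <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mrna, 1, 3 * (nchar(mrna) %/% 3)))))
  oracle <- sub("\\*.*$", "", oracle)
  expect_equal(np$sequence, oracle)
  expect_true(np$frameshift)   # 5 mod 3 != 0
})

test_that("start-codon loss rejects unless rescue is enabled", {
  fx <- hand_assembly_fixture()
  # donor breakend in the 5'UTR of gene P (transcript coord 10 -> pos 111)
  ann <- annotate_sv(sv_pair("sl", breakend("cA", 111L, "LEFT"),
                             breakend("cA", 461L, "RIGHT")), fx$db)
  expect_true(ann$feasible)      # breakpoint filters pass; assembly rejects
  expect_equal(assemble_neo_transcript(ann, fx$db, fx$genome),
               "NO_UTR_STRUCTURE")
  nt <- assemble_neo_transcript(ann, fx$db, fx$genome, start_rescue = TRUE)
  expect_s3_class(nt, "NeoTranscript")
  np <- translate_neo(nt)
  expect_true(np$start_rescued)
  expect_equal(substr(np$sequence, 1, 1), "M")
})

test_that("mutated span marks the divergent residue window", {
  mk_np <- function(seq, frameshift, single_gene, termination = "STOP") {
    structure(list(sequence = seq, frameshift = frameshift,
                   single_gene = single_gene, termination = termination),
              class = "NeoProtein")
  }
  # first difference at index 2, frameshift-like tail
  expect_equal(mutated_interval(mk_np("MAXYZ", TRUE, TRUE), "MABCD"),
               c(2L, 5L))
  # in-frame deletion with identical junction residues: empty span
  expect_equal(mutated_interval(mk_np("MABGH", FALSE, TRUE), "MABDEFGH"),
               c(3L, 3L))
  # frameshift diverging from residue 7 of a 30-mer
  wt <- strrep("A", 40)
  np_seq <- paste0(strrep("A", 7), strrep("W", 23))
  expect_equal(mutated_interval(mk_np(np_seq, TRUE, TRUE), wt), c(7L, 30L))
  # identical sequences: empty span at 0
  expect_equal(mutated_interval(mk_np("MABC", FALSE, TRUE), "MABC"),
               c(0L, 0L))
  # in-frame single-gene insertion: junction window only
  expect_equal(mutated_interval(mk_np("MAQQBC", FALSE, TRUE), "MABC"),
               c(2L, 4L))
  # two-gene in-frame fusion: span extends to the end
  expect_equal(mutated_interval(mk_np("MAXYZ", FALSE, FALSE), "MABCD"),
               c(2L, 5L))
})

test_that("in-frame two-gene fusion at codon boundaries concatenates the
           wild-type prefix and suffix", {
  fx <- toy_fixture()
  ref <- fx$ref
  # exact codon boundary: donor keeps 90 coding nt of g1, acceptor enters
  # g2 at coding offset 201 (both multiples of 3)
  pr <- sv_pair("fus", svneo:::.sim_donor_be(ref, "g1", 90L),
                svneo:::.sim_acceptor_be(ref, "g2", 201L), patient = "PX")
  ann <- annotate_sv(pr, ref$txdb)
  nt <- assemble_neo_transcript(ann, ref$txdb, ref$genome)
  np <- translate_neo(nt, wt = ref$proteome[["g1"]])
  expect_false(np$frameshift)
  expect_equal(np$junction_aa, 30L)       # 90 / 3
  donor_prefix <- substr(ref$proteome[["g1"]], 1, 30)
  acceptor_suffix <- substr(ref$proteome[["g2"]], 68, nchar(ref$proteome[["g2"]]))
  if (np$termination == "STOP") {
    expect_equal(np$sequence, paste0(donor_prefix, acceptor_suffix))
  }
})

test_that("protein length equals the number of complete codons translated", {
  fx <- toy_fixture()
  run <- run_pipeline(run_config(vcf = fx$sp$vcf_bnd, gtf = fx$ref$gtf_path,
                                 fasta = fx$ref$fasta_path,
                                 alleles = fx$sp$alleles_path,
                                 backend = "never"))
  for (i in seq_len(nrow(run$proteins))) {
    id <- run$proteins$sv_id[i]
    t <- fx$sp$truth[[id]]
    expect_equal(nchar(run$proteins$sequence[i]), nchar(t$protein))
  }
})
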