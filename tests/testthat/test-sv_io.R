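# VCF breakend parsing, canonicalization, and annotation loading.

write_vcf_lines <- function(rows, path,
                            info_hdr = c("SVTYPE", "END", "MATEID", "CHR2", "CT")) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"x\">",
                   info_hdr),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

pair_keys <- function(pairs) sort(vapply(pairs, svneo:::.pair_key, character(1)))

test_that("bracket ALT forms map to side-retained orientations", {
  f <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "chr1\t1000\tb1\tA\tA[chr2:5000[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr2\t5000\tb2\tT\t]chr1:1000]T\t.\tPASS\tSVTYPE=BND;MATEID=b1"), f)
  p <- parse_sv_vcf(f)
  expect_equal(length(p$pairs), 1L)
  expect_equal(nrow(p$rejects), 0L)
  pr <- p$pairs[[1]]
  ends <- list(pr$first, pr$second)
  left <- ends[[which(vapply(ends, function(e) e$chrom, "") == "chr1")]]
  right <- ends[[which(vapply(ends, function(e) e$chrom, "") == "chr2")]]
  expect_equal(left$pos, 1000L); expect_equal(left$orient, "LEFT")
  expect_equal(right$pos, 5000L); expect_equal(right$orient, "RIGHT")

  # all four bracket forms, self-contained records (no MATEID)
  f2 <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "chr1\t10\ta\tN\tN]chr1:90]\t.\tPASS\tSVTYPE=BND",
    "chr1\t20\tb\tN\t]chr1:80]N\t.\tPASS\tSVTYPE=BND",
    "chr1\t30\tc\tN\t[chr1:70[N\t.\tPASS\tSVTYPE=BND"), f2)
  p2 <- parse_sv_vcf(f2)
  orients <- lapply(p2$pairs, function(q) c(q$first$orient, q$second$orient))
  expect_equal(orients[[1]], c("LEFT", "LEFT"))     # t]p]
  expect_equal(orients[[2]], c("RIGHT", "LEFT"))    # ]p]t
  expect_equal(orients[[3]], c("RIGHT", "RIGHT"))   # [p[t
})

test_that("symbolic alleles canonicalize; DEL equals its BND form", {
  f <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "chr1\t1000\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5000",
    "chr1\t1000\tb1\tN\tN[chr1:5000[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr1\t5000\tb2\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=b1"), f)
  p <- parse_sv_vcf(f)
  # deduplicated: symbolic record and BND mates describe the same junction
  expect_equal(length(p$pairs), 1L)
  pr <- p$pairs[[1]]
  expect_equal(pr$declared_type, "DEL")
  expect_equal(pr$first$orient, "LEFT")
  expect_equal(pr$second$orient, "RIGHT")
  expect_equal(pr$second$pos, 5000L)

  f2 <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "chr1\t100\tu1\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=900",
    "chr1\t100\ti1\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=900",
    "chr1\t100\tt1\tN\t<TRA>\t.\tPASS\tSVTYPE=TRA;CHR2=chr2;END=300;CT=3to5"), f2)
  p2 <- parse_sv_vcf(f2)
  expect_equal(length(p2$pairs), 4L)       # DUP + two INV junctions + TRA
  ids <- vapply(p2$pairs, function(q) q$id, "")
  expect_true(all(c("i1_h2h", "i1_t2t") %in% ids))
  inv_h <- p2$pairs[[match("i1_h2h", ids)]]
  expect_equal(c(inv_h$first$orient, inv_h$second$orient), c("LEFT", "LEFT"))
  inv_t <- p2$pairs[[match("i1_t2t", ids)]]
  expect_equal(c(inv_t$first$orient, inv_t$second$orient), c("RIGHT", "RIGHT"))
  tra <- p2$pairs[[match("t1", ids)]]
  expect_equal(tra$second$chrom, "chr2")
  expect_equal(c(tra$first$orient, tra$second$orient), c("LEFT", "RIGHT"))
})

test_that("records failing canonicalization are rejected with reasons", {
  f <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "chr1\t10\tbad1\tN\tN[chr1_broken\t.\tPASS\tSVTYPE=BND",
    "chr1\t20\tbad2\tN\tN[chr1:50[\t.\tPASS\tSVTYPE=BND;MATEID=ghost",
    "chr1\t30\tbad3\tN\t<WEIRD>\t.\tPASS\tSVTYPE=WEIRD;END=99",
    "chr1\t40\tbad4\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL",
    "chr1\t50\tbad5\tN\t<TRA>\t.\tPASS\tSVTYPE=TRA;CHR2=chr2;END=70"), f)
  p <- parse_sv_vcf(f)
  expect_equal(length(p$pairs), 0L)
  expect_setequal(p$rejects$id, c("bad1", "bad2", "bad3", "bad4", "bad5"))
  expect_equal(p$rejects$reason[p$rejects$id == "bad1"], "unparseable ALT")
  expect_equal(p$rejects$reason[p$rejects$id == "bad2"], "unpaired BND")
  expect_match(p$rejects$reason[p$rejects$id == "bad3"], "unknown symbolic")
  expect_equal(p$rejects$reason[p$rejects$id == "bad4"], "missing END")
})

test_that("mate order does not change the parsed pair set", {
  rows <- c("chr1\t1000\tb1\tN\tN[chr2:5000[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
            "chr2\t5000\tb2\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=b1")
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf_lines(rows, f1)
  write_vcf_lines(rev(rows), f2)
  expect_equal(pair_keys(parse_sv_vcf(f1)$pairs),
               pair_keys(parse_sv_vcf(f2)$pairs))
})

test_that("write + re-parse round-trips the canonical pair set", {
  set.seed(11)
  pairs <- lapply(1:12, function(i) {
    sv_pair(sprintf("sv%02d", i),
            breakend(sample(c("chr1", "chr2"), 1), sample(1e5, 1),
                     sample(c("LEFT", "RIGHT"), 1)),
            breakend(sample(c("chr1", "chr2"), 1), sample(1e5, 1),
                     sample(c("LEFT", "RIGHT"), 1)),
            clonality = sample(c("CLONAL", "SUBCLONAL"), 1),
            patient = "PX")
  })
  f <- tempfile(fileext = ".vcf")
  write_sv_vcf(pairs, f)
  back <- parse_sv_vcf(f)
  expect_equal(nrow(back$rejects), 0L)
  expect_equal(pair_keys(back$pairs), pair_keys(pairs))
  expect_equal(sort(vapply(back$pairs, function(p) p$id, "")),
               sort(vapply(pairs, function(p) p$id, "")))
})

test_that("chromosome names are normalized against the genome", {
  g <- genome_from_strings(c(chr1 = strrep("ACGT", 30)))
  f <- tempfile(fileext = ".vcf")
  write_vcf_lines("1\t10\td\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=90", f)
  p <- parse_sv_vcf(f, genome = g)
  expect_equal(p$pairs[[1]]$first$chrom, "chr1")
  f2 <- tempfile(fileext = ".vcf")
  write_vcf_lines("chrZ\t10\td\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=90", f2)
  p2 <- parse_sv_vcf(f2, genome = g)
  expect_equal(length(p2$pairs), 0L)
  expect_match(p2$rejects$reason, "not found in genome")
})

test_that("header-only VCF yields empty pairs and rejects", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), f)
  p <- parse_sv_vcf(f)
  expect_length(p$pairs, 0)
  expect_equal(nrow(p$rejects), 0L)
})

test_that("annotation loads with strand-ordered exons and CDS bookkeeping", {
  fx <- toy_fixture()
  txdb <- load_annotation(fx$ref$gtf_path)
  expect_equal(length(txdb$genes), 8L)
  # minus-strand transcription order: descending genomic starts
  g3 <- txdb$transcripts[["g3.t1"]]
  expect_equal(g3$strand, "-")
  expect_true(all(diff(g3$exons[, 1]) < 0))
  # 5'UTR + CDS + 3'UTR partition the exonic length (every coding transcript)
  for (tx in txdb$transcripts) {
    expect_equal(tx$utr5_len + tx$cds_length + tx$utr3_len, tx$tx_length)
  }
  # reconstructed CDS length matches the generator's geometry
  expect_equal(txdb$transcripts[["g1.t1"]]$cds_length,
               fx$ref$genes$g1$cds_len)
})

test_that("transcripts whose CDS escapes the exons are excluded as malformed", {
  gtf <- c(
    "chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id \"gX\"; transcript_id \"gX.t1\";",
    "chr1\tx\tCDS\t150\t260\t.\t+\t.\tgene_id \"gX\"; transcript_id \"gX.t1\";",
    "chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id \"gY\"; transcript_id \"gY.t1\";",
    "chr1\tx\tCDS\t320\t340\t.\t+\t.\tgene_id \"gY\"; transcript_id \"gY.t1\";")
  f <- tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  expect_message(txdb <- load_annotation(f), "malformed")
  expect_equal(txdb$malformed$transcript_id, "gX.t1")
  expect_equal(names(txdb$transcripts), "gY.t1")
})

test_that("longest-CDS isoform selection with deterministic tie-break", {
  mk <- function(tid, cds_end) {
    transcript_model(tid, "G", "G", "c", "+",
                     exons = rbind(c(0L, 500L)),
                     cds = rbind(c(30L, cds_end)))
  }
  db <- build_txdb(list(mk("tB", 330L), mk("tA", 480L)))
  expect_equal(select_transcript(db, "G")$transcript_id, "tA")   # 450 beats 300
  db2 <- build_txdb(list(mk("tB", 330L), mk("tA", 330L)))
  expect_equal(select_transcript(db2, "G")$transcript_id, "tA")  # lexicographic
  noncoding <- transcript_model("tN", "N", "N", "c", "+",
                                exons = rbind(c(0L, 100L)))
  db3 <- build_txdb(list(noncoding))
  expect_null(select_transcript(db3, "N"))
})

test_that("genome accessors honour half-open coordinates and bounds", {
  g <- genome_from_strings(c(c1 = "ACGT"))
  expect_equal(genome_subseq(g, "c1", 0, 2), "AC")
  expect_equal(genome_subseq(g, "c1", 2, 4), "GT")
  expect_equal(revcomp("ACGT"), "ACGT")    # palindrome
  expect_equal(revcomp("AACG"), "CGTT")
  expect_error(genome_subseq(g, "c1", 2, 5), "out of bounds")
  expect_error(genome_subseq(g, "nope", 0, 1), "unknown contig")
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(load_genome(dup), "duplicate")
})
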