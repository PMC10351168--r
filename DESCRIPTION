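Package: svneo
Title: Prediction of MHC Class I Neoantigens from Somatic Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts MHC class I neoantigens arising from somatic structural
    variants (SVs). Breakend pairs parsed from VCF (bracket BND notation or
    symbolic alleles) are mapped onto a transcript annotation, filtered for
    orientation feasibility, assembled into chimeric neo-transcripts, and
    translated with frameshift and read-through bookkeeping. Neo-proteins are
    fragmented into 8-11-mer candidate peptides, purged of self peptides, and
    scored against patient HLA alleles through a pluggable MHC binding backend
    (external predictor adapters plus a deterministic mock for testing).
    Cohort-level immunogenomic statistics are included: shared-neoantigen
    recurrence, peptidome self-dissimilarity, intratumor heterogeneity,
    immunoediting odds ratios with the Haldane-Anscombe correction, a
    covariate-adjusted logistic depletion model, and integrated neoantigen
    burden metrics. A synthetic-data module generates toy genomes, annotations,
    and spiked SV call sets with analytically known truth peptides.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
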