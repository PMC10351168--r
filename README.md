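# svneo — MHC class I neoantigen prediction from somatic structural variants

Somatic structural variants (SVs) — deletions, duplications, inversions,
translocations — fuse distant genomic segments. When a junction falls inside
genes, the rearranged locus can produce a chimeric transcript whose
translation exposes peptides the immune system has never seen, including
long frameshifted tails of entirely novel sequence. Most neoantigen callers
only consider SNVs and small indels; svneo covers the SV-derived repertoire.

The package is for cancer immunogenomics analysts: it takes somatic SV
calls (VCF, bracket-BND or symbolic), a transcript annotation (GTF/GFF), a
reference genome (FASTA), and patient HLA class I alleles, and produces
neoantigen calls plus the cohort-level statistics used to study them.

## The method

1. **Canonicalize junctions.** Every record becomes one or two breakend
   pairs with side-retained orientations (`LEFT` = bases ≤ pos kept,
   `RIGHT` = bases ≥ pos kept); `<INV>` expands into its head-to-head and
   tail-to-tail junctions. Orientation geometry classifies each junction
   (deletion-like, duplication-like, h2h/t2t inversion, translocation).
2. **Filter.** Junctions with intergenic breakpoints are removed, as are
   junctions where no donor/acceptor role assignment lets transcription run
   continuously across the junction (the donor must retain its promoter
   side, the acceptor its 3' remainder). Per gene, the longest-CDS isoform
   is used.
3. **Assemble and translate.** The chimeric mRNA = donor spliced sequence
   up to the breakend + acceptor spliced sequence from the breakend
   (intronic breakends splice at the nearest complete exon boundary).
   Translation runs from the donor start codon to the first stop
   (`STOP`) or the transcript end (`READ_THROUGH`). A junction is
   **frameshift** when the donor's retained coding length mod 3 differs
   from the native phase of the first acceptor-derived coding base.
4. **Window and filter peptides.** All 8–11-mers overlapping the mutated
   residue span by ≥ 1 residue are candidates; exact substrings of any
   wild-type protein are removed.
5. **Call neoantigens.** A pluggable MHC-I binding backend (external
   NetMHCpan-style adapter, or a deterministic mock for testing) scores
   every peptide × allele; a peptide passes with IC50 < 500 nM **and**
   percentile rank < 2.0 (both strict, both configurable).

The statistics layer implements shared-neoantigen recurrence (> 2 patients),
peptidome self-dissimilarity (best local BLOSUM62 alignment, gap 11/1,
high-similarity when score > 35), intratumor heterogeneity (subclonal
fraction), Haldane–Anscombe odds ratios and per-patient clonal/subclonal
immunoediting ORs, the logistic depletion model
logit(P) = β₀ + β₁·oncogenic + β₂·affected-aa + β₃·frameshift, and the
burden metrics TNB / SVNB / GANB with the 323-neoantigen high-burden
threshold.

A first-class synthetic-data module (`make_toy_reference()`, `spike_svs()`,
`simulate_cohort()`) builds toy genomes with multi-exon genes on both
strands, plants SVs of every class with analytically known truth (computed
by an independent string-level oracle), and simulates cohorts at known
logistic coefficients and clonality enrichment — the test bed for the whole
pipeline.

## Worked example

```r
library(svneo)

ref <- make_toy_reference(sim_spec(seed = 1), dir = "demo")
sp  <- spike_svs(ref)                      # 23 SVs incl. designed rejects
run <- run_pipeline(run_config(
  vcf = sp$vcf_bnd, gtf = ref$gtf_path, fasta = ref$fasta_path,
  alleles = sp$alleles_path, backend = "always"))   # always-bind mock
print(run)
```

```
svneo pipeline run
  records parsed     23
  canonical junctions 23
  feasible junctions 19
  neo-proteins       18
  candidate peptides 886
  neoantigens        886
  drops by stage/reason:
    windowing   EMPTY_MUTATED_SPAN       2
    filter      INTERGENIC               2
    filter      NO_CODING_EFFECT         1
    assembly    NO_UTR_STRUCTURE         1
    filter      ORIENTATION              1
```

The funnel is conservative: 23 parsed junctions, of which 4 are removed by
the breakpoint filters (intergenic, incompatible orientation, 3'UTR donor),
1 fails assembly (start-codon loss), and 2 in-frame events have junction
residues identical to wild type and so yield no peptides. With the
always-bind mock every filtered peptide becomes a call, which is how the
end-to-end tests compare against the truth set; with a real backend
(`backend = "netmhcpan"`) only binders survive.

```r
head(run$neoantigens[, c("patient", "sv_id", "sequence", "best_allele",
                         "sv_class", "frameshift")], 4)
#   patient              sv_id  sequence best_allele      sv_class frameshift
# 1     P02 del_sg_fs_intronic  VVSPPALS HLA-A*02:01 DELETION_LIKE       TRUE
# 2     P02 del_sg_fs_intronic  VSPPALSR HLA-A*02:01 DELETION_LIKE       TRUE
# 3     P02 del_sg_fs_intronic  SPPALSRV HLA-A*02:01 DELETION_LIKE       TRUE
# 4     P02 del_sg_fs_intronic KVVSPPALS HLA-A*02:01 DELETION_LIKE       TRUE

self_dissimilarity("VVSPPALS", ref$proteome)
# $score 34   $class "LOW"      — no wild-type counterpart above 35
hydrophobic_fraction("VVSPPALS")
# 0.375                         — 3 of 8 residues in {V,I,L,F,M,W,C}
odds_ratio_from_proportions(0.291, 0.569)
# 0.3095                        — oncogenic vs passenger depletion OR (0.31)
burdens(200, 50, 100)
# TNB 250, SVNB 100, GANB 350 (threshold 323): rescued by SV neoantigens
```

The frameshifted 8-mers come from a deletion that skips a 115-nt exon; the
peptide is absent from every wild-type protein (self-dissimilarity LOW), and
the burden example shows a patient who would be missed by TNB alone but
crosses the high-burden threshold once SV neoantigens are counted.

A thin command-line wrapper with `predict`, `simulate`, and `stats`
subcommands is installed under `inst/cli/svneo.R`:

```sh
Rscript inst/cli/svneo.R simulate --seed 5 --out demo/
Rscript inst/cli/svneo.R predict --vcf demo/svs_bnd.vcf \
    --gtf demo/annotation.gtf --fasta demo/genome.fa \
    --alleles demo/alleles.txt --backend mock --seed 5 --out run/
```

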