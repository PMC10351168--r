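---
title: "Predicting MHC class I neoantigens from structural variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MHC class I neoantigens from structural variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svneo)
```

## The problem

Somatic structural variants (SVs) — deletions, duplications, inversions, and
translocations — fuse distant pieces of the genome. When a junction falls
inside genes, the rearranged locus can be transcribed into a chimeric mRNA
and translated into a protein that the patient's immune system has never
seen. Such junction-derived peptides are attractive immunotherapy targets:
frameshifted tails in particular are long stretches of fully novel sequence,
far less similar to self than the single-residue changes produced by point
mutations. Most neoantigen callers operate on SNVs and small indels and
ignore this source entirely. svneo predicts MHC class I neoantigens from
SV breakends and provides the cohort-level statistics used to study their
immunogenomics: recurrence across patients, similarity to the wild-type
peptidome, intratumor heterogeneity, immunoediting odds ratios, a
covariate-adjusted depletion model, and integrated neoantigen burden.

## The junction model

Every SV is reduced to one or two **breakend pairs**. A breakend is a
reference position plus a side-retained flag: `LEFT` means the reference
bases at or before the position survive and are joined at the junction,
`RIGHT` means the bases at or after it survive. The four VCF bracket forms
(`t[p[`, `t]p]`, `]p]t`, `[p[t`) map onto these two flags for each mate, and
symbolic alleles are expanded to the same representation (`<DEL>` joins the
left flank to the right flank; `<DUP>` the reverse; `<INV>` becomes *two*
junctions, head-to-head and tail-to-tail, processed independently). This
makes the orientation semantics identical no matter which mate or dialect a
caller emitted, and it gives a purely geometric SV classification:
on one chromosome, (LEFT, RIGHT) ordered by position is deletion-like,
(RIGHT, LEFT) duplication-like, (LEFT, LEFT) a head-to-head inversion
junction, (RIGHT, RIGHT) tail-to-tail; junctions across chromosomes are
translocations.

Internally all intervals are 0-based half-open; the 1-based inclusive
conventions of VCF and GTF are converted exactly once, at the I/O boundary.
This keeps the splicing arithmetic free of off-by-one ambiguity.

## Candidate filters

A junction can only change a protein if transcription can run continuously
across it. Each breakend is mapped onto the transcript annotation; for genes
with several isoforms the one with the longest coding region is used
throughout (ties break to the lexicographically smallest transcript id, so
results are reproducible across annotation orderings). Two filters follow:

* **Intergenic**: junctions with a breakend outside any coding gene are
  removed. The strict form (either end intergenic) is the default; a
  configuration switch (`allow_one_intergenic`) keeps junctions whose genic
  end can act as donor, modelling read-through into intergenic sequence.
* **Orientation**: there must exist an assignment of donor (5' part) and
  acceptor (3' part) roles such that the donor's retained side contains its
  transcript's promoter and the acceptor's retained side contains its
  transcript's 3' remainder. For a plus-strand gene the promoter side is
  LEFT and the tail side RIGHT; for a minus-strand gene the reverse. Both
  role assignments are enumerated; if neither works the junction cannot
  produce a transcript and is rejected. A donor breakend in the 3'UTR
  passes the geometry but cannot alter the coding sequence and is rejected
  separately (`NO_CODING_EFFECT`). When both assignments are valid the
  first in a fixed order (first listed breakend as donor) is taken, so the
  outcome is deterministic.

## Neo-transcript assembly and translation

The chimeric mRNA is the donor transcript's spliced sequence from its
transcription start to the breakend, concatenated with the acceptor
transcript's spliced sequence from the breakend to its 3' end. Exonic
breakends truncate the exon at the retained base, producing junction-derived
codons; intronic breakends splice at the nearest complete exon boundary on
the retained side — the donor's 5' splice site joined to the acceptor's 3'
splice site, the standard convention for fusion transcripts. Splice-site
destruction by breakends within a few nucleotides of an exon boundary is
deliberately not modelled. Products that lack the donor's intact 5'UTR and
start codon, or any 3' sequence, are rejected (`NO_UTR_STRUCTURE`).

Translation starts at the donor's annotated start codon and proceeds by the
standard codon table until the first stop codon (`STOP`) or, if none occurs,
the 3' boundary of the transcript (`READ_THROUGH`, with any trailing
incomplete codon discarded). Read-through products are labelled, not
dropped: a junction that removes the stop codon can translate into the
3'UTR. Codons containing ambiguous bases translate to `X`, and any peptide
window containing `X` is excluded downstream, since binding predictors
reject non-standard residues. Start-loss events can optionally be rescued
from the first downstream ATG (`start_rescue`), but rescued proteins are
excluded from neoantigen calling by default (`include_start_rescued =
FALSE`) because the true translation start of such products is uncertain.

**Frame.** The junction is in frame when the donor's retained coding length
modulo 3 equals the native codon phase of the first acceptor-derived coding
base in its own wild-type transcript, counting any acceptor 5'UTR remainder
toward the chimeric frame. Acceptor sequence with no native coding context
(3'UTR tails, intergenic read-through) is frameshifted by definition. The
test suite verifies this arithmetic against the string-level definition: a
frameshifted acceptor region diverges from the acceptor's wild-type protein,
an in-frame one reappears in it.

**Mutated span.** The neo-protein is compared with the donor's wild-type
protein. For frameshift, two-gene, and read-through events everything from
the first differing residue to the end is mutated. For in-frame single-gene
events only the junction window that actually differs is kept (common
prefix and suffix removed); an in-frame deletion whose junction residues
happen to be identical to wild type has an empty span and correctly yields
zero neo-peptides rather than an error.

## Peptides and neoantigen calls

All 8–11-mer windows of the neo-protein that overlap the mutated span by at
least one residue are candidates. Self peptides are then removed: by
default a candidate is discarded if it occurs as an exact substring of
*any* wild-type protein in the annotation proteome (longest-CDS isoform per
gene), the conservative reading of "at least one non-self residue"; a
parents-only mode restricts the comparison to the two genes forming the
junction. The filter is idempotent and its output is provably disjoint from
the proteome's substring set. Per-patient duplicate peptides are collapsed
with their SV provenance merged, so cohort recurrence counts patients, not
records.

Binding is delegated to a pluggable backend. The external adapter drives a
NetMHCpan-style binary in batch and maps its tabular output back to the
query positionally, refusing partial output. For testing and CI the package
ships a deterministic mock that hashes (peptide, allele, seed) to a uniform
IC50 in [1, 50000] nM and a percentile rank in [0, 100], plus always-bind
and never-bind modes; with the always-bind mode the neoantigen set equals
the filtered peptide set, which is what the end-to-end tests exploit. A
peptide is called a neoantigen when at least one allele call has IC50 below
500 nM **and** rank below 2.0, both strict inequalities; the two thresholds
are combined with AND as the conservative reading, and both are
configurable. Binding stability is adapter-only (an external
NetMHCstabPan-style binary or a seeded mock); no stability model is
implemented here.

## Cohort statistics

* **Recurrence** counts distinct patients per peptide sequence; a peptide
  seen in more than two patients is recurrent.
* **Self-dissimilarity** scores each peptide against the wild-type
  peptidome by local (Smith–Waterman) alignment under BLOSUM62 with gap
  open 11 / extend 1 — the substitution model and penalties of standard
  protein BLAST, whose raw alignment score the threshold refers to. A
  peptide whose best counterpart scores strictly above 35 is
  "high-similarity". The peptidome can be held as full proteins (default;
  cheaper) or as the explicit 8–11-mer set; for local alignment of short
  queries the two give identical maxima, and a test asserts the
  equivalence.
* **Intratumor heterogeneity** is the fraction of a patient's neoantigens
  arising from subclonal SVs, with unlabelled records excluded.
* **Immunoediting odds ratios** use the Haldane–Anscombe correction: when
  any cell of the 2×2 table is zero, 0.5 is added to all four cells, the
  standard form of the correction. Per-patient clonal/subclonal ORs are
  computed for patients with at least one SV of each clonality class, and
  the cohort median log-OR is tested against zero with the Wilcoxon
  signed-rank procedure (exact distribution below n = 25, normal
  approximation above).
* **The depletion model** is the logistic regression
  logit(P) = b0 + b1·X1 + b2·X2 + b3·X3, where P is the probability that an
  SV generates a neoantigen, X1 indicates an oncogenic SV, X2 is the number
  of affected amino acids, and X3 indicates a frameshift. X2 is
  operationalized as the length of the mutated span, the natural measure of
  how much novel protein an SV exposes. The fit is maximum likelihood by
  iteratively reweighted least squares (tolerance 1e-8, at most 100
  iterations) with standard errors from the observed information and a Wald
  test for b1, the oncogenic-depletion coefficient. Non-varying covariates
  are dropped and reported as zero. Perfect separation — detected from the
  fitted probabilities and from runaway coefficient magnitudes — marks the
  fit non-converged and its coefficients unreliable.
* **Burdens**: TNB is the SNV+indel neoantigen count (consumed as
  precomputed inputs; calling SNV/indel neoantigens is out of scope), SVNB
  the SV-derived count, GANB their sum. Classification uses a high-burden
  threshold of 323 neoantigens per exome (strict `>`); a patient is
  "rescued" when TNB is at or below the threshold but GANB exceeds it —
  the patients whose immunotherapy eligibility changes once SV neoantigens
  are counted.

## The synthetic test bed

`make_toy_reference()` builds a two-chromosome genome with eight multi-exon
coding genes on both strands. Exon and intron lengths are fixed by design
(exons roughly 110–160 nt, introns 80–120 nt) so that exhaustive oracles run
in milliseconds, while sequence content is drawn from the seed — the same
seed reproduces byte-identical FASTA/GTF/VCF. Every CDS starts with ATG,
contains no in-frame stop, and is followed by a stop codon at the start of
the 3'UTR (Ensembl-style CDS annotation, stop excluded). One gene carries a
3'UTR tail of pure GGC repeats, which contains no stop codon in any reading
frame and guarantees a read-through product when a junction removes the
stop.

`spike_svs()` plants 23 SVs: every junction class, each with in-frame and
frameshift variants where the geometry permits, in single-gene and two-gene
contexts, plus designed rejects (both-intergenic, one-intergenic,
orientation-incompatible, 3'UTR donor, start-codon loss) and the
read-through case. Exonic spikes choose their breakpoints by coding phase,
so frame intent is satisfied by construction; impossible intents raise an
error naming the constraint. The same junction set is written in two VCF
dialects — pure bracket-BND, and symbolic `<DEL>`/`<DUP>` records mixed with
BND for the junction types symbolic alleles cannot express — to harden the
parser; a test requires identical neoantigen output from both.

Expected outcomes are computed by a **naive truth oracle** that shares no
code with the pipeline: it re-reads the written FASTA/GTF/VCF with its own
minimal parsers, splices by plain substring arithmetic, translates with its
own codon map, windows peptides by exhaustive enumeration, and filters self
peptides with its own substring scan. End-to-end tests then require the
pipeline (always-bind mock) to reproduce every truth record exactly —
feasibility or reject reason, frameshift flag, protein sequence, mutated
span, and the full non-self peptide set — and the same comparison is run on
100 random junctions per session.

`simulate_cohort()` draws per-SV covariates and outcomes from the logistic
model at chosen true coefficients — defaults b = (−1.0, −1.2, 0.01, 1.5)
over 200 patients with 40–80 SVs each, X2 Poisson with mean 20 — and
assigns clonality so that the odds of being subclonal differ between
neoantigenic and non-neoantigenic SVs by a chosen true enrichment OR
(default 2.0 over a baseline subclonal probability of 0.4). Parameter-
recovery tests fit the first 5000 rows and require every coefficient within
three standard errors of truth, and the cohort median per-patient OR close
to the true enrichment.

What the generator does **not** emulate: realistic SV size and frequency
distributions, sequencing noise or breakpoint uncertainty, micro-homology
at junctions, splice-site disruption, expression and proteasomal
processing, and real MHC binding affinities (the mock's scores are uniform
hashes). Passing tests therefore demonstrate that the junction arithmetic,
translation, windowing, filtering, and statistics are implemented exactly
as specified — not that predictions on real tumors are accurate, which
additionally depends on the external binding predictor and the quality of
the SV calls and annotation.

## Numerical and design choices

* Problem sizes in the tests — 23 spiked plus 100 random junctions on a
  ~7 kb genome, 200 windowing cases, one cohort of 200 patients with a
  5000-row logistic fit — keep the whole suite under a couple of minutes on
  one core while leaving every check exhaustive rather than sampled.
* Coordinates: 0-based half-open internally; conversions only at I/O.
* Tie-breaks are all lexicographic (isoform selection, overlapping genes),
  making every run order-independent.
* Breakends exactly on an exon boundary take the region of the retained
  base (a LEFT breakend at an exon's last base is exonic).
* The duplication-like junction models the junction-containing transcript
  (donor = the copy ending at the downstream breakend, acceptor = the copy
  starting at the upstream one), which captures every novel peptide of a
  tandem duplication without enumerating the full repeated mRNA.
* Micro-homology/insertion sequence in bracket ALTs is retained as metadata
  but ignored for coordinates: the method uses breakpoint positions and
  orientations only.
* `<TRA>` records require a connection-type (`CT`) INFO key; without it the
  orientation is unknowable and the record is rejected rather than guessed.
* The mock backend's hash is plain 32-bit-safe double arithmetic, so its
  calls are bit-identical across platforms and R versions.
* The per-patient OR correction triggers on any zero cell (not only the
  zero cell itself), the standard form; the signed-rank test switches from
  the exact to the normal distribution at n = 25.

## Limitations

Only the longest-CDS isoform per gene is analysed; alternative isoforms and
RNA-guided isoform selection are out of scope. Complex multi-junction
events (chromothripsis chains) are treated junction by junction.
Copy-number context, expression filtering, and nonsense-mediated decay are
not modelled. MHC binding and stability come entirely from external
predictors; the package's mock exists to make the surrounding machinery
testable, and its scores carry no biology.
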