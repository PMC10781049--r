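---
title: "Tracing donor introgressions and their expression markers: methods"
author: "introtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing donor introgressions and their expression markers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introtrace)
```

## The problem

A backcross breeding programme crosses a donor parent carrying a target
trait into an elite recurrent parent, then repeatedly backcrosses the
offspring to the recurrent parent and finishes with several selfing
generations. The derived inbred line is a mosaic: most of its genome comes
from the recurrent parent, with donor-origin segments retained where the
trait locus (and whatever was linked or unselected) survived. Two questions
follow. Which genes did the line inherit from the donor? And which of those
genes show an expression pattern that tracks the donor allele — the
candidates for cheap DNA markers of the trait?

`introtrace` answers both from standard inputs: a trio of variant calls
(line plus both parents against one reference), a GFF3 gene annotation, the
reference FASTA, and a gene-level count matrix from an inoculation
experiment with a `genotype x treatment x replicate` design.

## Variant-origin classification

Every biallelic site with homozygous genotypes for the three roles is
labelled by two comparisons:

* `DONOR` — offspring shares the donor allele and that allele differs from
  the recurrent parent;
* `RECURRENT` — the mirrored case;
* `NON_POLYMORPHIC` — all three agree;
* `NOVEL` — both parents agree but the offspring differs (mutation or
  artefact; never used as evidence);
* `AMBIGUOUS` — any genotype missing.

The lines under study are inbred, so heterozygous calls are residual noise:
the default policy maps them to missing (hence ambiguous); an alternative
`major-allele` policy collapses a diploid 0/1 tie to the non-reference
allele. Multi-allelic records are split into biallelic sites against the
same REF; a sample carrying a third allele at a split site is missing
there. Indels are measured by the absolute REF/ALT length difference and
only lengths 1–99 bp are analysed; longer events are closer to structural
variation and are filtered with a logged count.

Variant coordinates stay 1-based (VCF convention) throughout; conversion to
half-open intervals happens only inside the interval index. Deletions are
anchored at their leftmost deleted base (VCF POS + 1), insertions at POS.

## Gene structural parts and coding effects

A gene is considered in the broad sense: coding exons, introns, 5′ and 3′
UTRs, and a putative promoter window of 1000 bp (configurable) upstream of
the ORF start — anchored at the CDS, not the transcript start, because the
promoter of interest sits upstream of the translated region. Windows are
strand-aware and clipped at contig boundaries. When a position satisfies
several definitions for one gene, the most specific functional context
wins: coding exon > UTR > intron > upstream window. Genes overlapping on
opposite strands each receive the variant; no evidence is discarded.

Coding effects are computed only for well-formed gene models (total CDS
length divisible by 3; others are flagged and skipped with a warning). SNVs
are translated through the standard genetic code, strand-aware, giving
`SYNONYMOUS` or `NONSYNONYMOUS`; CDS indels are `INFRAME_INDEL` when their
length is a multiple of 3 and `FRAMESHIFT` otherwise. Every REF string is
checked against the FASTA and a mismatch aborts with the offending
coordinate. Mobile-element and unknown-protein genes (GFF3 attributes) are
removed before gene-level aggregation, as their high mutation rates make
origin evidence unreliable.

## Gene-level verdicts and the donor fraction

A gene's verdict aggregates its classified variants (donor/recurrent
evidence only): `DONOR` with at least one donor variant and none recurrent,
`RECURRENT` mirrored, `MIXED` with both (a breakpoint inside the gene's
evidence span), `NON_POLYMORPHIC` with neither. One concordant variant
suffices by default; `min_evidence` raises the bar. Genes carrying both SNV
and indel evidence are counted once, with the overlap reported.

The donor-inherited fraction is the two-term ratio
`100 * N_donor / (N_donor + N_recurrent)`, reported to one decimal; mixed
and non-polymorphic genes appear in the verdict counts but not in the
ratio, whose terms are disjoint donor and recurrent gene sets. The
per-chromosome table reports donor-gene counts and whole-percent shares of
each chromosome's genes, plus a BED graphical genotype of consecutive
donor-gene runs.

The package also evaluates the expected donor fraction after `b`
backcrosses. The conventional pedigree expectation is `(1/2)^(b+1)` (the F1
already halves the donor genome). A widely quoted shorthand halves once per
backcross only, `(1/2)^b`, giving "about 3%" after five backcrosses instead
of 1.5625%. `expected_backcross_fraction()` implements the shorthand as its
default (`model = "halving"`) to match the emulated study's printed
arithmetic and offers `model = "pedigree"` for the standard form; the
discrepancy is deliberate and documented here. The simulator itself is
validated against the standard closed form by Monte-Carlo.

## Differential expression

Counts are TPM-normalized (`1e6 * (c/L) / sum(c/L)`) for filtering and
display. A gene is dropped only when it stays below 10 TPM in *every*
sample — the max-across-samples reading; dropping genes expressed in even
one sample would discard exactly the treatment-induced genes the analysis
is after.

Testing is per genotype, inoculated vs control, with an in-package
negative-binomial Wald test:

* size factors by the median-of-ratios method;
* per-gene NB dispersion by method of moments on normalized counts, with
  the within-group variance pooled across **all** (genotype, treatment)
  groups of the design. Dispersion is a property of the measurement
  process, so every group informs it — the same sharing DESeq2 and edgeR
  rely on. With three replicates per group the per-contrast estimate alone
  (4 residual df) is too noisy; pooling the study design gives 12.
  Estimates are floored at 1e-8;
* group means by Newton iteration under a log link with size-factor
  offsets; the Wald statistic uses the observed-information standard
  error;
* the statistic is referred to a **t distribution with the pooled residual
  df** rather than the normal. This is a deliberate small-sample
  correction: in null simulations (2000 genes, 3v3, dispersion 0.1) the
  normal reference rejected at 0.12 instead of 0.05, while the t reference
  held 0.047–0.05. Trended or shrunken dispersion with a normal reference
  was also examined and rejected (type-I 0.075–0.10);
* Benjamini–Hochberg adjustment across the tested genes within each
  genotype, mirroring per-genotype DEG reporting; `UP`/`DOWN` require
  adjusted p below `alpha` (default 0.05) with the matching fold-change
  sign.

Genes with all-zero counts in a contrast get `NA` p-values and `NS` status.
The log2 pseudo-count for display transforms is 1. Group-averaged,
z-scored log2(TPM+1) matrices are emitted for heatmaps; constant rows
become zero rows and are flagged rather than producing NaNs.

Cross-genotype response patterns partition the up-regulated sets into the
seven Venn regions. The donor-like pattern — up-regulated in offspring and
donor, **not significant** in the recurrent parent — is the permissive
reading: a nominal upward trend in the recurrent parent does not
disqualify a gene, only a significant call does.

## ASE marker candidates

Candidates are donor-like genes whose origin verdict is `DONOR` (or `MIXED`
with at least one donor-origin promoter-region variant). The `cis_flag`
marks the marker-ready shape: at least one donor-origin variant in the
upstream window or a UTR, and *no* donor-origin coding-altering variant
(non-synonymous, in-frame indel or frameshift; synonymous changes are
tolerated — "identical protein" is read at the amino-acid level). The
longest donor-origin upstream indel is reported as the promoter-insertion
length, and a per-candidate report lists every donor variant with its
strand-aware distance to the ORF start (negative = upstream). Candidates
are ordered by offspring adjusted p, ties by gene id, so output is
deterministic.

## The synthetic study

`simulate_trio_study()` builds everything the pipeline consumes, with truth
sidecars:

* **Genome/annotation.** Seven chromosomes of 1 Mb / 100 cM and ~210 genes
  by default — desk-scale, while preserving per-chromosome reporting.
  Genes have 1–4 coding exons (CDS of 60–300 codons with valid start/stop
  and no internal stops), UTRs, introns, and non-overlapping territories
  that reserve the promoter window on both flanks, so each simulated
  variant belongs to at most one gene (the analysis code itself handles
  overlapping genes; the generator simply never creates ambiguous truth).
  15% of genes are flagged mobile-element and 10% unknown-protein.
* **Pedigree.** Meiosis under the Haldane model: Poisson crossover counts
  (`length_cM/100` expected per chromosome), uniform positions, no
  interference; one offspring carried forward per generation; five
  backcrosses then four selfings by default. The derived line is treated
  as fixed: one haplotype of the final individual is the line mosaic, and
  all emitted genotypes are homozygous (inbred pea; residual
  heterozygosity is available only as the ambiguous-call policy's error
  mode).
* **Selection guarantee.** The real programme selected phenotypically for
  the trait, so the causal locus survives backcrossing by construction.
  The simulator mirrors this: if a pedigree draw retains no fully-donor
  unflagged gene, the mosaic region covering one randomly chosen gene is
  converted to donor origin *before* any truth quantity is computed. After
  five backcrosses the whole-genome donor retention is often zero at this
  genome size, so the guarantee matters.
* **Variants.** Per-gene SNV/indel placement across upstream/UTR/intron/
  exon strata (weights 0.45/0.15/0.25/0.15), donor- or recurrent-polarized
  at random, plus small fractions of trio-non-polymorphic (5%) and novel
  (2%) sites and intergenic background. Indel lengths are uniform on
  1–120 bp so the 99-bp analysis filter is genuinely exercised. The cis
  gene gets a donor-only 9-bp insertion 300 bp upstream of its ORF, no
  coding-region variants, and SNV-only background markers, making the
  planted insertion its single promoter indel. A `dense` mode adds a
  300-bp grid of distinguishing SNVs plus flanking markers on each side of
  every mosaic breakpoint inside a gene span, which makes marker evidence
  resolve every gene origin exactly.
* **Counts.** NB counts (dispersion 0.1) in the 3 genotypes x 2 treatments
  x 3 replicates design, log-normal baselines, library-size factors
  uniform on 0.7–1.3. Ten percent of genes are commonly
  inoculation-responsive at log2FC 3 (a strong induction typical of
  symbiosis-responsive genes), eight repressed at −2, four private
  responders per genotype, and the cis gene induced at log2FC 5 only in
  the genotypes carrying the donor promoter allele (offspring and donor).

Truth is recorded at three levels: per-site origin labels, per-gene origin
both span-based (the mosaic label over the gene + upstream evidence span,
`MIXED` when a breakpoint falls inside) and marker-aware (aggregate of
placed distinguishing sites), and summary donor fractions (bp-weighted,
gene-weighted, marker-weighted). Under dense markers the pipeline's
gene-weighted estimate equals the span-based truth exactly; under sparse
defaults it tracks within a couple of percentage points, the residual
coming from genes that drew no marker or straddle a breakpoint with
one-sided evidence.

What the generator does **not** emulate: sequencing error and genotype
likelihoods, mapping bias, read-level data, selection during breeding
beyond the single-locus guarantee, linkage between the cis gene's
expression and any phenotype, and 3′-biased count artefacts. Passing tests
therefore demonstrate correctness of the analysis logic under clean calls,
not robustness to upstream calling noise.

## Numerical and reporting choices

* Donor fraction to one decimal; per-chromosome percentages to whole
  percent; floats in reports to six significant digits.
* Identical seed and configuration give byte-identical outputs; input
  paths inside the output directory are echoed relative to it so reports
  from different directories stay comparable.
* Newton iterations for NB means are clamped at 1e-10 and run a fixed 15
  steps (monotone in practice; a fixed count keeps runs deterministic).
* Validation distinguishes hard errors (unparseable input, chromosome-name
  mismatch across files, design/matrix inconsistencies) from warnings;
  the pipeline aborts on hard errors only.

## Problem sizes used in the shipped checks

The test-suite property checks run at deliberately modest scale: 10,000
gametes for the meiosis expectation, 400 pedigree replicates for the BC5
closed form, 20 seeded studies for donor-fraction recovery and for cis
candidate uniqueness, 2000-gene null and planted-effect matrices for DE
calibration, and a single >= 10^4-site study for classification
round-trips. These sizes give comfortable Monte-Carlo margins for the
assertions made while keeping a full run in minutes.

## Known limitations

* The NB test is a two-group Wald per genotype; no interaction model, no
  shrinkage of fold-changes, no outlier refitting. Exact parity with
  DESeq2 is out of scope by design.
* One gene model per gene: no isoforms, no splice-site effect classes, no
  start/stop-loss subcategories.
* The donor fraction weights every gene equally; it is a gene-count
  statistic, not a physical-length estimate (the bp-weighted truth is
  reported alongside in simulations).
* Residual heterozygosity is handled as a calling policy, not modelled in
  the pedigree.
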