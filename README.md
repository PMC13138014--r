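# imputeref

Reads that carry non-reference alleles align worse to a single linear
reference genome than reads that match it — *reference bias*. A remedy
is to personalize the reference before the expensive analysis begins:
genotype the donor roughly from a cheap, low-coverage sample of reads,
let a haplotype panel impute and phase a complete diploid call set from
those rough genotypes, substitute the calls into the reference to get
two personalized haplotype sequences, align the full read set against
them, and lift the alignments back to reference coordinates for
standard downstream tooling.

`imputeref` implements that impute-first workflow end to end for R
users, together with the evaluation statistics needed to judge it. It
is aimed at method developers and teaching settings: every stage runs
on synthetic diploid data generated inside the package, so the whole
workflow is exercisable on a laptop in seconds without external
references, panels or aligners.

## What the package computes

**Personalization.** A pileup-based genotype caller assigns each
covered site the maximum-likelihood diploid genotype under a symmetric
binomial read-sampling model: with per-read error rate *e*, a read
shows the ALT allele with probability *e*, ½, or 1−*e* under genotypes
0/0, 0/1, 1/1, and the call's QUAL is the Phred-scaled posterior error
under a flat prior. Calls are filtered (QUAL ≥ 20, DP ≤ 100 by
default) and handed to the imputer, which scores every ordered pair of
panel haplotypes per chunk of sites by qual-weighted agreement with
the rough genotype dosages and stitches chunks by junction-flank
agreement. The winning pair *is* the phased diploid call set.

**Consensus and chains.** `buildDiploidReference()` substitutes each
haplotype's alleles into the reference and emits a UCSC-dialect chain
per haplotype. SNVs stay inside match blocks (chains encode coordinate
shifts, not sequence identity); an edit replacing *d* reference bases
with *r* haplotype bases contributes gaps `dt = d`, `dq = r`.

**Liftover and reconciliation.** `liftAlignments()` rewrites CIGARs
through a chain — haplotype-only bases covered by a read become `I`
operations, spanned reference-only bases become `D` — conserving the
query length of every record; `reconcileAlignments()` picks the best
candidate per read by mapping quality, then alignment score, then
source label.

**Evaluation.** Allele-level confusion counts treat each diploid call
as two allele calls (Precision = TP/(TP+FP), Recall = TP/(TP+FN));
HET-level counts score sites. Pivot-window accuracy asks, for the
200 bp window ending at each polymorphic site, whether every member
site is correctly genotyped *and* phased under one consistent
haplotype labelling, stratified by window density (1–5, 6–10, 11+
sites). Allelic balance at a HET site is ALT/(ALT+REF) over
informative overlapping reads, summarized in allele-length bins
(mean, 25th/75th percentiles); 0.5 means no bias.

## Worked example

```r
library(imputeref)

cfg <- simConfig(refLength = 20000L, nSnv = 60L, nIndel = 20L, nSv = 2L,
                 hetFraction = 0.6, coverage = 20, seed = 1L)
simulateTruth(cfg)
#> TruthSample on ref (20000 bp): 82 variants, 49 HET
#>   hap lengths: 19987 / 19857

res <- runPipeline(list(
  outDir = file.path(tempdir(), "demo"), seed = 1L,
  sim = list(refLength = 20000L, nSnv = 60L, nIndel = 20L, nSv = 2L,
             hetFraction = 0.6, coverage = 20),
  personalization = list(subsampleFraction = 0.25)))

res$prf
#>    level precision recall f1
#> 1 allele         1      1  1
#> 2    het         1      1  1

res$windowAccuracy
#>   stratum nWindows nCorrect accuracy callset
#> 1     1-5       82       82 1.000000 imputed
#> 4     1-5       82       66 0.804878   rough
#> ...

mean(abs(res$balancePersonalized$balance - 0.5), na.rm = TRUE)  # 0.066
mean(abs(res$balanceLinear$balance - 0.5), na.rm = TRUE)        # 0.198
```

The run simulates a 20 kb diploid sample (82 variants, 49 of them
heterozygous), subsamples the 20× read set to 5× for rough genotyping,
imputes against a 20-haplotype panel, builds the personalized diploid
reference, lifts and reconciles the full read set, and evaluates.
Imputation lifts window accuracy from 0.80 (rough calls alone) to 1.00
here, and the personalized reference brings the mean allelic-balance
deviation at HET sites from 0.198 down to 0.066 — the reference-bias
reduction the workflow exists for. Each stage writes its outputs and a
JSON manifest under `outDir`; `run.log` records per-stage timing and
record counts.

A command-line wrapper for the individual stages lives in
`inst/scripts/imputeref.R` (`run`, `simulate`, `genotype`, `impute`,
`personalize`, `lift`, `reconcile`).

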