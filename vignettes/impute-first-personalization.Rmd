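---
title: "Impute-first personalization: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impute-first personalization: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputeref)
```

This vignette is the package's own account of the science it
implements: the models behind each stage, the parameters that matter
and why their defaults are what they are, what the synthetic data
generator does and does not emulate, and the places where the design
was genuinely open and a choice had to be made.

## The problem

Aligning reads to a single linear reference penalizes reads that carry
the donor's non-reference alleles, especially around indels: such
reads accumulate mismatches or clipped bases, mis-place, or drop out.
The downstream symptom is skewed allele counts at heterozygous sites
(allelic balance below 0.5) and degraded variant calls. The
impute-first idea is to spend a small amount of sequencing first:
genotype the donor roughly from low coverage, let a haplotype panel's
linkage structure fill in and phase the rest, and then align the full
read set to the resulting personalized diploid reference instead of
the generic one. Rough genotypes are not trustworthy by themselves;
the bet — which the evaluation stages of this package are designed to
measure — is that they carry enough signal for panel-based imputation
to reconstruct the donor's haplotypes accurately.

## Stage models

### Rough genotyping

`pileupFromAlignments()` walks each CIGAR: aligned (`M`) bases
contribute the read base at the reference position; insertions and
deletions contribute a single token (`+SEQ` / `-SEQ`) anchored at the
preceding reference base, VCF-style, replacing that read's base
contribution at the anchor so that total contributions equal total
aligned bases exactly. Soft clips contribute nothing.

`callRoughGenotypes()` is deliberately the simplest defensible caller:
the diploid genotype likelihoods under a symmetric binomial model with
per-read error rate $e$ are

$$L(g) = \binom{n}{k} p_g^k (1-p_g)^{n-k},\qquad
  p_{0/0} = e,\; p_{0/1} = \tfrac12,\; p_{1/1} = 1 - e,$$

with $k$ ALT-supporting and $n$ informative reads. QUAL is the
Phred-scaled posterior error under a flat prior, capped at 99 to avoid
infinities at high depth. The caller exists to feed the imputer and to
be replaceable: any external caller can be substituted through the VCF
interface. Filtering retains `qual >= 20` and `depth <= 100` — the
boundary semantics are strict ("below 20" excluded, "exceeding 100"
excluded), so QUAL 20 and DP 100 both pass. The filter reads the
record-level quality column and documents that choice.

### Imputation

The built-in imputer is an exhaustive haplotype-pair search, not a
Li–Stephens model: panels at the package's scale are tens of
haplotypes, where $O(H^2 S)$ scoring is instantaneous and exact. Sites
are processed in chunks (default 100 sites); within a chunk every
ordered pair of *distinct* panel rows is scored by
$\sum_s w_s\,[\,\{a_s, b_s\} = \{g_{1s}, g_{2s}\}\,]$, where the
weight $w_s = \min(\mathrm{QUAL}_s, 50)$ caps the influence of any one
overconfident rough call and genotypes agree as multisets (dosage
equality, for biallelic sites). Ties break to the lowest row-index
pair, making the no-information case deterministic. Adjacent chunks
are stitched by keeping or swapping the new chunk's labels, whichever
agrees better over the ten sites flanking each side of the junction —
a miniature of the chunk/ligate/phase structure of production
imputation engines, which remain out of scope and pluggable through
`runExternalImputer()`'s `{rough}`/`{panel}`/`{out}` adapter contract.

Panel hygiene is implemented exactly: `excludeSamples()` removes both
haplotype rows of each excluded sample id before imputation, because a
panel containing the donor (or family) yields unrealistically accurate
self-imputation. Family membership is supplied explicitly; the package
never infers relatedness.

### Consensus and chains

`planEdits()` normalizes each applied call by stripping the common
REF/ALT prefix (the VCF anchor base), so insertions become
zero-length-interval edits, deletions pure removals, and SNVs
same-length substitutions. `applyEdits()` splices the haplotype and
builds the chain in one pass. Two conventions matter:

* **Chain direction.** Chains map haplotype (source) to reference
  (target), because the downstream operation is lifting alignments
  *back* to reference coordinates. The inverse is available through
  `invertChain()`.
* **SNVs produce no chain gap.** Chains encode coordinate shifts, not
  sequence identity, so same-length substitutions stay inside match
  blocks. A consequence used by the test suite: for indel-only call
  sets, every match block pairs byte-identical substrings.

Coordinates are 1-based internally (the R/Bioconductor idiom); emitted
chain files use the UCSC 0-based half-open dialect and SAM/VCF their
standard 1-based forms.

Overlapping records are resolved leftmost-wins, with a warning. This
is a documented substitute for upstream normalization, not an inferred
intent: production pipelines normalize their VCFs before consensus,
and a deterministic, auditable rule is preferable to silent behavior.
Symbolic ALTs (`<DEL>` etc.) are rejected; only sequence-resolved
alleles are applied.

### Liftover and reconciliation

`liftAlignments()` rewrites each record through the chain's per-base
provenance map: read bases over haplotype-only sequence become `I`
operations, reference bases skipped between consecutive mapped read
bases become `D`, and the query-consuming length is asserted unchanged
for every record. Reads that lie entirely inside a haplotype insertion
cannot be expressed in reference coordinates; they are emitted as
unmapped records with reason `fully-inside-insertion` rather than
dropped, so read counts stay auditable end to end. Reads partially
overlapping an insertion edge keep their inserted bases as `I` rather
than being clipped — preserving exactly the evidence the
allelic-balance statistics need at variant loci.

`reconcileAlignments()` orders candidates by mapping quality, then
alignment score, then source label (`hap1 < hap2 < rescue`). The two
quality criteria are applied in that order; since a tie-break must be
fixed for determinism, label order — with the first haplotype first —
is the final key, and the output is invariant to candidate input
order.

### Evaluation statistics

*Allele-level confusion*: each called diploid genotype contributes two
allele calls. ALT call with ≥1 true ALT → TP; ALT call against
homozygous-REF truth → FP; REF call with ≥1 true REF → TN; REF call
against homozygous-ALT truth → FN. Totals are forced to
$2\times|\text{sites}|$, and the HET-level analogue to
$|\text{sites}|$; both identities are asserted on every run.

*Site universe*: evaluation runs over the panel's polymorphic sites,
with calls or truth missing at a site closed as homozygous REF — the
only closure that keeps the accounting total fixed.

*Pivot windows*: one window per polymorphic site, containing the pivot
and all sites within 200 bp to its left; strata "1–5", "6–10", "11+"
by member count. A window is correct when a single label assignment
(identity or swap) applied across the whole window reproduces truth at
every member site. Haplotype labels are globally arbitrary, and
whether the orientation should be fixed globally or per window is a
genuine ambiguity; per-window assignment is implemented and flagged
here, as the window-local reading of "correctly genotyped and
correctly phased".

*Allelic balance*: read classification at a HET site is a direct
base/CIGAR comparison — SNVs by the aligned base, indels by presence
or absence of the exact gap operation at the locus, requiring the read
to span the variant interval; anything else is uninformative and
excluded from the denominator. This is a simplified substitute for
context-aware read-assignment algorithms, adequate for the synthetic
setting where alignments are exact. Length bins clamp
$\mathrm{len}(ALT)-\mathrm{len}(REF)$ to $[-30, 30]$; percentiles use
linear interpolation between order statistics (quantile type 7) so
outputs are bit-reproducible.

*ROC tables*: thresholds sweep the QUAL field; rows report TP/FP/FN
plus precision and recall. A false-positive *rate* would need a
negative-site universe that is not well defined here, so the table
exposes counts and leaves any FPR axis to the caller; recall doubles
as TPR.

## The synthetic data generator

The generator's defaults define the package's study conditions: a
20 kb contig, 60 SNVs + 20 indels (≤ 10 bp) + 2 SVs (≥ 50 bp,
the conventional SV threshold), 60% of variants heterozygous, a
20-haplotype panel at 2% per-site discordance and $10^{-5}$ per-base
recombination switch rate, and 30× per-haplotype coverage of 100 bp
single-end reads at a 0.2% substitution error rate. These are desk-
scale stand-ins for human WGS conditions (tens of millions of panel
sites, 30× coverage, HGSVC/HPRC-scale panels): variant density is a
few per kilobase so that pivot windows populate all strata at small
cost, and the panel's first two haplotypes source deterministically
from the two truth haplotypes so that recovery limits are testable.

`coverage` means fold coverage of *each* haplotype: the read count is
Poisson with mean `coverage * (|hap1| + |hap2|) / readLength`, reads
drawn from the two haplotypes pooled in proportion to length, so
sequenced bases total `coverage` × diploid genome size and each
haplotype is covered `coverage`-fold in expectation.

What the simulator does *not* emulate, and what passing tests
therefore do not show about real data: sequencing-technology error
profiles (errors are uniform substitutions; no quality-score
structure, no indel errors), paired-end structure, mapping ambiguity
from repeats (truth alignments are exact by construction), structural
variation beyond clean insertions/deletions, multiallelic or nested
records, and population structure in the panel beyond a two-haplotype
mosaic process. Conclusions about real reference-bias magnitudes or
real imputation accuracy require real aligners, real panels and real
error models; what the synthetic path validates is the *correctness*
of the bookkeeping (consensus, chains, liftover, accounting) and the
*direction* of the workflow's effects.

### The bare-reference baseline

The package contains no read aligner, by design: alignment algorithms
are external, consumed via SAM. Both arms of the reference-bias
comparison therefore use the same idealized exact-placement model.
Against the personalized diploid reference, reads place exactly on
their source haplotype and the chains re-express them in reference
coordinates, gap operations included. Against the bare linear
reference, `projectReadsUngapped()` places each read at the better of
its left- or right-anchored projected position with an all-match
CIGAR — a gap-unaware placement that keeps the read's bases but loses
its gap evidence, which is precisely the failure mode that causes
reference bias at indel HETs. The contrast between the two arms is
then measured by the same `siteAllelicBalance()` code path.

## Numerical and degenerate-input choices

* Genotype QUAL capped at 99; caller restricted to `0 < e < 0.5`.
* Zero-depth pileup columns and all-reference columns emit no call.
* `prfFromCounts()` marks zero-denominator precision/recall as `NA`
  rather than 0 or 1.
* Sites with no informative read are omitted from balance summaries,
  with their count reported in an attribute.
* Tie-breaks are fixed everywhere (lexicographic ALT token, lowest
  row-index pair, left anchor, `hap1` first) so every output is a pure
  function of the inputs and seed; the pipeline's manifests make that
  reproducibility checkable by digest.
* Empty edit plans produce a single full-length match block; chains
  re-derive both sequence lengths by block arithmetic, enforced by the
  class validity method and the strict `readChain()` parser.

## Problem sizes used by the test suite

The suite and the acceptance script use 10–100 kb contigs, panels of
10–20 haplotypes, 150–250 sites for imputation experiments (20
replicates), and coverages between 2.5× and 20×. These sizes were
chosen so the statistical checks (binomial/Poisson tolerances at three
standard deviations, ≥ 30× depth at balance sites, ≥ 50 HET indels for
the bias contrast) are well powered while the whole suite stays
interactive; they are the package's own choice of desk scale.

## Known limitations

* The imputer is exact-search, not HMM-based: it cannot model
  recombination within a chunk and scales quadratically in panel
  haplotypes. It is the reference implementation of the contract, not
  a competitor to production engines.
* Only biallelic, sequence-resolved variants flow through the system;
  multiallelic and symbolic records are rejected at the boundary.
* Single-contig workflows are the tested path; multi-contig inputs
  work per contig but chains and pipelines are exercised on one.
* The reconciliation `rescue` slot (a third candidate set from an
  alternate assembly) is accepted by the contract but no rescue
  aligner is provided.
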