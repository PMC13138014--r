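Package: imputeref
Title: Impute-First Personalized Diploid References with Liftover and
    Reference-Bias Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs phased diploid personalized reference genomes from
    rough low-coverage genotypes and a haplotype panel, emits UCSC chain
    files describing the coordinate shifts, lifts read alignments from the
    personalized haplotypes back to reference coordinates with full CIGAR
    rewriting, reconciles candidate alignments per read, and evaluates the
    result with allele-level and heterozygous-site confusion accounting,
    pivot-window phasing accuracy, allelic-balance profiles at heterozygous
    sites, and QUAL-threshold ROC tables. Includes a synthetic diploid data
    generator (reference, truth sample, haplotype panel, error-bearing
    reads with truth alignments) so the whole workflow runs end-to-end
    without external data, plus a pipeline orchestrator with JSON manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Alignment, VariantDetection, Coverage, Software
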