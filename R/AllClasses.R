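#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet subseq
#' @importFrom stats dbinom quantile rbinom rpois runif setNames
#' @importFrom utils head tail write.table read.table
NULL

#' Simulation configuration
#'
#' Holds every knob of the synthetic diploid data generator: reference
#' length, variant counts by class (SNV, small indel, structural variant),
#' the fraction of variants that are heterozygous, panel composition and
#' its relation to the truth haplotypes (per-site discordance, per-base
#' recombination switch rate), and the read model (fold coverage per
#' haplotype, read length, per-base substitution error rate).
#'
#' Coverage convention: \code{coverage} is the fold coverage of each
#' haplotype, so the total number of sequenced bases is
#' \code{coverage * (|hap1| + |hap2|)}, i.e. reads are drawn from the two
#' haplotypes pooled, in proportion to their lengths.
#'
#' @slot refLength integer, reference length in bases.
#' @slot nSnv,nIndel,nSv integer variant counts; structural variants are
#'   insertions/deletions of at least \code{svMin} (>= 50) bases.
#' @slot hetFraction proportion of variants that are heterozygous.
#' @slot indelMax maximum small-indel length (< 50).
#' @slot svMin minimum structural-variant length (>= 50).
#' @slot panelHaplotypes number of panel haplotypes (even, >= 2).
#' @slot panelDiscordance per-site allele flip probability in the panel.
#' @slot recombRate per-base probability of switching source haplotype
#'   along a panel mosaic.
#' @slot coverage per-haplotype fold coverage of simulated reads.
#' @slot readLength read length in bases.
#' @slot errorRate per-base substitution error probability.
#' @slot seed integer RNG seed; all generator output is a pure function
#'   of the configuration including the seed.
#' @export
setClass("SimConfig", representation(
    refLength = "integer", nSnv = "integer", nIndel = "integer",
    nSv = "integer", hetFraction = "numeric", indelMax = "integer",
    svMin = "integer", panelHaplotypes = "integer",
    panelDiscordance = "numeric", recombRate = "numeric",
    coverage = "numeric", readLength = "integer", errorRate = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(refLength = object@refLength, nSnv = object@nSnv,
             nIndel = object@nIndel, nSv = object@nSv,
             indelMax = object@indelMax, svMin = object@svMin,
             panelHaplotypes = object@panelHaplotypes,
             readLength = object@readLength)
    if (any(cnt < 0L)) msg <- c(msg, "counts and lengths must be >= 0")
    prb <- c(object@hetFraction, object@panelDiscordance,
             object@recombRate, object@errorRate)
    if (any(prb < 0 | prb > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@refLength <= object@readLength)
        msg <- c(msg, "refLength must exceed readLength")
    if (object@svMin < 50L)
        msg <- c(msg, "svMin must be >= 50 (SV length convention)")
    if (object@indelMax >= 50L)
        msg <- c(msg, "indelMax must be < 50 to stay below the SV class")
    if (object@panelHaplotypes %% 2L != 0L)
        msg <- c(msg, "panelHaplotypes must be even (two per sample)")
    if (object@coverage < 0) msg <- c(msg, "coverage must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param refLength reference length in bases.
#' @param nSnv,nIndel,nSv counts of SNVs, small indels and structural
#'   variants placed on the reference.
#' @param hetFraction fraction of variants simulated as heterozygous.
#' @param indelMax maximum small-indel length.
#' @param svMin minimum structural-variant length (>= 50 by convention).
#' @param panelHaplotypes number of panel haplotypes (even).
#' @param panelDiscordance per-site allele flip probability.
#' @param recombRate per-base switch probability of the panel mosaic.
#' @param coverage per-haplotype fold coverage.
#' @param readLength read length in bases.
#' @param errorRate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(refLength = 5000L, nSnv = 20L, seed = 1L)
#' @export
simConfig <- function(refLength = 20000L, nSnv = 60L, nIndel = 20L,
                      nSv = 2L, hetFraction = 0.6, indelMax = 10L,
                      svMin = 50L, panelHaplotypes = 20L,
                      panelDiscordance = 0.02, recombRate = 1e-5,
                      coverage = 30, readLength = 100L,
                      errorRate = 0.002, seed = 1L) {
    new("SimConfig", refLength = as.integer(refLength),
        nSnv = as.integer(nSnv), nIndel = as.integer(nIndel),
        nSv = as.integer(nSv), hetFraction = hetFraction,
        indelMax = as.integer(indelMax), svMin = as.integer(svMin),
        panelHaplotypes = as.integer(panelHaplotypes),
        panelDiscordance = panelDiscordance, recombRate = recombRate,
        coverage = coverage, readLength = as.integer(readLength),
        errorRate = errorRate, seed = as.integer(seed))
}

#' Truth diploid sample
#'
#' A single-contig reference together with a phased set of variants and
#' the two haplotype sequences obtained by substituting each haplotype's
#' alleles into the reference. The variant table is the package's phased
#' variant representation: columns \code{chrom}, \code{pos} (1-based
#' position of the first REF base), \code{ref}, \code{alt}, \code{h1},
#' \code{h2} (allele index on each haplotype, 0 = REF, 1 = ALT).
#'
#' @slot refName name of the reference contig.
#' @slot reference reference sequence (character).
#' @slot variants phased variant data.frame, sorted, non-overlapping.
#' @slot hap1,hap2 haplotype sequences (character).
#' @export
setClass("TruthSample", representation(
    refName = "character", reference = "character",
    variants = "data.frame", hap1 = "character", hap2 = "character"))

setValidity("TruthSample", function(object) {
    v <- object@variants
    need <- c("chrom", "pos", "ref", "alt", "h1", "h2")
    if (!all(need %in% names(v)))
        return(paste("variants must have columns:",
                     paste(need, collapse = ", ")))
    if (nrow(v) > 1L) {
        if (is.unsorted(v$pos, strictly = TRUE))
            return("variant positions must be strictly increasing")
        ends <- v$pos + nchar(v$ref) - 1L
        if (any(v$pos[-1L] <= ends[-nrow(v)]))
            return("variants must not overlap on the reference")
    }
    TRUE
})

#' Coordinate chain between a personalized haplotype and the reference
#'
#' A piecewise-colinear map from a source sequence (a personalized
#' haplotype) to a target sequence (the reference contig). Blocks are
#' matched stretches; after each block \code{dSource} bases are skipped
#' on the haplotype (an insertion relative to the reference) and
#' \code{dTarget} bases on the reference (a deletion from the haplotype).
#' Same-length substitutions (SNVs) stay inside match blocks: a chain
#' encodes coordinate shifts, not sequence identity.
#'
#' @slot source,sourceLength haplotype name and length.
#' @slot target,targetLength reference contig name and length.
#' @slot blocks data.frame with columns \code{size}, \code{dSource},
#'   \code{dTarget}; the final block has zero gaps.
#' @export
setClass("Chain", representation(
    source = "character", sourceLength = "integer",
    target = "character", targetLength = "integer",
    blocks = "data.frame"))

setValidity("Chain", function(object) {
    b <- object@blocks
    if (!all(c("size", "dSource", "dTarget") %in% names(b)))
        return("blocks needs columns size, dSource, dTarget")
    if (any(b$size < 0L) || any(b$dSource < 0L) || any(b$dTarget < 0L))
        return("block sizes and gaps must be >= 0")
    if (nrow(b)) {
        if (b$dSource[nrow(b)] != 0L || b$dTarget[nrow(b)] != 0L)
            return("terminal block must have zero gaps")
        if (sum(b$size) + sum(b$dSource) != object@sourceLength)
            return("block arithmetic does not re-derive source length")
        if (sum(b$size) + sum(b$dTarget) != object@targetLength)
            return("block arithmetic does not re-derive target length")
    }
    TRUE
})

#' Personalized diploid reference
#'
#' The two personalized haplotype sequences for one contig, each paired
#' with the [Chain-class] mapping it back to reference coordinates, plus
#' a digest of the phased call set they were built from.
#'
#' @slot refName reference contig name.
#' @slot hap1,hap2 haplotype sequences (character).
#' @slot chain1,chain2 chains mapping hap1/hap2 to the reference.
#' @slot provenance digest of the source call set.
#' @export
setClass("DiploidReference", representation(
    refName = "character", hap1 = "character", hap2 = "character",
    chain1 = "Chain", chain2 = "Chain", provenance = "character"))

setValidity("DiploidReference", function(object) {
    if (nchar(object@hap1) != object@chain1@sourceLength ||
        nchar(object@hap2) != object@chain2@sourceLength)
        return("haplotype lengths disagree with their chains")
    TRUE
})

#' Haplotype reference panel
#'
#' Ordered biallelic sites and a haplotype-by-site matrix of allele
#' indices, two haplotype rows per sample. The panel is the linkage
#' backbone the imputer searches for the pair of haplotypes best
#' explaining a set of rough genotype calls.
#'
#' @slot sites data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, strictly increasing \code{pos} within \code{chrom}.
#' @slot haplotypes integer matrix (rows = haplotypes, cols = sites) of
#'   allele indices in \{0, 1\}.
#' @slot sampleIds character vector, one id per pair of rows; row
#'   \code{2k-1} and \code{2k} belong to sample \code{k}.
#' @export
setClass("PanelMatrix", representation(
    sites = "data.frame", haplotypes = "matrix",
    sampleIds = "character"))

setValidity("PanelMatrix", function(object) {
    h <- object@haplotypes
    if (nrow(h) != 2L * length(object@sampleIds))
        return("haplotype rows must be 2 x number of samples")
    if (ncol(h) != nrow(object@sites))
        return("haplotype columns must match number of sites")
    if (length(h) && !all(h %in% c(0L, 1L)))
        return("allele indices must be 0 or 1")
    p <- object@sites$pos
    if (length(p) > 1L && any(diff(p) <= 0L))
        return("site positions must be strictly increasing")
    TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@refLength, "bp reference;",
        object@nSnv, "SNV /", object@nIndel, "indel /", object@nSv,
        "SV; HET fraction", object@hetFraction, "\n")
    cat("  panel:", object@panelHaplotypes, "haplotypes, discordance",
        object@panelDiscordance, ", recomb", object@recombRate, "\n")
    cat("  reads:", paste0(object@coverage, "x per haplotype, "),
        object@readLength, "bp, error", object@errorRate,
        ", seed", object@seed, "\n")
})

setMethod("show", "TruthSample", function(object) {
    v <- object@variants
    cat("TruthSample on", object@refName,
        paste0("(", nchar(object@reference), " bp):"),
        nrow(v), "variants,", sum(v$h1 != v$h2), "HET\n")
    cat("  hap lengths:", nchar(object@hap1), "/", nchar(object@hap2), "\n")
})

setMethod("show", "Chain", function(object) {
    cat("Chain", object@source, "->", object@target, ":",
        nrow(object@blocks), "blocks,",
        object@sourceLength, "->", object@targetLength, "bp\n")
})

setMethod("show", "DiploidReference", function(object) {
    cat("DiploidReference for", object@refName, ": hap1",
        nchar(object@hap1), "bp, hap2", nchar(object@hap2), "bp\n")
})

setMethod("show", "PanelMatrix", function(object) {
    cat("PanelMatrix:", nrow(object@haplotypes), "haplotypes (",
        length(object@sampleIds), "samples ) x",
        nrow(object@sites), "sites\n")
})

#' @describeIn TruthSample-class phased variant table of a truth sample.
#' @param x object.
#' @export
truthVariants <- function(x) x@variants

#' @describeIn TruthSample-class the two haplotype sequences.
#' @export
hapSequences <- function(x) c(hap1 = x@hap1, hap2 = x@hap2)

#' @describeIn PanelMatrix-class site table of a panel.
#' @export
panelSites <- function(x) x@sites

#' @describeIn PanelMatrix-class haplotype allele matrix of a panel.
#' @export
panelHaplotypes <- function(x) x@haplotypes

#' @describeIn PanelMatrix-class sample ids of a panel.
#' @export
panelSamples <- function(x) x@sampleIds

#' @describeIn Chain-class block table of a chain.
#' @export
chainBlocks <- function(x) x@blocks
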