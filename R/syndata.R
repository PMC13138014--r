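# Synthetic diploid data: reference, truth sample, haplotype panel, and
# error-bearing reads with truth alignments. Every downstream stage of
# the workflow is testable against these without external data.

#' Simulate a truth diploid sample
#'
#' Generates a random reference contig and places non-overlapping SNVs,
#' small indels and structural variants (insertions/deletions of at
#' least `svMin` bases) on it. A fixed number
#' `round(hetFraction * n)` of variants is heterozygous (the ALT allele
#' assigned to a random haplotype); the rest are homozygous ALT. Both
#' haplotype sequences are built by direct splicing of allele strings
#' between the inter-variant reference stretches — deliberately a
#' different code path from [buildDiploidReference()], so round-trip
#' comparisons between the two are meaningful.
#'
#' @param cfg a [SimConfig-class].
#' @return a [TruthSample-class]; deterministic for a fixed `cfg@seed`.
#' @examples
#' ts <- simulateTruth(simConfig(refLength = 5000L, nSnv = 10L,
#'                               nIndel = 4L, nSv = 1L, seed = 7L))
#' ts
#' @export
simulateTruth <- function(cfg) {
    validObject(cfg)
    withSeed(deriveSeed(cfg@seed, "truth"), {
        refName <- "ref"
        reference <- randomSeq(cfg@refLength)
        n <- cfg@nSnv + cfg@nIndel + cfg@nSv
        if (n == 0L)
            return(new("TruthSample", refName = refName,
                       reference = reference,
                       variants = emptyVariantTable(),
                       hap1 = reference, hap2 = reference))
        type <- sample(rep(c("snv", "indel", "sv"),
                           c(cfg@nSnv, cfg@nIndel, cfg@nSv)))
        isIns <- logical(n)
        len <- integer(n)   # indel length (bases inserted or deleted)
        idx <- type == "indel"
        len[idx] <- sample.int(cfg@indelMax, sum(idx), replace = TRUE)
        idx <- type == "sv"
        len[idx] <- cfg@svMin +
            sample.int(cfg@svMin, sum(idx), replace = TRUE) - 1L
        isIns[type != "snv"] <- runif(sum(type != "snv")) < 0.5
        # reference footprint: SNV = 1; insertion = 1 (anchor);
        # deletion = 1 + len (anchor + deleted bases)
        foot <- ifelse(type == "snv", 1L, ifelse(isIns, 1L, 1L + len))
        margin <- max(2L, cfg@readLength %/% 10L)
        slack <- cfg@refLength - sum(foot) - n - 2L * margin
        if (slack < n)
            stop("variant density infeasible: ", n, " variants with ",
                 sum(foot), " footprint bases do not fit in a ",
                 cfg@refLength, " bp reference")
        u <- sort(sample.int(slack, n))
        pos <- margin + u + c(0L, cumsum(foot + 1L))[seq_len(n)]
        refA <- substring(reference, pos, pos + foot - 1L)
        altA <- character(n)
        for (i in seq_len(n)) {
            if (type[i] == "snv") {
                altA[i] <- sample(setdiff(BASES, refA[i]), 1L)
            } else if (isIns[i]) {
                altA[i] <- paste0(refA[i], randomSeq(len[i]))
            } else {
                altA[i] <- substr(refA[i], 1L, 1L)
            }
        }
        nHet <- round(cfg@hetFraction * n)
        hetIdx <- if (nHet > 0L) sample.int(n, nHet) else integer()
        h1 <- rep(1L, n); h2 <- rep(1L, n)
        whichHap <- runif(length(hetIdx)) < 0.5
        h1[hetIdx[whichHap]] <- 0L
        h2[hetIdx[!whichHap]] <- 0L
        v <- data.frame(chrom = refName, pos = pos, ref = refA,
                        alt = altA, h1 = h1, h2 = h2,
                        stringsAsFactors = FALSE)
        spliceHap <- function(allele) {
            ends <- v$pos + nchar(v$ref) - 1L
            keepStart <- c(1L, ends + 1L)
            keepEnd <- c(v$pos - 1L, nchar(reference))
            between <- substring(reference, keepStart, keepEnd)
            alleleSeq <- ifelse(allele == 1L, v$alt, v$ref)
            paste0(paste0(between[seq_len(n)], alleleSeq,
                          collapse = ""), between[n + 1L])
        }
        new("TruthSample", refName = refName, reference = reference,
            variants = v, hap1 = spliceHap(v$h1), hap2 = spliceHap(v$h2))
    })
}

#' Simulate a haplotype panel related to a truth sample
#'
#' Panel sites equal the truth sites. Each panel haplotype is a mosaic
#' of the two truth haplotypes: the source haplotype switches between
#' adjacent sites with probability `1 - (1 - recombRate)^gap` (gap in
#' bases), and each copied allele is flipped independently with
#' probability `panelDiscordance`. The first two panel haplotypes source
#' deterministically from truth haplotype 1 and 2 respectively, so with
#' zero discordance and zero recombination the truth haplotypes are
#' members of the panel (and the truth diploid is recoverable).
#'
#' @param truth a [TruthSample-class].
#' @param cfg the [SimConfig-class] used to generate it.
#' @return a [PanelMatrix-class]; deterministic for fixed seed.
#' @export
simulatePanel <- function(truth, cfg) {
    stopifnot(cfg@panelHaplotypes >= 2L)
    withSeed(deriveSeed(cfg@seed, "panel"), {
        v <- truth@variants
        S <- nrow(v)
        H <- cfg@panelHaplotypes
        tr <- rbind(v$h1, v$h2)
        hap <- matrix(0L, nrow = H, ncol = S)
        if (S > 0L) {
            gaps <- diff(v$pos)
            pSwitch <- 1 - (1 - cfg@recombRate)^gaps
            for (k in seq_len(H)) {
                src <- if (k <= 2L) k else sample(2L, 1L)
                srcs <- integer(S)
                srcs[1L] <- src
                if (S > 1L) {
                    sw <- runif(S - 1L) < pSwitch
                    srcs[-1L] <- ifelse(cumsum(sw) %% 2L == 1L,
                                        3L - src, src)
                }
                a <- tr[cbind(srcs, seq_len(S))]
                flip <- runif(S) < cfg@panelDiscordance
                hap[k, ] <- ifelse(flip, 1L - a, a)
            }
        }
        new("PanelMatrix",
            sites = v[, c("chrom", "pos", "ref", "alt")],
            haplotypes = hap,
            sampleIds = sprintf("PANEL%03d", seq_len(H %/% 2L)))
    })
}

#' Simulate error-bearing reads with truth alignments
#'
#' Draws `Poisson(coverage * (|hap1| + |hap2|) / readLength)` single-end
#' fixed-length reads uniformly from the two haplotypes pooled (each
#' haplotype is therefore covered `coverage`-fold in expectation), and
#' applies independent per-base substitution errors at `errorRate`. The
#' truth alignment of each read is its source haplotype (`hap1`/`hap2`),
#' its 1-based start, and an all-match CIGAR — exact because reads are
#' contiguous substrings of their haplotype.
#'
#' @param truth a [TruthSample-class].
#' @param cfg the [SimConfig-class].
#' @return list with `reads` (data.frame `qname`, `seq`) and
#'   `alignments` (truth alignment data.frame in haplotype coordinates,
#'   with `score` = read length).
#' @export
simulateReads <- function(truth, cfg) {
    stopifnot(cfg@coverage > 0)
    L1 <- nchar(truth@hap1); L2 <- nchar(truth@hap2)
    rl <- cfg@readLength
    if (rl > L1 || rl > L2)
        stop("readLength ", rl, " exceeds a haplotype length (",
             L1, "/", L2, ")")
    withSeed(deriveSeed(cfg@seed, "reads"), {
        n <- rpois(1L, cfg@coverage * (L1 + L2) / rl)
        hapIdx <- 1L + (runif(n) < L2 / (L1 + L2))
        starts <- integer(n)
        starts[hapIdx == 1L] <-
            sample.int(L1 - rl + 1L, sum(hapIdx == 1L), replace = TRUE)
        starts[hapIdx == 2L] <-
            sample.int(L2 - rl + 1L, sum(hapIdx == 2L), replace = TRUE)
        seqs <- character(n)
        seqs[hapIdx == 1L] <- substring(truth@hap1,
            starts[hapIdx == 1L], starts[hapIdx == 1L] + rl - 1L)
        seqs[hapIdx == 2L] <- substring(truth@hap2,
            starts[hapIdx == 2L], starts[hapIdx == 2L] + rl - 1L)
        nErr <- rbinom(n, rl, cfg@errorRate)
        for (i in which(nErr > 0L)) {
            at <- sample.int(rl, nErr[i])
            s <- strsplit(seqs[i], "")[[1L]]
            s[at] <- vapply(s[at], function(b)
                sample(setdiff(BASES, b), 1L), character(1))
            seqs[i] <- paste(s, collapse = "")
        }
        reads <- data.frame(
            qname = sprintf("read%06d", seq_len(n)),
            seq = seqs, stringsAsFactors = FALSE)
        aln <- data.frame(
            qname = reads$qname, flag = 0L,
            rname = paste0("hap", hapIdx), pos = starts,
            mapq = 60L, cigar = paste0(rl, "M"), seq = seqs,
            score = rl, stringsAsFactors = FALSE)
        list(reads = reads, alignments = aln)
    })
}

#' Write all synthetic outputs of one configuration to a directory
#'
#' Emits reference and haplotype FASTAs, truth and panel VCFs (phased
#' `|` genotypes), reads FASTQ, and the truth SAM (with `AS` tags), all
#' with the generation parameters echoed into headers.
#'
#' @param cfg a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the in-memory objects
#'   (`truth`, `panel`, `reads`, paths).
#' @export
writeSynData <- function(cfg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    truth <- simulateTruth(cfg)
    panel <- simulatePanel(truth, cfg)
    rd <- simulateReads(truth, cfg)
    params <- paste0(
        "syndata: seed=", cfg@seed, " refLength=", cfg@refLength,
        " nSnv=", cfg@nSnv, " nIndel=", cfg@nIndel, " nSv=", cfg@nSv,
        " hetFraction=", cfg@hetFraction,
        " coverage=", cfg@coverage, "x-per-haplotype",
        " readLength=", cfg@readLength, " errorRate=", cfg@errorRate)
    refLen <- setNames(nchar(truth@reference), truth@refName)
    hapLen <- c(hap1 = nchar(truth@hap1), hap2 = nchar(truth@hap2))
    writeFasta(setNames(truth@reference, truth@refName),
               file.path(dir, "ref.fasta"))
    writeFasta(c(hap1 = truth@hap1, hap2 = truth@hap2),
               file.path(dir, "truth_haps.fasta"))
    writeVcf(truth@variants, refLen, file.path(dir, "truth.vcf"),
             phased = TRUE, sampleName = "TRUTH", comments = params)
    writePanelVcf(panel, refLen, file.path(dir, "panel.vcf"),
                  comments = params)
    writeFastq(rd$reads, file.path(dir, "reads.fastq"))
    writeSam(rd$alignments, hapLen, file.path(dir, "truth.sam"),
             comments = params)
    invisible(list(truth = truth, panel = panel, reads = rd$reads,
                   alignments = rd$alignments, dir = dir))
}
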