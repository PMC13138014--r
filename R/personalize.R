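# Personalized diploid reference construction: normalize phased calls
# into per-haplotype edit plans, apply them to the reference, and emit
# chains describing the coordinate shifts.

#' Plan the edits a haplotype's alleles imply on the reference
#'
#' One edit per call whose haplotype-`hapIndex` allele is ALT. Each
#' REF/ALT pair is normalized by stripping its common prefix (the VCF
#' anchor base), so insertions become zero-length-interval edits and
#' deletions pure removals; SNVs stay same-length substitutions.
#' Overlapping calls are resolved leftmost-wins: the first by position
#' is kept and later overlapping records dropped with a warning.
#'
#' @param reference reference sequence (character).
#' @param calls phased variant data.frame, sorted by position; REF
#'   alleles must match the reference at their loci.
#' @param hapIndex 1 or 2.
#' @return data.frame edit plan: `start` (1-based first replaced base),
#'   `len` (replaced interval length, 0 for pure insertion before
#'   `start`), `replacement`.
#' @export
planEdits <- function(reference, calls, hapIndex) {
    stopifnot(hapIndex %in% c(1L, 2L))
    if (nrow(calls) == 0L)
        return(data.frame(start = integer(), len = integer(),
                          replacement = character(),
                          stringsAsFactors = FALSE))
    if (is.unsorted(calls$pos))
        stop("calls must be sorted by position")
    if (any(grepl("^<", calls$alt)))
        stop("symbolic ALT alleles are not supported: ",
             calls$alt[grep("^<", calls$alt)[1L]])
    refObs <- substring(reference, calls$pos,
                        calls$pos + nchar(calls$ref) - 1L)
    bad <- which(refObs != calls$ref |
                 calls$pos + nchar(calls$ref) - 1L > nchar(reference) |
                 calls$pos < 1L)
    if (length(bad))
        stop("REF allele mismatch at ", calls$chrom[bad[1L]], ":",
             calls$pos[bad[1L]], " (expected '", calls$ref[bad[1L]],
             "', reference has '", refObs[bad[1L]], "')")
    allele <- if (hapIndex == 1L) calls$h1 else calls$h2
    calls <- calls[allele == 1L, , drop = FALSE]
    if (nrow(calls) == 0L)
        return(data.frame(start = integer(), len = integer(),
                          replacement = character(),
                          stringsAsFactors = FALSE))
    # strip common REF/ALT prefix (VCF anchoring)
    npre <- mapply(function(r, a) {
        k <- min(nchar(r), nchar(a))
        i <- 0L
        while (i < k && substr(r, i + 1L, i + 1L) ==
                        substr(a, i + 1L, i + 1L)) i <- i + 1L
        i
    }, calls$ref, calls$alt)
    start <- calls$pos + npre
    len <- nchar(calls$ref) - npre
    repl <- substring(calls$alt, npre + 1L)
    # leftmost-wins overlap resolution on [start, start+len)
    keep <- rep(TRUE, length(start))
    lastEnd <- 0L  # last kept occupied ref base
    for (i in seq_along(start)) {
        lo <- start[i]
        hi <- start[i] + max(len[i] - 1L, 0L)
        if (lo <= lastEnd) {
            keep[i] <- FALSE
        } else {
            lastEnd <- max(lastEnd, hi)
        }
    }
    if (any(!keep))
        warning(sum(!keep), " call(s) overlapping an earlier call ",
                "dropped (leftmost-wins)")
    data.frame(start = start[keep], len = len[keep],
               replacement = repl[keep], stringsAsFactors = FALSE)
}

#' Apply an edit plan, producing the haplotype and its chain
#'
#' The haplotype is the reference with each edit's interval replaced.
#' The chain maps haplotype (source) to reference (target): unedited
#' stretches and same-length substitutions form match blocks; an edit
#' replacing `d` reference bases with `r` haplotype bases with `d != r`
#' contributes a junction with `dTarget = d`, `dSource = r`.
#'
#' @param reference reference sequence (character).
#' @param plan edit plan from [planEdits()].
#' @param refName,hapName sequence names recorded in the chain.
#' @return list with `seq` (haplotype character) and `chain`
#'   ([Chain-class]).
#' @export
applyEdits <- function(reference, plan, refName = "ref",
                       hapName = "hap") {
    L <- nchar(reference)
    n <- nrow(plan)
    if (n > 0L) {
        occEnd <- plan$start + pmax(plan$len - 1L, 0L)
        if (is.unsorted(plan$start) ||
            (n > 1L && any(plan$start[-1L] <= occEnd[-n])))
            stop("edit plan must be sorted and non-overlapping")
        if (any(plan$start < 1L) || any(plan$start + plan$len - 1L > L))
            stop("edit outside reference bounds")
    }
    # sequence splice
    pieces <- character(2L * n + 1L)
    prev <- 1L
    for (i in seq_len(n)) {
        pieces[2L * i - 1L] <- substring(reference, prev,
                                         plan$start[i] - 1L)
        pieces[2L * i] <- plan$replacement[i]
        prev <- plan$start[i] + plan$len[i]
    }
    pieces[2L * n + 1L] <- substring(reference, prev, L)
    hap <- paste(pieces, collapse = "")
    # chain blocks: same-length substitutions merge into match blocks
    size <- integer(); dS <- integer(); dT <- integer()
    pending <- 0L
    prev <- 1L
    for (i in seq_len(n)) {
        d <- plan$len[i]
        r <- nchar(plan$replacement[i])
        pending <- pending + (plan$start[i] - prev)
        if (d == r) {
            pending <- pending + d
        } else if (pending == 0L && length(size)) {
            dS[length(dS)] <- dS[length(dS)] + r
            dT[length(dT)] <- dT[length(dT)] + d
        } else {
            size <- c(size, pending); dS <- c(dS, r); dT <- c(dT, d)
            pending <- 0L
        }
        prev <- plan$start[i] + d
    }
    pending <- pending + (L - prev + 1L)
    size <- c(size, pending); dS <- c(dS, 0L); dT <- c(dT, 0L)
    chain <- new("Chain", source = hapName,
                 sourceLength = nchar(hap), target = refName,
                 targetLength = L,
                 blocks = data.frame(size = size, dSource = dS,
                                     dTarget = dT))
    validObject(chain)
    list(seq = hap, chain = chain)
}

#' Build a personalized diploid reference from phased calls
#'
#' Runs [planEdits()] and [applyEdits()] per haplotype. Input genotypes
#' must be phased: this stage is only meaningful downstream of phasing.
#'
#' @param reference named character vector of length 1 (single contig)
#'   or a bare character.
#' @param calls phased variant data.frame (`h1`, `h2`), or a path to a
#'   phased VCF.
#' @return a [DiploidReference-class].
#' @examples
#' calls <- data.frame(chrom = "ref", pos = 3L, ref = "C", alt = "T",
#'                     h1 = 1L, h2 = 0L)
#' dr <- buildDiploidReference(c(ref = "AACGGT"), calls)
#' dr
#' @export
buildDiploidReference <- function(reference, calls) {
    if (is.character(calls) && length(calls) == 1L)
        calls <- readVcfCalls(calls, requirePhased = TRUE)
    refName <- if (!is.null(names(reference))) names(reference)[1L]
               else "ref"
    reference <- unname(reference[1L])
    if (nrow(calls) && any(!calls$h1 %in% c(0L, 1L) |
                           !calls$h2 %in% c(0L, 1L)))
        stop("allele indices must be 0/1 (biallelic, phased)")
    prov <- paste0("calls:", digestCalls(calls))
    h1 <- applyEdits(reference, planEdits(reference, calls, 1L),
                     refName = refName, hapName = "hap1")
    h2 <- applyEdits(reference, planEdits(reference, calls, 2L),
                     refName = refName, hapName = "hap2")
    new("DiploidReference", refName = refName, hap1 = h1$seq,
        hap2 = h2$seq, chain1 = h1$chain, chain2 = h2$chain,
        provenance = prov)
}

# order-sensitive content digest of a call table (no external digest
# package needed: md5 of a serialized temp file)
digestCalls <- function(calls) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(paste(calls$chrom, calls$pos, calls$ref, calls$alt,
                     calls$h1, calls$h2), f)
    unname(tools::md5sum(f))
}

#' Write a diploid reference to FASTA + chain files
#'
#' @param dr a [DiploidReference-class].
#' @param outPrefix path prefix; writes `<prefix>.hap1.fasta`,
#'   `<prefix>.hap2.fasta`, `<prefix>.hap1.chain`, `<prefix>.hap2.chain`.
#' @return invisibly, the four paths.
#' @export
writeDiploidReference <- function(dr, outPrefix) {
    p <- paste0(outPrefix, c(".hap1.fasta", ".hap2.fasta",
                             ".hap1.chain", ".hap2.chain"))
    writeFasta(c(hap1 = dr@hap1), p[1L])
    writeFasta(c(hap2 = dr@hap2), p[2L])
    writeChain(dr@chain1, p[3L])
    writeChain(dr@chain2, p[4L])
    invisible(p)
}

#' Per-base provenance map of a chain
#'
#' @param chain a [Chain-class] (haplotype -> reference).
#' @return integer vector of length `sourceLength`: for each haplotype
#'   position (1-based) the reference position it maps to, or `NA` for
#'   haplotype-only (inserted) bases.
#' @export
provenanceMap <- function(chain) {
    b <- chain@blocks
    m <- rep(NA_integer_, chain@sourceLength)
    s <- 1L; t <- 1L
    for (i in seq_len(nrow(b))) {
        if (b$size[i] > 0L)
            m[s:(s + b$size[i] - 1L)] <- t:(t + b$size[i] - 1L)
        s <- s + b$size[i] + b$dSource[i]
        t <- t + b$size[i] + b$dTarget[i]
    }
    m
}

#' Invert a chain (swap source and target roles)
#'
#' @param chain a [Chain-class].
#' @return the inverse [Chain-class].
#' @export
invertChain <- function(chain) {
    b <- chain@blocks
    new("Chain", source = chain@target,
        sourceLength = chain@targetLength, target = chain@source,
        targetLength = chain@sourceLength,
        blocks = data.frame(size = b$size, dSource = b$dTarget,
                            dTarget = b$dSource))
}
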