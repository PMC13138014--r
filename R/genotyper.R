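# Rough genotyping: pileup columns from alignments, a binomial
# maximum-likelihood diploid caller, and the record-level QUAL/DP
# filter. The calls this stage produces are deliberately rough — they
# are the input to panel-based imputation, not an end product.

#' Build pileup columns from alignments
#'
#' Walks each record's CIGAR: `M` bases contribute the read base at the
#' aligned position; an `I` contributes an insertion token
#' (`+<inserted seq>`) and a `D` a deletion token (`-<deleted ref
#' seq>`), both anchored at the preceding reference base (VCF-style
#' left anchoring). An indel token replaces that read's base
#' contribution at the anchor, so total contributions equal total
#' aligned `M` bases exactly. Soft-clipped and unaligned bases are
#' excluded.
#'
#' @param records alignment data.frame in reference coordinates.
#' @param reference named character vector of reference sequences
#'   covering every alignment target.
#' @return data.frame of pileup contributions aggregated per column:
#'   `chrom`, `pos`, `token`, `count`; the depth of a column is the sum
#'   of its counts.
#' @export
pileupFromAlignments <- function(records, reference) {
    records <- records[bitwAnd(records$flag, 4L) == 0L, , drop = FALSE]
    missingRef <- setdiff(unique(records$rname), names(reference))
    if (length(missingRef))
        stop("alignment target(s) absent from the reference set: ",
             paste(missingRef, collapse = ", "))
    chromL <- vector("list", nrow(records))
    posL <- vector("list", nrow(records))
    tokL <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
        p <- parseCigar(records$cigar[i])
        rpos <- records$pos[i]; qpos <- 1L
        seqi <- records$seq[i]
        chrom <- records$rname[i]
        pos <- integer(); tok <- character()
        for (k in seq_along(p$ops)) {
            op <- p$ops[k]; len <- p$lens[k]
            if (op == "M") {
                pos <- c(pos, rpos:(rpos + len - 1L))
                tok <- c(tok, strsplit(substring(seqi, qpos,
                                                 qpos + len - 1L),
                                       "")[[1L]])
                rpos <- rpos + len; qpos <- qpos + len
            } else if (op == "I") {
                ins <- substring(seqi, qpos, qpos + len - 1L)
                anchor <- rpos - 1L
                drop <- which(pos == anchor)
                if (length(drop)) {
                    pos <- pos[-drop[length(drop)]]
                    tok <- tok[-drop[length(drop)]]
                }
                pos <- c(pos, anchor); tok <- c(tok, paste0("+", ins))
                qpos <- qpos + len
            } else if (op == "D") {
                del <- substring(reference[[chrom]], rpos,
                                 rpos + len - 1L)
                anchor <- rpos - 1L
                drop <- which(pos == anchor)
                if (length(drop)) {
                    pos <- pos[-drop[length(drop)]]
                    tok <- tok[-drop[length(drop)]]
                }
                pos <- c(pos, anchor); tok <- c(tok, paste0("-", del))
                rpos <- rpos + len
            } else if (op == "S") {
                qpos <- qpos + len
            } else {
                stop("unsupported CIGAR op '", op, "'")
            }
        }
        chromL[[i]] <- rep(chrom, length(pos))
        posL[[i]] <- pos; tokL[[i]] <- tok
    }
    chromL <- unlist(chromL); posL <- unlist(posL); tokL <- unlist(tokL)
    if (!length(posL))
        return(data.frame(chrom = character(), pos = integer(),
                          token = character(), count = integer(),
                          stringsAsFactors = FALSE))
    agg <- aggregate(list(count = rep(1L, length(posL))),
                     by = list(chrom = chromL, pos = posL,
                               token = tokL), FUN = sum)
    agg <- agg[order(agg$chrom, agg$pos, agg$token), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Call rough diploid genotypes from pileup columns
#'
#' For every column where a non-reference allele is observed, evaluates
#' genotype likelihoods for 0/0, 0/1 and 1/1 under a symmetric binomial
#' read-sampling model: a read carries ALT with probability
#' `errorRate`, 1/2, or `1 - errorRate` respectively. The
#' maximum-likelihood genotype is emitted with a Phred-scaled posterior
#' error under a flat genotype prior (capped at 99); depth is the full
#' column depth. The candidate ALT is the most frequent non-reference
#' token (ties broken lexicographically).
#'
#' @param pileup pileup data.frame from [pileupFromAlignments()].
#' @param reference named character vector of reference sequences.
#' @param errorRate per-read error probability, in (0, 0.5).
#' @return rough call data.frame: `chrom`, `pos`, `ref`, `alt`, `h1`,
#'   `h2` (unphased pair, `h1 <= h2`), `qual`, `depth`.
#' @export
callRoughGenotypes <- function(pileup, reference, errorRate = 0.01) {
    stopifnot(errorRate > 0, errorRate < 0.5)
    out <- list()
    if (nrow(pileup) == 0L)
        return(cbind(emptyVariantTable(),
                     data.frame(qual = numeric(), depth = integer())))
    # restrict to columns where a non-reference token was observed
    refBaseAll <- substring(unname(reference[pileup$chrom]),
                            pileup$pos, pileup$pos)
    key <- paste(pileup$chrom, pileup$pos)
    hasAlt <- key %in% unique(key[pileup$token != refBaseAll])
    pileup <- pileup[hasAlt, , drop = FALSE]
    key <- key[hasAlt]
    for (col in split(seq_len(nrow(pileup)), key)) {
        chrom <- pileup$chrom[col[1L]]
        pos <- pileup$pos[col[1L]]
        refBase <- substring(reference[[chrom]], pos, pos)
        toks <- pileup$token[col]; cnts <- pileup$count[col]
        nonref <- which(toks != refBase)
        if (!length(nonref)) next
        altTok <- toks[nonref][order(-cnts[nonref],
                                     toks[nonref])][1L]
        k <- cnts[toks == altTok]
        r <- sum(cnts[toks == refBase])
        n <- k + r
        ll <- c(dbinom(k, n, errorRate),       # 0/0
                dbinom(k, n, 0.5),             # 0/1
                dbinom(k, n, 1 - errorRate))   # 1/1
        post <- ll / sum(ll)
        g <- which.max(ll)
        gt <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))[[g]]
        if (startsWith(altTok, "+")) {
            refA <- refBase
            altA <- paste0(refBase, substring(altTok, 2L))
        } else if (startsWith(altTok, "-")) {
            refA <- paste0(refBase, substring(altTok, 2L))
            altA <- refBase
        } else {
            refA <- refBase; altA <- altTok
        }
        out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, pos = pos, ref = refA, alt = altA,
            h1 = gt[1L], h2 = gt[2L],
            qual = phred(1 - post[g]), depth = sum(cnts),
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(cbind(emptyVariantTable(),
                     data.frame(qual = numeric(), depth = integer())))
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$pos), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Filter rough calls on QUAL and depth
#'
#' Retains exactly the calls with `qual >= minQual` and
#' `depth <= maxDepth`, preserving order: quality strictly below the
#' threshold is excluded and depth strictly exceeding the cap is
#' excluded, so both boundary values pass. A pure subset operation,
#' idempotent by construction.
#'
#' @param calls rough call data.frame with `qual` and `depth`.
#' @param minQual minimum quality retained (default 20).
#' @param maxDepth maximum depth retained (default 100).
#' @return the retained subset.
#' @export
filterRoughCalls <- function(calls, minQual = 20, maxDepth = 100) {
    stopifnot(minQual >= 0, maxDepth >= 0)
    out <- calls[calls$qual >= minQual & calls$depth <= maxDepth, ,
                 drop = FALSE]
    rownames(out) <- NULL
    out
}
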