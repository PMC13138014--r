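# Liftover of positions and alignments from personalized-haplotype
# coordinates to reference coordinates via chains, with CIGAR
# rewriting, and best-of-k reconciliation of candidate alignments.

#' Lift haplotype positions to reference coordinates
#'
#' Positions inside match blocks map by block offset arithmetic.
#' Positions inside a haplotype-only gap (an insertion relative to the
#' reference) are flagged and annotated with the flanking reference
#' coordinate: the last matched reference base to the left of the
#' insertion.
#'
#' @param chain a [Chain-class] (haplotype -> reference).
#' @param pos integer vector of 1-based haplotype positions.
#' @return data.frame with `refPos` (NA when inside an insertion),
#'   `insideInsertion`, and `flank` (NA unless inside an insertion).
#' @export
liftPosition <- function(chain, pos) {
    if (any(pos < 1L | pos > chain@sourceLength))
        stop("position out of chain source bounds")
    b <- chain@blocks
    sStart <- 1L + c(0L, cumsum(b$size + b$dSource))[seq_len(nrow(b))]
    tStart <- 1L + c(0L, cumsum(b$size + b$dTarget))[seq_len(nrow(b))]
    i <- findInterval(pos, sStart)
    off <- pos - sStart[i]
    inMatch <- off < b$size[i]
    data.frame(
        refPos = ifelse(inMatch, tStart[i] + off, NA_integer_),
        insideInsertion = !inMatch,
        flank = ifelse(inMatch, NA_integer_,
                       tStart[i] + b$size[i] - 1L))
}

# Rewrite one alignment through the provenance map `m` of a chain.
# Returns list(pos, cigar) or NULL when no read base maps (fully inside
# a haplotype insertion).
liftOneCigar <- function(pos, cigar, m) {
    p <- parseCigar(cigar)
    outOps <- character(); outLens <- integer()
    emit <- function(op, len) {
        if (len > 0L) {
            outOps[length(outOps) + 1L] <<- op
            outLens[length(outLens) + 1L] <<- len
        }
    }
    h <- pos
    lastRef <- NA_integer_
    outPos <- NA_integer_
    for (k in seq_along(p$ops)) {
        op <- p$ops[k]; len <- p$lens[k]
        if (op == "S" || op == "I") {
            emit(op, len)
        } else if (op == "M" || op == "D") {
            r <- m[h:(h + len - 1L)]
            mapped <- !is.na(r)
            if (op == "M") {
                # runs of unmapped bases -> I; mapped bases -> M with D
                # gaps where the reference jumps
                rl <- rle(mapped)
                j <- 1L
                for (q in seq_along(rl$values)) {
                    ln <- rl$lengths[q]
                    if (!rl$values[q]) {
                        emit("I", ln)
                    } else {
                        rr <- r[j:(j + ln - 1L)]
                        # split at internal reference jumps
                        brk <- c(0L, which(diff(rr) != 1L), ln)
                        for (s in seq_len(length(brk) - 1L)) {
                            seg <- rr[(brk[s] + 1L):brk[s + 1L]]
                            if (!is.na(lastRef) &&
                                seg[1L] > lastRef + 1L)
                                emit("D", seg[1L] - lastRef - 1L)
                            if (is.na(outPos)) outPos <- seg[1L]
                            emit("M", length(seg))
                            lastRef <- seg[length(seg)]
                        }
                    }
                    j <- j + ln
                }
            } else {  # D: consumes haplotype, emits reference deletion
                rr <- r[mapped]
                if (length(rr)) {
                    lo <- rr[1L]; hi <- rr[length(rr)]
                    gap <- if (!is.na(lastRef)) lo - lastRef - 1L else 0L
                    emit("D", gap + hi - lo + 1L)
                    lastRef <- hi
                }
            }
            h <- h + len
        } else {
            stop("unsupported CIGAR op '", op, "'")
        }
    }
    if (is.na(outPos)) return(NULL)
    list(pos = outPos, cigar = unparseCigar(outOps, outLens))
}

#' Lift alignments through a chain, rewriting CIGARs
#'
#' Haplotype-only bases covered by a read become insertions (`I`),
#' reference-only bases spanned become deletions (`D`), and matched
#' stretches are preserved; the query-consuming CIGAR length is
#' unchanged. Reads falling entirely inside a haplotype insertion, or
#' outside the chain, are emitted as unmapped records with a `reason`
#' (`fully-inside-insertion` / `off-chain`). `mapq` and `score` are
#' carried through unchanged.
#'
#' @param chain a [Chain-class] (haplotype -> reference).
#' @param records alignment data.frame targeting the chain source.
#' @param map optional precomputed [provenanceMap()] of `chain`.
#' @return the records lifted to reference coordinates, with columns
#'   `reason` (`NA` for lifted records) preserved ordering.
#' @export
liftAlignments <- function(chain, records, map = provenanceMap(chain)) {
    n <- nrow(records)
    out <- records
    out$rname <- chain@target
    out$reason <- NA_character_
    for (i in seq_len(n)) {
        qlen <- cigarQueryLength(records$cigar[i])
        if (qlen != nchar(records$seq[i]))
            stop("CIGAR query length (", qlen, ") disagrees with read ",
                 "length (", nchar(records$seq[i]), ") for ",
                 records$qname[i])
        span <- cigarRefLength(records$cigar[i])
        if (records$pos[i] < 1L ||
            records$pos[i] + span - 1L > chain@sourceLength) {
            out$flag[i] <- bitwOr(records$flag[i], 4L)
            out$rname[i] <- "*"; out$pos[i] <- 0L
            out$cigar[i] <- "*"; out$mapq[i] <- 0L
            out$reason[i] <- "off-chain"
            next
        }
        lifted <- liftOneCigar(records$pos[i], records$cigar[i], map)
        if (is.null(lifted)) {
            out$flag[i] <- bitwOr(records$flag[i], 4L)
            out$rname[i] <- "*"; out$pos[i] <- 0L
            out$cigar[i] <- "*"; out$mapq[i] <- 0L
            out$reason[i] <- "fully-inside-insertion"
            next
        }
        newQ <- cigarQueryLength(lifted$cigar)
        if (newQ != qlen)
            stop("internal error: lifted CIGAR query length changed")
        out$pos[i] <- lifted$pos
        out$cigar[i] <- lifted$cigar
    }
    out
}

#' Reconcile candidate alignments per read
#'
#' For each read, unmapped/unliftable candidates are dropped, then the
#' best candidate is chosen by mapping quality (descending), alignment
#' score (descending), and finally source label order
#' `hap1 < hap2 < rescue`; the winner's label is recorded in the
#' `source` column. Reads with no liftable candidate are emitted as
#' unmapped records, so read counts are conserved.
#'
#' @param candidates list of alignment data.frames, one per source.
#' @param labels character vector naming each candidate set; order
#'   defines the tie-break.
#' @return one alignment data.frame, one record per read, ordered by
#'   read name.
#' @export
reconcileAlignments <- function(candidates,
                                labels = c("hap1", "hap2", "rescue")) {
    stopifnot(length(candidates) >= 1L,
              length(labels) >= length(candidates))
    all <- do.call(rbind, lapply(seq_along(candidates), function(i) {
        x <- candidates[[i]]
        x$source <- labels[i]
        x$srcOrder <- i
        x[, c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
              "score", "source", "srcOrder")]
    }))
    mapped <- all[bitwAnd(all$flag, 4L) == 0L, , drop = FALSE]
    sc <- ifelse(is.na(mapped$score), -Inf, mapped$score)
    ord <- order(mapped$qname, -mapped$mapq, -sc, mapped$srcOrder)
    mapped <- mapped[ord, , drop = FALSE]
    best <- mapped[!duplicated(mapped$qname), , drop = FALSE]
    lost <- setdiff(unique(all$qname), best$qname)
    if (length(lost)) {
        seqs <- all$seq[match(lost, all$qname)]
        best <- rbind(best, data.frame(
            qname = lost, flag = 4L, rname = "*", pos = 0L, mapq = 0L,
            cigar = "*", seq = seqs, score = NA_integer_,
            source = "none", srcOrder = 0L, stringsAsFactors = FALSE))
    }
    best <- best[order(best$qname), , drop = FALSE]
    best$srcOrder <- NULL
    rownames(best) <- NULL
    best
}
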