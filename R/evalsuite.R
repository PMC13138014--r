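# Evaluation statistics: allele-level and HET-level confusion
# accounting, precision/recall/F1, pivot-window phasing accuracy with
# density strata, allelic balance at HET sites with length binning, and
# QUAL-threshold ROC tables.

#' Allele-level confusion counts against a diploid truth
#'
#' Every called diploid genotype is treated as a pair of individual
#' allele calls over a fixed site universe. A called ALT allele is a TP
#' when the true genotype carries at least one ALT, and an FP when the
#' truth is homozygous REF; a called REF allele is a TN when the truth
#' carries at least one REF, and an FN when the truth is homozygous
#' ALT. Calls or truth missing at a site count as homozygous REF, so
#' `tp + fp + fn + tn = 2 * |sites|` always.
#'
#' @param calls,truth variant data.frames with `h1`, `h2`.
#' @param sites site universe data.frame (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @return named integer vector `tp`, `fp`, `fn`, `tn`.
#' @export
alleleAltConfusion <- function(calls, truth, sites) {
    cg <- genotypesAtSites(calls, sites)
    tg <- genotypesAtSites(truth, sites)
    cAlt <- cg$h1 + cg$h2           # called ALT alleles per site
    tDos <- tg$h1 + tg$h2           # true ALT dosage
    counts <- c(
        tp = sum(cAlt[tDos >= 1L]),
        fp = sum(cAlt[tDos == 0L]),
        fn = sum((2L - cAlt)[tDos == 2L]),
        tn = sum((2L - cAlt)[tDos <= 1L]))
    stopifnot(sum(counts) == 2L * nrow(sites))
    counts
}

#' HET-level confusion counts
#'
#' Per site: a HET call that is truly HET is a TP; a HET call at a
#' non-HET truth site an FP; a non-HET call at a truly HET site an FN;
#' otherwise a TN. Totals sum to `|sites|`.
#'
#' @inheritParams alleleAltConfusion
#' @return named integer vector `tp`, `fp`, `fn`, `tn`.
#' @export
hetConfusion <- function(calls, truth, sites) {
    cg <- genotypesAtSites(calls, sites)
    tg <- genotypesAtSites(truth, sites)
    cHet <- (cg$h1 + cg$h2) == 1L
    tHet <- (tg$h1 + tg$h2) == 1L
    counts <- c(tp = sum(cHet & tHet), fp = sum(cHet & !tHet),
                fn = sum(!cHet & tHet), tn = sum(!cHet & !tHet))
    stopifnot(sum(counts) == nrow(sites))
    counts
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`, F1 their harmonic
#' mean. A zero denominator yields `NA` (explicitly undefined).
#'
#' @param counts named vector with `tp`, `fp`, `fn`.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
prfFromCounts <- function(counts) {
    tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
    p <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(p) && !is.na(r) && p + r > 0)
        2 * p * r / (p + r) else NA_real_
    c(precision = p, recall = r, f1 = f1)
}

#' Build pivot windows over polymorphic sites
#'
#' One window per polymorphic site (the pivot), containing the pivot
#' and all sites to its left within `window` bases
#' (`pivot - window <= pos <= pivot`). Windows are stratified by member
#' count: "1-5", "6-10", "11+".
#'
#' @param sites site data.frame sorted by `pos`, unique per `chrom`.
#' @param window window width in bases (default 200).
#' @return data.frame with `chrom`, `pivotPos`, `from`, `to` (member
#'   site row indices into `sites`), `n`, `stratum`.
#' @export
buildPivotWindows <- function(sites, window = 200L) {
    pos <- sites$pos
    if (is.unsorted(pos)) stop("sites must be sorted by position")
    lo <- findInterval(pos - window - 0.5, pos) + 1L
    n <- seq_along(pos) - lo + 1L
    data.frame(chrom = sites$chrom, pivotPos = pos, from = lo,
               to = seq_along(pos), n = n,
               stratum = cut(n, c(0L, 5L, 10L, Inf),
                             labels = c("1-5", "6-10", "11+")),
               stringsAsFactors = FALSE)
}

#' Pivot-window genotype-and-phase accuracy by density stratum
#'
#' A window is correct when a single haplotype-label assignment
#' (identity or swap), applied consistently across the whole window,
#' makes every member site's per-haplotype alleles match truth — both
#' correctly genotyped and correctly phased up to the globally
#' arbitrary haplotype labelling.
#'
#' @param imputed,truth phased variant data.frames.
#' @param windows window table from [buildPivotWindows()].
#' @param sites the site universe the windows index into.
#' @return data.frame per stratum: `stratum`, `nWindows`, `nCorrect`,
#'   `accuracy`.
#' @export
windowAccuracy <- function(imputed, truth, windows, sites) {
    ig <- genotypesAtSites(imputed, sites)
    tg <- genotypesAtSites(truth, sites)
    idBad <- cumsum(!(ig$h1 == tg$h1 & ig$h2 == tg$h2))
    swBad <- cumsum(!(ig$h1 == tg$h2 & ig$h2 == tg$h1))
    rangeSum <- function(cum, from, to)
        cum[to] - c(0L, cum)[from]
    okId <- rangeSum(idBad, windows$from, windows$to) == 0L
    okSw <- rangeSum(swBad, windows$from, windows$to) == 0L
    correct <- okId | okSw
    strata <- c("1-5", "6-10", "11+")
    res <- data.frame(
        stratum = strata,
        nWindows = vapply(strata, function(s)
            sum(windows$stratum == s), integer(1)),
        nCorrect = vapply(strata, function(s)
            sum(correct[windows$stratum == s]), integer(1)),
        stringsAsFactors = FALSE)
    res$accuracy <- ifelse(res$nWindows > 0L,
                           res$nCorrect / res$nWindows, NA_real_)
    rownames(res) <- NULL
    res
}

# Per-read reference-space layout: matched ref intervals, deletion
# intervals, and insertion junctions (anchored after a ref position).
readLayout <- function(pos, cigar) {
    p <- parseCigar(cigar)
    mStart <- integer(); mEnd <- integer()
    dStart <- integer(); dEnd <- integer()
    insAt <- integer(); insLen <- integer()
    rpos <- pos
    for (k in seq_along(p$ops)) {
        op <- p$ops[k]; len <- p$lens[k]
        if (op == "M") {
            mStart <- c(mStart, rpos); mEnd <- c(mEnd, rpos + len - 1L)
            rpos <- rpos + len
        } else if (op == "D") {
            dStart <- c(dStart, rpos); dEnd <- c(dEnd, rpos + len - 1L)
            rpos <- rpos + len
        } else if (op == "I") {
            insAt <- c(insAt, rpos - 1L); insLen <- c(insLen, len)
        }
    }
    list(mStart = mStart, mEnd = mEnd, dStart = dStart, dEnd = dEnd,
         insAt = insAt, insLen = insLen)
}

# Query (read) offset of a reference position inside M segments, or NA.
queryOffsetAt <- function(pos, cigar, refPos) {
    p <- parseCigar(cigar)
    rpos <- pos; qpos <- 1L
    for (k in seq_along(p$ops)) {
        op <- p$ops[k]; len <- p$lens[k]
        if (op == "M") {
            if (refPos >= rpos && refPos < rpos + len)
                return(qpos + (refPos - rpos))
            rpos <- rpos + len; qpos <- qpos + len
        } else if (op == "D") {
            rpos <- rpos + len
        } else if (op %in% c("I", "S")) {
            qpos <- qpos + len
        }
    }
    NA_integer_
}

#' Per-site allelic balance at HET sites
#'
#' Classifies each read overlapping a HET site as REF-supporting,
#' ALT-supporting or uninformative. SNVs compare the read base aligned
#' over the site; indels test for the presence (ALT) or absence (REF)
#' of the corresponding I/D operation at the locus in the read's
#' reference-space CIGAR, requiring the read to span the full variant
#' interval. Balance is `ALT / (ALT + REF)`; uninformative reads are
#' excluded from the denominator, and sites with no informative read
#' are reported with `NA` balance (their number is in attribute
#' `nOmitted`).
#'
#' @param records reference-coordinate alignment data.frame.
#' @param hetSites phased variant data.frame of HET sites.
#' @return `hetSites` with added `nRef`, `nAlt`, `balance`.
#' @export
siteAllelicBalance <- function(records, hetSites) {
    records <- records[bitwAnd(records$flag, 4L) == 0L, , drop = FALSE]
    n <- nrow(hetSites)
    nRef <- integer(n); nAlt <- integer(n)
    if (nrow(records)) {
        spans <- IRanges::IRanges(
            start = records$pos,
            end = records$pos + vapply(records$cigar, cigarRefLength,
                                       numeric(1)) - 1L)
        siteEnd <- ifelse(nchar(hetSites$alt) > nchar(hetSites$ref),
                          hetSites$pos + nchar(hetSites$ref),
                          hetSites$pos + nchar(hetSites$ref) - 1L)
        siteRg <- IRanges::IRanges(start = hetSites$pos, end = siteEnd)
        hits <- IRanges::findOverlaps(siteRg, spans,
                                      type = "within")
        layouts <- lapply(seq_len(nrow(records)), function(i)
            readLayout(records$pos[i], records$cigar[i]))
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        for (h in seq_along(qh)) {
            si <- qh[h]
            ri <- sh[h]
            if (records$rname[ri] != hetSites$chrom[si]) next
            refA <- hetSites$ref[si]; altA <- hetSites$alt[si]
            pos <- hetSites$pos[si]
            lay <- layouts[[ri]]
            if (nchar(refA) == 1L && nchar(altA) == 1L) {   # SNV
                q <- queryOffsetAt(records$pos[ri],
                                   records$cigar[ri], pos)
                if (is.na(q)) next
                b <- substring(records$seq[ri], q, q)
                if (b == altA) nAlt[si] <- nAlt[si] + 1L
                else if (b == refA) nRef[si] <- nRef[si] + 1L
            } else if (nchar(altA) > nchar(refA)) {          # insertion
                insLen <- nchar(altA) - nchar(refA)
                anchor <- pos + nchar(refA) - 1L
                has <- any(lay$insAt == anchor & lay$insLen == insLen)
                if (has) {
                    nAlt[si] <- nAlt[si] + 1L
                } else {
                    # spans the junction in a single M segment
                    inM <- any(lay$mStart <= anchor &
                               lay$mEnd >= anchor + 1L)
                    if (inM) nRef[si] <- nRef[si] + 1L
                }
            } else {                                        # deletion
                delStart <- pos + nchar(altA)
                delEnd <- pos + nchar(refA) - 1L
                has <- any(lay$dStart == delStart &
                           lay$dEnd == delEnd)
                if (has) {
                    nAlt[si] <- nAlt[si] + 1L
                } else {
                    inM <- any(lay$mStart <= delStart &
                               lay$mEnd >= delEnd)
                    if (inM) nRef[si] <- nRef[si] + 1L
                }
            }
        }
    }
    out <- hetSites
    out$nRef <- nRef; out$nAlt <- nAlt
    out$balance <- ifelse(nRef + nAlt > 0L,
                          nAlt / (nRef + nAlt), NA_real_)
    attr(out, "nOmitted") <- sum(nRef + nAlt == 0L)
    out
}

#' Aggregate allelic balances into allele-length bins
#'
#' Length key is `len(ALT) - len(REF)` clamped to \[-30, 30\]: SNVs sit
#' at zero, deletions to the left, insertions to the right, and
#' variants beyond 30 bp share the terminal bins. Per bin the mean
#' balance, the 25th and 75th percentiles (linear interpolation between
#' order statistics) and the variant count are reported.
#'
#' @param balances output of [siteAllelicBalance()] (rows with `NA`
#'   balance are dropped).
#' @return data.frame `lengthKey`, `meanBalance`, `q25`, `q75`,
#'   `nVariants`, sorted by `lengthKey`.
#' @export
biasLengthBins <- function(balances) {
    x <- balances[!is.na(balances$balance), , drop = FALSE]
    key <- pmax(pmin(nchar(x$alt) - nchar(x$ref), 30L), -30L)
    sp <- split(x$balance, key)
    out <- data.frame(
        lengthKey = as.integer(names(sp)),
        meanBalance = vapply(sp, mean, numeric(1)),
        q25 = vapply(sp, function(v)
            unname(quantile(v, 0.25, type = 7)), numeric(1)),
        q75 = vapply(sp, function(v)
            unname(quantile(v, 0.75, type = 7)), numeric(1)),
        nVariants = vapply(sp, length, integer(1)))
    out <- out[order(out$lengthKey), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' QUAL-threshold ROC table
#'
#' At each threshold `t`, calls with `QUAL >= t` are retained and
#' compared with the truth set by exact biallelic match (site, alleles
#' and unordered genotype). The retained-call columns are
#' non-increasing in `t`. The table reports counts plus precision and
#' recall (recall doubles as the true-positive rate; no negative-site
#' universe is assumed, so no FPR denominator is imposed).
#'
#' @param calls scored call data.frame (`qual` required).
#' @param truth truth call data.frame.
#' @param thresholds numeric vector of QUAL thresholds.
#' @return data.frame per threshold: `threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
qualRocTable <- function(calls, truth, thresholds) {
    gkey <- function(x) paste(x$chrom, x$pos, x$ref, x$alt,
                              pmin(x$h1, x$h2), pmax(x$h1, x$h2))
    ck <- gkey(calls); tk <- gkey(truth)
    out <- lapply(thresholds, function(t) {
        kept <- ck[calls$qual >= t]
        tp <- sum(kept %in% tk)
        fp <- length(kept) - tp
        fn <- length(tk) - tp
        data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
                   precision = if (tp + fp > 0) tp / (tp + fp)
                               else NA_real_,
                   recall = if (tp + fn > 0) tp / (tp + fn)
                            else NA_real_)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
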