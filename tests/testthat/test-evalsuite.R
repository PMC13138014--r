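oneSite <- function(ch1, ch2, th1, th2) {
    sites <- data.frame(chrom = "ref", pos = 100L, ref = "A",
                        alt = "T", stringsAsFactors = FALSE)
    calls <- cbind(sites, data.frame(h1 = ch1, h2 = ch2))
    truth <- cbind(sites, data.frame(h1 = th1, h2 = th2))
    list(sites = sites, calls = calls, truth = truth)
}

test_that("allele-level accounting follows the per-allele rules", {
    x <- oneSite(0L, 1L, 1L, 1L)     # call 0/1, truth 1/1
    cc <- alleleAltConfusion(x$calls, x$truth, x$sites)
    expect_equal(cc[["tp"]], 1L)
    expect_equal(cc[["fn"]], 1L)
    x <- oneSite(1L, 1L, 0L, 0L)     # call 1/1, truth 0/0
    cc <- alleleAltConfusion(x$calls, x$truth, x$sites)
    expect_equal(cc[["fp"]], 2L)
    expect_equal(sum(cc), 2L)
})

test_that("HET-level accounting counts sites, not alleles", {
    x <- oneSite(0L, 1L, 0L, 1L)
    expect_equal(hetConfusion(x$calls, x$truth, x$sites)[["tp"]], 1L)
    x <- oneSite(1L, 1L, 0L, 1L)     # hom call at a true HET
    expect_equal(hetConfusion(x$calls, x$truth, x$sites)[["fn"]], 1L)
    g <- randomGenotypeTables(50L, 4L)
    cc <- hetConfusion(g$calls, g$calls, g$sites)
    expect_equal(cc[["fp"]] + cc[["fn"]], 0L)
})

test_that("confusion counts match the exhaustive case oracle", {
    for (seed in c(1L, 2L)) {
        g <- randomGenotypeTables(300L, seed)
        got <- alleleAltConfusion(g$calls, g$truth, g$sites)
        want <- oracleAlleleConfusion(g$calls$h1 + g$calls$h2,
                                      g$truth$h1 + g$truth$h2)
        expect_identical(got, want)
        expect_equal(sum(got), 2L * nrow(g$sites))
        gotH <- hetConfusion(g$calls, g$truth, g$sites)
        wantH <- oracleHetConfusion(g$calls$h1 + g$calls$h2,
                                    g$truth$h1 + g$truth$h2)
        expect_equal(unname(gotH), unname(wantH))
    }
})

test_that("missing calls and truth are closed as homozygous REF", {
    sites <- data.frame(chrom = "ref", pos = c(10L, 20L), ref = "A",
                        alt = "T", stringsAsFactors = FALSE)
    calls <- cbind(sites[1L, ], data.frame(h1 = 1L, h2 = 1L))
    truth <- cbind(sites[2L, ], data.frame(h1 = 1L, h2 = 0L))
    cc <- alleleAltConfusion(calls, truth, sites)
    # site 1: call 1/1 vs hom-REF truth -> 2 FP
    # site 2: missing call (0/0) vs HET truth -> 1 TN + 1 FN? no:
    # truth has one REF, so both REF calls are TN, none FN
    expect_equal(cc[["fp"]], 2L)
    expect_equal(cc[["fn"]], 0L)
    expect_equal(cc[["tn"]], 2L)
    expect_equal(sum(cc), 4L)
})

test_that("precision/recall/F1 formulas and edge cases hold", {
    prf <- prfFromCounts(c(tp = 9L, fp = 1L, fn = 3L))
    expect_equal(prf[["precision"]], 0.9)
    expect_equal(prf[["recall"]], 0.75)
    expect_equal(prf[["f1"]], 2 * 0.9 * 0.75 / 1.65)
    expect_true(is.na(prfFromCounts(c(tp = 0L, fp = 0L,
                                      fn = 3L))[["precision"]]))
    # harmonic-mean identity: P == R == x implies F1 == x
    for (x in c(0.2, 0.5, 0.99)) {
        n <- 1000L
        tp <- round(x * n)
        prf <- prfFromCounts(c(tp = tp, fp = n - tp, fn = n - tp))
        expect_equal(prf[["f1"]], prf[["precision"]])
    }
})

test_that("pivot windows collect the pivot plus left-neighbours", {
    sites <- data.frame(chrom = "ref", pos = c(1L, 101L, 151L),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
    w <- buildPivotWindows(sites, window = 200L)
    expect_equal(nrow(w), 3L)            # one window per pivot
    expect_equal(w$n, c(1L, 2L, 3L))     # pivot 151 reaches back to 1
    expect_equal(as.character(w$stratum), rep("1-5", 3L))
    # isolated site
    far <- data.frame(chrom = "ref", pos = c(1L, 500L), ref = "A",
                      alt = "T", stringsAsFactors = FALSE)
    wf <- buildPivotWindows(far, 200L)
    expect_equal(wf$n, c(1L, 1L))
    # strata partition the windows
    dense <- data.frame(chrom = "ref", pos = seq(1L, 400L, by = 20L),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
    wd <- buildPivotWindows(dense, 200L)
    expect_equal(sum(table(wd$stratum)), nrow(dense))
    expect_true(any(wd$stratum == "6-10"))
    expect_true(any(wd$stratum == "11+"))
})

test_that("window correctness allows one consistent label swap", {
    sites <- data.frame(chrom = "ref", pos = c(10L, 60L), ref = "A",
                        alt = "T", stringsAsFactors = FALSE)
    truth <- cbind(sites, data.frame(h1 = c(1L, 0L), h2 = c(0L, 1L)))
    w <- buildPivotWindows(sites, 200L)
    # identity scores 1.0 in every populated stratum
    wa <- windowAccuracy(truth, truth, w, sites)
    expect_true(all(wa$accuracy[wa$nWindows > 0L] == 1))
    # both HETs phase-flipped: the global swap repairs the window
    flipped <- truth; flipped$h1 <- truth$h2; flipped$h2 <- truth$h1
    wa <- windowAccuracy(flipped, truth, w, sites)
    expect_equal(wa$nCorrect[1L], wa$nWindows[1L])
    # exactly one site flipped: no single assignment fits
    half <- truth; half$h1[2L] <- truth$h2[2L]; half$h2[2L] <- truth$h1[2L]
    wa <- windowAccuracy(half, truth, w, sites)
    expect_equal(wa$nCorrect[1L], 1L)  # only the isolated first pivot
})

test_that("window correctness equals the two-assignment enumeration oracle", {
    set.seed(31)
    g <- randomGenotypeTables(120L, 31L)
    w <- buildPivotWindows(g$sites, 200L)
    wa <- windowAccuracy(g$calls, g$truth, w, g$sites)
    correctOracle <- vapply(seq_len(nrow(w)), function(i) {
        idx <- w$from[i]:w$to[i]
        id <- all(g$calls$h1[idx] == g$truth$h1[idx] &
                  g$calls$h2[idx] == g$truth$h2[idx])
        sw <- all(g$calls$h1[idx] == g$truth$h2[idx] &
                  g$calls$h2[idx] == g$truth$h1[idx])
        id || sw
    }, logical(1))
    for (s in c("1-5", "6-10", "11+")) {
        inS <- w$stratum == s
        expect_equal(wa$nCorrect[wa$stratum == s], sum(correctOracle[inS]))
    }
})

test_that("injected genotype errors never increase window accuracy", {
    cfg <- simConfig(refLength = 20000L, nSnv = 100L, nIndel = 0L,
                     nSv = 0L, seed = 41L)
    ts <- simulateTruth(cfg)
    v <- truthVariants(ts)
    sites <- v[, c("chrom", "pos", "ref", "alt")]
    w <- buildPivotWindows(sites, 200L)
    base <- windowAccuracy(v, v, w, sites)$accuracy
    set.seed(41)
    err <- v
    order <- sample.int(nrow(v))
    prev <- base
    for (k in 1:10) {
        i <- order[k]
        err$h1[i] <- 1L - err$h1[i]
        wa <- windowAccuracy(err, v, w, sites)$accuracy
        ok <- is.na(wa) | is.na(prev) | wa <= prev
        expect_true(all(ok))
        prev <- wa
    }
})

test_that("allelic balance counts supporting reads per HET site", {
    het <- data.frame(chrom = "ref", pos = 50L, ref = "A", alt = "T",
                      h1 = 1L, h2 = 0L, stringsAsFactors = FALSE)
    mk <- function(n, base) do.call(rbind, lapply(seq_len(n), function(i)
        data.frame(qname = paste0(base, i), flag = 0L, rname = "ref",
                   pos = 41L, mapq = 60L, cigar = "20M",
                   seq = paste0(strrep("C", 9L), base,
                                strrep("C", 10L)),
                   score = 20L, stringsAsFactors = FALSE)))
    bal <- siteAllelicBalance(rbind(mk(10L, "T"), mk(10L, "A")), het)
    expect_equal(bal$balance, 0.5)
    bal <- siteAllelicBalance(mk(8L, "A"), het)
    expect_equal(bal$balance, 0)
    # neither-allele reads are uninformative
    bal <- siteAllelicBalance(mk(4L, "G"), het)
    expect_true(is.na(bal$balance))
    expect_equal(attr(bal, "nOmitted"), 1L)
})

test_that("indel balance classifies by gap ops at the locus", {
    # deletion of ref 51..52, anchored at 50
    het <- data.frame(chrom = "ref", pos = 50L, ref = "AGG", alt = "A",
                      h1 = 1L, h2 = 0L, stringsAsFactors = FALSE)
    alt <- data.frame(qname = "a", flag = 0L, rname = "ref", pos = 41L,
                      mapq = 60L, cigar = "10M2D10M",
                      seq = strrep("C", 20L), score = 20L)
    ref <- data.frame(qname = "r", flag = 0L, rname = "ref", pos = 41L,
                      mapq = 60L, cigar = "20M", seq = strrep("C", 20L),
                      score = 20L)
    bal <- siteAllelicBalance(rbind(alt, ref), het)
    expect_equal(bal$nAlt, 1L)
    expect_equal(bal$nRef, 1L)
    # insertion after pos 50
    hetI <- data.frame(chrom = "ref", pos = 50L, ref = "A", alt = "ATT",
                       h1 = 1L, h2 = 0L, stringsAsFactors = FALSE)
    altI <- data.frame(qname = "ai", flag = 0L, rname = "ref",
                       pos = 41L, mapq = 60L, cigar = "10M2I8M",
                       seq = strrep("C", 20L), score = 20L)
    bal <- siteAllelicBalance(rbind(altI, ref), hetI)
    expect_equal(bal$nAlt, 1L)
    expect_equal(bal$nRef, 1L)
})

test_that("simulated balanced coverage yields balance near one half", {
    cfg <- simConfig(refLength = 20000L, nSnv = 100L, nIndel = 0L,
                     nSv = 0L, hetFraction = 1, coverage = 20,
                     errorRate = 0, seed = 51L)
    ts <- simulateTruth(cfg)
    rd <- simulateReads(ts, cfg)
    dr <- buildDiploidReference(setNames(ts@reference, ts@refName),
                                truthVariants(ts))
    refAln <- rbind(
        liftAlignments(dr@chain1,
                       rd$alignments[rd$alignments$rname == "hap1", ]),
        liftAlignments(dr@chain2,
                       rd$alignments[rd$alignments$rname == "hap2", ]))
    bal <- siteAllelicBalance(refAln, truthVariants(ts))
    n <- sum(bal$nRef + bal$nAlt)
    expect_gt(n / nrow(bal), 30)
    p <- sum(bal$nAlt) / n
    expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
})

test_that("length bins clamp at 30 and handle degenerate bins", {
    mkBal <- function(ref, alt, balance)
        data.frame(chrom = "ref", pos = 1L, ref = ref, alt = alt,
                   h1 = 1L, h2 = 0L, nRef = 5L, nAlt = 5L,
                   balance = balance, stringsAsFactors = FALSE)
    snv <- mkBal("A", "T", 0.5)
    bigDel <- mkBal(paste0("A", strrep("C", 35L)), "A", 0.25)
    ins <- mkBal("A", "ATT", 0.75)
    bins <- biasLengthBins(rbind(snv, bigDel, ins))
    expect_equal(bins$lengthKey, c(-30L, 0L, 2L))
    one <- bins[bins$lengthKey == -30L, ]
    expect_equal(one$meanBalance, 0.25)
    expect_equal(one$q25, 0.25)
    expect_equal(one$q75, 0.25)
    expect_equal(one$nVariants, 1L)
})

test_that("the QUAL ROC table matches a filter-then-count oracle", {
    set.seed(61)
    g <- randomGenotypeTables(200L, 61L)
    calls <- g$calls
    calls$qual <- round(runif(200L, 0, 60), 1)
    truth <- g$truth[g$truth$h1 + g$truth$h2 > 0L, ]
    thr <- c(0, 15, 30, 45, 60, 70)
    roc <- qualRocTable(calls, truth, thr)
    key <- function(x) paste(x$pos, pmin(x$h1, x$h2), pmax(x$h1, x$h2))
    for (i in seq_along(thr)) {
        kept <- calls[calls$qual >= thr[i], ]
        tp <- sum(key(kept) %in% key(truth))
        expect_equal(roc$tp[i], tp)
        expect_equal(roc$fp[i], nrow(kept) - tp)
        expect_equal(roc$fn[i], nrow(truth) - tp)
    }
    # identity threshold keeps everything; beyond-max keeps nothing
    expect_equal(roc$tp[1L] + roc$fp[1L], nrow(calls))
    expect_equal(roc$tp[length(thr)], 0L)
    expect_equal(roc$fn[length(thr)], nrow(truth))
    # monotone in the threshold
    expect_true(all(diff(roc$tp) <= 0))
    expect_true(all(diff(roc$fp) <= 0))
})
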