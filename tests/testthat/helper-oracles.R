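# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately written as literal case enumerations or
# brute-force recounts, sharing no code with the package internals.

# Allele-level confusion by explicit enumeration of all 3x3 genotype
# cases (call dosage x truth dosage), one site at a time.
oracleAlleleConfusion <- function(callDose, truthDose) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(callDose)) {
        cd <- callDose[i]; td <- truthDose[i]
        for (allele in c(rep(1L, cd), rep(0L, 2L - cd))) {
            if (allele == 1L) {
                if (td >= 1L) tp <- tp + 1L else fp <- fp + 1L
            } else {
                if (td == 2L) fn <- fn + 1L else tn <- tn + 1L
            }
        }
    }
    c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracleHetConfusion <- function(callDose, truthDose) {
    cHet <- callDose == 1L; tHet <- truthDose == 1L
    c(tp = sum(cHet & tHet), fp = sum(cHet & !tHet),
      fn = sum(!cHet & tHet), tn = sum(!cHet & !tHet))
}

# A synthetic SNV site universe with genotypes drawn per haplotype.
randomGenotypeTables <- function(nSites, seed) {
    set.seed(seed)
    sites <- data.frame(chrom = "ref",
                        pos = sort(sample.int(nSites * 50L, nSites)),
                        ref = sample(c("A", "C", "G", "T"), nSites,
                                     replace = TRUE),
                        alt = "T", stringsAsFactors = FALSE)
    gt <- function() cbind(sample(0:1, nSites, TRUE),
                           sample(0:1, nSites, TRUE))
    cg <- gt(); tg <- gt()
    calls <- cbind(sites, data.frame(h1 = cg[, 1], h2 = cg[, 2]))
    truth <- cbind(sites, data.frame(h1 = tg[, 1], h2 = tg[, 2]))
    list(sites = sites, calls = calls, truth = truth)
}

# Build a panel whose first two rows are exactly the truth haplotypes
# and whose remaining rows are truth alleles flipped independently.
panelWithTruth <- function(truth, nHap = 20L, flip = 0.3, seed = 1L) {
    v <- truthVariants(truth)
    S <- nrow(v)
    hap <- matrix(0L, nrow = nHap, ncol = S)
    hap[1L, ] <- v$h1
    hap[2L, ] <- v$h2
    set.seed(seed)
    for (k in 3:nHap) {
        src <- if (k %% 2L == 1L) v$h1 else v$h2
        fl <- runif(S) < flip
        hap[k, ] <- ifelse(fl, 1L - src, src)
    }
    new("PanelMatrix", sites = v[, c("chrom", "pos", "ref", "alt")],
        haplotypes = hap,
        sampleIds = sprintf("P%02d", seq_len(nHap %/% 2L)))
}

# Error-free rough calls at a fraction of the truth sites.
roughFromTruth <- function(truth, fraction, seed = 1L, qual = 50) {
    v <- truthVariants(truth)
    set.seed(seed)
    n <- max(1L, round(fraction * nrow(v)))
    idx <- sort(sample.int(nrow(v), n))
    out <- v[idx, , drop = FALSE]
    out$qual <- qual
    out$depth <- 30L
    rownames(out) <- NULL
    out
}

# Reconstruct per-base reference positions consumed by the M ops of a
# lifted alignment; used as the per-base liftover oracle counterpart.
mBaseRefPositions <- function(pos, cigar) {
    num <- as.integer(regmatches(cigar,
        gregexpr("[0-9]+", cigar))[[1L]])
    op <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1L]]
    refs <- integer(0)
    r <- pos
    for (k in seq_along(op)) {
        if (op[k] == "M") {
            refs <- c(refs, r:(r + num[k] - 1L))
            r <- r + num[k]
        } else if (op[k] == "D") {
            r <- r + num[k]
        }
    }
    refs
}

# Query-consuming length of a CIGAR, computed with regexes only.
queryLenOf <- function(cigar) {
    num <- as.integer(regmatches(cigar,
        gregexpr("[0-9]+", cigar))[[1L]])
    op <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1L]]
    sum(num[op %in% c("M", "I", "S")])
}

# Dosage concordance between two variant tables over the first's sites.
doseConcordance <- function(a, b) {
    key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
    idx <- match(key(a), key(b))
    da <- a$h1 + a$h2
    db <- ifelse(is.na(idx), 0L, b$h1[idx] + b$h2[idx])
    mean(da == db)
}
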