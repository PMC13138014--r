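# Shared internal helpers: seeded RNG scoping, CIGAR handling, small
# sequence utilities.

BASES <- c("A", "C", "G", "T")

# Evaluate expr under a local RNG stream; restores the caller's RNG state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Derive a sub-seed for a named stage from a master seed, kept < 2^31.
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

randomSeq <- function(n) {
    paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# CIGAR string -> list(ops = character, lens = integer)
parseCigar <- function(cigar) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
    list(ops = ops, lens = lens)
}

unparseCigar <- function(ops, lens) {
    keep <- lens > 0L
    ops <- ops[keep]; lens <- lens[keep]
    if (!length(ops)) return("*")
    # merge adjacent identical ops
    r <- rle(ops)
    if (any(r$lengths > 1L)) {
        idx <- rep(seq_along(r$values), r$lengths)
        lens <- as.integer(tapply(lens, idx, sum))
        ops <- r$values
    }
    paste0(lens, ops, collapse = "")
}

cigarQueryLength <- function(cigar) {
    p <- parseCigar(cigar)
    sum(p$lens[p$ops %in% c("M", "I", "S", "=", "X")])
}

cigarRefLength <- function(cigar) {
    p <- parseCigar(cigar)
    sum(p$lens[p$ops %in% c("M", "D", "=", "X")])
}

phred <- function(pErr) {
    q <- -10 * log10(pmax(pErr, 1e-10))
    pmin(q, 99)
}

# Vectorised per-base mismatch count between a read and a reference
# window of equal length.
countMismatches <- function(read, refWindow) {
    a <- utf8ToInt(read); b <- utf8ToInt(refWindow)
    if (length(a) != length(b)) stop("length mismatch")
    sum(a != b)
}

emptyVariantTable <- function() {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), h1 = integer(), h2 = integer(),
               stringsAsFactors = FALSE)
}

# Align calls/truth tables onto a site universe by chrom+pos+alleles;
# missing rows are filled as homozygous REF (the only closure that keeps
# the accounting total fixed).
genotypesAtSites <- function(tab, sites) {
    key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
    tkey <- paste(tab$chrom, tab$pos, tab$ref, tab$alt)
    idx <- match(key, tkey)
    h1 <- ifelse(is.na(idx), 0L, tab$h1[idx])
    h2 <- ifelse(is.na(idx), 0L, tab$h2[idx])
    if (any(!h1 %in% c(0L, 1L)) || any(!h2 %in% c(0L, 1L)))
        stop("allele index outside {0,1}: biallelic contract violated")
    data.frame(h1 = as.integer(h1), h2 = as.integer(h2))
}
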