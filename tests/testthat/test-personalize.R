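test_that("planEdits turns phased SNV calls into per-haplotype edits", {
    calls <- data.frame(chrom = "ref", pos = 2L, ref = "C", alt = "T",
                        h1 = 1L, h2 = 0L)
    p1 <- planEdits("ACGT", calls, 1L)
    expect_equal(p1$start, 2L)
    expect_equal(p1$len, 1L)
    expect_equal(p1$replacement, "T")
    p2 <- planEdits("ACGT", calls, 2L)
    expect_equal(nrow(p2), 0L)
})

test_that("planEdits rejects REF mismatches naming the locus", {
    calls <- data.frame(chrom = "ref", pos = 2L, ref = "G", alt = "T",
                        h1 = 1L, h2 = 1L)
    expect_error(planEdits("ACGT", calls, 1L), "ref:2")
})

test_that("planEdits rejects symbolic ALT alleles", {
    calls <- data.frame(chrom = "ref", pos = 2L, ref = "C",
                        alt = "<DEL>", h1 = 1L, h2 = 1L)
    expect_error(planEdits("ACGT", calls, 1L), "symbolic")
})

test_that("overlapping calls resolve leftmost-wins with a warning", {
    ref <- "ACGTACGTAC"
    calls <- data.frame(chrom = "ref", pos = c(2L, 4L),
                        ref = c("CGTA", "TA"), alt = c("C", "T"),
                        h1 = c(1L, 1L), h2 = c(0L, 0L))
    expect_warning(p <- planEdits(ref, calls, 1L), "leftmost")
    expect_equal(nrow(p), 1L)
    # oracle: exhaustively assert pairwise non-overlap of the kept plan
    if (nrow(p) > 1L)
        for (i in seq_len(nrow(p) - 1L))
            expect_true(p$start[i + 1L] >
                        p$start[i] + max(p$len[i] - 1L, 0L))
})

test_that("applyEdits identity: empty plan gives one full match block", {
    ref <- paste(rep("ACGT", 25L), collapse = "")
    empty <- planEdits(ref, data.frame(chrom = character(),
        pos = integer(), ref = character(), alt = character(),
        h1 = integer(), h2 = integer()), 1L)
    out <- applyEdits(ref, empty)
    expect_identical(out$seq, ref)
    b <- chainBlocks(out$chain)
    expect_equal(nrow(b), 1L)
    expect_equal(b$size, 100L)
    expect_equal(b$dSource + b$dTarget, 0L)
})

test_that("a deletion shortens the haplotype and shifts the map", {
    set.seed(3)
    ref <- paste(sample(c("A", "C", "G", "T"), 100L, TRUE),
                 collapse = "")
    # delete ref bases 11..13 (anchor at 10, VCF-style)
    calls <- data.frame(chrom = "ref", pos = 10L,
                        ref = substr(ref, 10L, 13L),
                        alt = substr(ref, 10L, 10L),
                        h1 = 1L, h2 = 0L)
    out <- applyEdits(ref, planEdits(ref, calls, 1L))
    expect_equal(nchar(out$seq), 97L)
    m <- provenanceMap(out$chain)
    # oracle: per-base provenance carried through the edit by hand
    expected <- c(1:10, 14:100)
    expect_identical(m, as.integer(expected))
    expect_identical(out$seq, paste0(substr(ref, 1, 10),
                                     substr(ref, 14, 100)))
})

test_that("an insertion lengthens the haplotype; downstream lifts shift", {
    set.seed(4)
    ref <- paste(sample(c("A", "C", "G", "T"), 60L, TRUE),
                 collapse = "")
    ins <- "TTTTT"
    calls <- data.frame(chrom = "ref", pos = 20L,
                        ref = substr(ref, 20L, 20L),
                        alt = paste0(substr(ref, 20L, 20L), ins),
                        h1 = 1L, h2 = 0L)
    out <- applyEdits(ref, planEdits(ref, calls, 1L))
    expect_equal(nchar(out$seq), 65L)
    m <- provenanceMap(out$chain)
    expect_identical(m[1:20], 1:20)
    expect_true(all(is.na(m[21:25])))
    # right of the insertion every haplotype position maps back by -5
    right <- 26:65
    expect_identical(m[right], right - 5L)
})

test_that("SNVs stay inside match blocks (no chain gap)", {
    ref <- strrep("ACGT", 30L)
    calls <- data.frame(chrom = "ref", pos = c(10L, 50L),
                        ref = c(substr(ref, 10, 10), substr(ref, 50, 50)),
                        alt = c("T", "A"), h1 = c(1L, 1L), h2 = c(1L, 1L))
    calls$alt <- ifelse(calls$alt == calls$ref, "C", calls$alt)
    out <- applyEdits(ref, planEdits(ref, calls, 1L))
    expect_equal(nrow(chainBlocks(out$chain)), 1L)
    expect_equal(nchar(out$seq), nchar(ref))
})

test_that("homozygous and heterozygous calls land on the right haplotypes", {
    ref <- c(ref = "AACGGTTCAA")
    hom <- data.frame(chrom = "ref", pos = 3L, ref = "C", alt = "A",
                      h1 = 1L, h2 = 1L)
    dr <- buildDiploidReference(ref, hom)
    expect_identical(substr(dr@hap1, 3, 3), "A")
    expect_identical(substr(dr@hap2, 3, 3), "A")
    het <- data.frame(chrom = "ref", pos = 3L, ref = "C", alt = "A",
                      h1 = 1L, h2 = 0L)
    dr <- buildDiploidReference(ref, het)
    expect_false(dr@hap1 == dr@hap2)
    expect_identical(dr@hap2, unname(ref))
})

test_that("unphased VCF input is rejected before consensus", {
    ref <- c(ref = "AACGGTTCAA")
    f <- tempfile(fileext = ".vcf")
    calls <- data.frame(chrom = "ref", pos = 3L, ref = "C", alt = "A",
                        h1 = 0L, h2 = 1L)
    writeVcf(calls, c(ref = 10L), f, phased = FALSE)
    expect_error(buildDiploidReference(ref, f), "unphased")
})

test_that("consensus round-trips the simulator across variant mixes", {
    for (seed in 1:10) {
        cfg <- simConfig(refLength = 15000L, nSnv = 40L, nIndel = 15L,
                         nSv = 2L, hetFraction = 0.6, seed = seed)
        ts <- simulateTruth(cfg)
        dr <- buildDiploidReference(setNames(ts@reference, ts@refName),
                                    truthVariants(ts))
        expect_identical(dr@hap1, ts@hap1)
        expect_identical(dr@hap2, ts@hap2)
        v <- truthVariants(ts)
        for (h in 1:2) {
            ch <- slot(dr, paste0("chain", h))
            b <- chainBlocks(ch)
            expect_equal(sum(b$size) + sum(b$dSource), ch@sourceLength)
            expect_equal(sum(b$size) + sum(b$dTarget), ch@targetLength)
            applied <- v[v[[paste0("h", h)]] == 1L, ]
            expect_equal(nchar(slot(dr, paste0("hap", h))) -
                         nchar(ts@reference),
                         sum(nchar(applied$alt) - nchar(applied$ref)))
        }
    }
})

test_that("written chains are accepted and round-tripped by the strict parser", {
    cfg <- simConfig(refLength = 8000L, nSnv = 20L, nIndel = 8L,
                     nSv = 1L, seed = 17L)
    ts <- simulateTruth(cfg)
    dr <- buildDiploidReference(setNames(ts@reference, ts@refName),
                                truthVariants(ts))
    f <- tempfile(fileext = ".chain")
    writeChain(dr@chain1, f)
    back <- readChain(f)
    expect_identical(chainBlocks(back), chainBlocks(dr@chain1))
    expect_identical(back@sourceLength, dr@chain1@sourceLength)
    expect_identical(back@source, "hap1")
    # corrupt the block arithmetic; the parser must refuse
    x <- readLines(f)
    row <- which(grepl("^[0-9]+ [0-9]+ [0-9]+$", x))[1L]
    parts <- as.integer(strsplit(x[row], " ")[[1L]])
    x[row] <- paste(parts[1L] + 1L, parts[2L], parts[3L])
    writeLines(x, f)
    expect_error(readChain(f), "span mismatch")
})

test_that("chain match blocks pair identical substrings for indel-only edits", {
    cfg <- simConfig(refLength = 10000L, nSnv = 0L, nIndel = 20L,
                     nSv = 2L, seed = 23L)
    ts <- simulateTruth(cfg)
    dr <- buildDiploidReference(setNames(ts@reference, ts@refName),
                                truthVariants(ts))
    b <- chainBlocks(dr@chain1)
    s <- 1L; t <- 1L
    for (i in seq_len(nrow(b))) {
        if (b$size[i] > 0L)
            expect_identical(
                substr(dr@hap1, s, s + b$size[i] - 1L),
                substr(ts@reference, t, t + b$size[i] - 1L))
        s <- s + b$size[i] + b$dSource[i]
        t <- t + b$size[i] + b$dTarget[i]
    }
})

test_that("inverting a chain swaps the roles exactly", {
    cfg <- simConfig(refLength = 5000L, nSnv = 10L, nIndel = 5L,
                     nSv = 1L, seed = 31L)
    ts <- simulateTruth(cfg)
    dr <- buildDiploidReference(setNames(ts@reference, ts@refName),
                                truthVariants(ts))
    inv <- invertChain(dr@chain1)
    expect_identical(inv@sourceLength, dr@chain1@targetLength)
    expect_identical(invertChain(inv)@blocks, dr@chain1@blocks)
    # composition: map hap -> ref -> hap is the identity on matched bases
    m <- provenanceMap(dr@chain1)
    mi <- provenanceMap(inv)
    ok <- !is.na(m)
    expect_identical(mi[m[ok]], which(ok))
})
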