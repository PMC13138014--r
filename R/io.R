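# Standard-format input/output: FASTA/FASTQ through Biostrings, VCF 4.2
# (minimal writer; reading through vcfR), SAM text records, UCSC chain
# files.

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return named character vector.
#' @export
readFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
}

#' Write reads to FASTQ
#'
#' Constant base qualities are emitted; the simulator's error process is
#' per-base substitution at a flat rate, so qualities carry no signal.
#'
#' @param reads data.frame with columns `qname`, `seq`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFastq <- function(reads, path) {
    n <- nrow(reads)
    out <- character(4L * n)
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$qname)
    out[seq(2L, by = 4L, length.out = n)] <- reads$seq
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <-
        vapply(nchar(reads$seq), function(k)
            strrep("I", k), character(1))
    writeLines(out, path)
    invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ path.
#' @return data.frame with `qname`, `seq`.
#' @export
readFastq <- function(path) {
    x <- readLines(path)
    n <- length(x) %/% 4L
    data.frame(qname = sub("^@", "", x[seq(1L, by = 4L, length.out = n)]),
               seq = x[seq(2L, by = 4L, length.out = n)],
               stringsAsFactors = FALSE)
}

vcfHeader <- function(refLengths, extra = character(),
                      samples = "SAMPLE") {
    c("##fileformat=VCFv4.2",
      paste0("##contig=<ID=", names(refLengths),
             ",length=", unname(refLengths), ">"),
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      extra,
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t"))
}

#' Write a phased (or unphased rough) call set as VCF 4.2
#'
#' @param variants variant data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `h1`, `h2`, optional `qual`, `depth`).
#' @param refLengths named integer vector of contig lengths.
#' @param path output path.
#' @param phased emit `|`-separated GT (default) or `/`-separated.
#' @param sampleName sample column name.
#' @param comments extra `##`-header lines (e.g. generation parameters).
#' @return invisibly, `path`.
#' @export
writeVcf <- function(variants, refLengths, path, phased = TRUE,
                     sampleName = "SAMPLE", comments = character()) {
    sep <- if (phased) "|" else "/"
    qual <- if ("qual" %in% names(variants))
        sprintf("%.4g", variants$qual) else rep(".", nrow(variants))
    info <- if ("depth" %in% names(variants))
        paste0("DP=", variants$depth) else rep(".", nrow(variants))
    gt <- paste0(variants$h1, sep, variants$h2)
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, qual, "PASS", info, "GT", gt, sep = "\t")
    writeLines(c(vcfHeader(refLengths,
                           extra = paste0("##", comments),
                           samples = sampleName),
                 body), path)
    invisible(path)
}

#' Write a multi-sample phased panel as VCF 4.2
#'
#' @param panel a [PanelMatrix-class].
#' @param refLengths named contig lengths.
#' @param path output path.
#' @param comments extra header comment lines.
#' @return invisibly, `path`.
#' @export
writePanelVcf <- function(panel, refLengths, path,
                          comments = character()) {
    s <- panel@sites
    h <- panel@haplotypes
    ns <- length(panel@sampleIds)
    gt <- vapply(seq_len(ns), function(k)
        paste0(h[2L * k - 1L, ], "|", h[2L * k, ]), character(nrow(s)))
    if (nrow(s) == 1L) gt <- matrix(gt, nrow = 1L)
    body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".",
                  "GT", apply(gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(vcfHeader(refLengths, extra = paste0("##", comments),
                           samples = panel@sampleIds), body), path)
    invisible(path)
}

#' Read a single-sample VCF into the phased variant table
#'
#' @param path VCF path.
#' @param requirePhased fail on any `/`-separated GT, naming the record.
#' @return variant data.frame with `h1`, `h2` and, when present,
#'   `qual`, `depth`.
#' @export
readVcfCalls <- function(path, requirePhased = FALSE) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(emptyVariantTable())
    gtm <- vcfR::extract.gt(v, element = "GT")
    gt <- gtm[, 1L]
    unph <- grepl("/", gt, fixed = TRUE)
    if (requirePhased && any(unph))
        stop("unphased genotype at ", fix$CHROM[which(unph)[1L]], ":",
             fix$POS[which(unph)[1L]], " (GT '", gt[which(unph)[1L]],
             "'): phased `|` genotypes required")
    al <- strsplit(gt, "[|/]")
    out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      h1 = as.integer(vapply(al, `[`, "", 1L)),
                      h2 = as.integer(vapply(al, `[`, "", 2L)),
                      stringsAsFactors = FALSE)
    if (!all(is.na(fix$QUAL))) out$qual <- as.numeric(fix$QUAL)
    dp <- sub(".*DP=([0-9]+).*", "\\1", fix$INFO)
    if (any(grepl("DP=", fix$INFO))) out$depth <- as.integer(dp)
    rownames(out) <- NULL
    out
}

#' Read a multi-sample phased VCF into a PanelMatrix
#'
#' @param path VCF path.
#' @return a [PanelMatrix-class].
#' @export
readPanelVcf <- function(path) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    gtm <- vcfR::extract.gt(v, element = "GT")
    if (any(grepl("/", gtm, fixed = TRUE)))
        stop("panel VCF contains unphased genotypes")
    ns <- ncol(gtm)
    hap <- matrix(0L, nrow = 2L * ns, ncol = nrow(fix))
    for (k in seq_len(ns)) {
        al <- strsplit(gtm[, k], "|", fixed = TRUE)
        hap[2L * k - 1L, ] <- as.integer(vapply(al, `[`, "", 1L))
        hap[2L * k, ] <- as.integer(vapply(al, `[`, "", 2L))
    }
    new("PanelMatrix",
        sites = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT,
                           stringsAsFactors = FALSE),
        haplotypes = hap, sampleIds = colnames(gtm))
}

#' Write alignment records as SAM
#'
#' @param records alignment data.frame (`qname`, `flag`, `rname`, `pos`
#'   1-based, `mapq`, `cigar`, `seq`, optional `score` emitted as
#'   `AS:i:`, optional `source` emitted as `rc:Z:`).
#' @param refLengths named contig lengths for `@SQ` lines.
#' @param path output path.
#' @param comments `@CO` lines (generation parameters).
#' @return invisibly, `path`.
#' @export
writeSam <- function(records, refLengths, path, comments = character()) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", names(refLengths), "\tLN:",
                    unname(refLengths)),
             if (length(comments)) paste0("@CO\t", comments))
    tags <- character(nrow(records))
    if ("score" %in% names(records))
        tags <- paste0("\tAS:i:", records$score)
    if ("source" %in% names(records))
        tags <- paste0(tags, "\trc:Z:", records$source)
    body <- paste0(records$qname, "\t", records$flag, "\t",
                   records$rname, "\t", records$pos, "\t",
                   records$mapq, "\t", records$cigar,
                   "\t*\t0\t0\t", records$seq, "\t*", tags)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a SAM file into an alignment data.frame
#'
#' @param path SAM path.
#' @return data.frame with the mandatory columns plus `score` (from
#'   `AS:i:`, NA when absent).
#' @export
readSam <- function(path) {
    x <- readLines(path)
    x <- x[!startsWith(x, "@")]
    if (!length(x))
        return(data.frame(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          seq = character(), score = integer(),
                          stringsAsFactors = FALSE))
    f <- strsplit(x, "\t", fixed = TRUE)
    getf <- function(i) vapply(f, `[`, "", i)
    score <- vapply(f, function(v) {
        as_ <- grep("^AS:i:", v[-(1:11)], value = TRUE)
        if (length(as_)) as.integer(sub("AS:i:", "", as_[1L])) else NA_integer_
    }, integer(1))
    data.frame(qname = getf(1L), flag = as.integer(getf(2L)),
               rname = getf(3L), pos = as.integer(getf(4L)),
               mapq = as.integer(getf(5L)), cigar = getf(6L),
               seq = getf(10L), score = score, stringsAsFactors = FALSE)
}

#' Write a chain in the UCSC dialect
#'
#' Coordinates in the file are 0-based half-open per the UCSC
#' convention; the header lists target (reference) then query
#' (haplotype) with `size dt dq` triples, `dt` the reference gap and
#' `dq` the haplotype gap after each block.
#'
#' @param chain a [Chain-class].
#' @param path output path.
#' @param id chain id field.
#' @return invisibly, `path`.
#' @export
writeChain <- function(chain, path, id = 1L) {
    b <- chain@blocks
    hdr <- paste("chain", sum(b$size), chain@target, chain@targetLength,
                 "+", 0L, chain@targetLength, chain@source,
                 chain@sourceLength, "+", 0L, chain@sourceLength, id)
    n <- nrow(b)
    body <- if (n > 1L)
        paste(b$size[-n], b$dTarget[-n], b$dSource[-n]) else character()
    writeLines(c(hdr, body, as.character(b$size[n]), ""), path)
    invisible(path)
}

#' Strictly parse a UCSC chain file
#'
#' Validates the block arithmetic against the header lengths and spans.
#'
#' @param path chain path.
#' @return a [Chain-class].
#' @export
readChain <- function(path) {
    x <- readLines(path)
    x <- x[nzchar(x)]
    hdr <- strsplit(x[1L], " +")[[1L]]
    if (hdr[1L] != "chain" || length(hdr) < 13L)
        stop("malformed chain header: ", x[1L])
    tName <- hdr[3L]; tSize <- as.integer(hdr[4L])
    qName <- hdr[8L]; qSize <- as.integer(hdr[9L])
    tSpan <- as.integer(hdr[7L]) - as.integer(hdr[6L])
    qSpan <- as.integer(hdr[12L]) - as.integer(hdr[11L])
    rows <- strsplit(x[-1L], "[ \t]+")
    size <- vapply(rows, function(r) as.integer(r[1L]), integer(1))
    dT <- vapply(rows, function(r)
        if (length(r) >= 3L) as.integer(r[2L]) else 0L, integer(1))
    dQ <- vapply(rows, function(r)
        if (length(r) >= 3L) as.integer(r[3L]) else 0L, integer(1))
    if (length(rows[[length(rows)]]) != 1L)
        stop("terminal chain line must be a bare block size")
    if (sum(size) + sum(dT) != tSpan)
        stop("chain target span mismatch")
    if (sum(size) + sum(dQ) != qSpan)
        stop("chain query span mismatch")
    new("Chain", source = qName, sourceLength = qSize,
        target = tName, targetLength = tSize,
        blocks = data.frame(size = size, dSource = dQ, dTarget = dT))
}
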