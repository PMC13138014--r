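# Panel-based phased genotype imputation: panel hygiene (sample
# exclusion), a minimal built-in haplotype-pair imputer, and an adapter
# contract for external imputation engines.

#' Exclude samples (and their haplotype rows) from a panel
#'
#' Both haplotype rows of every excluded sample are removed; sites are
#' unchanged. Ids absent from the panel produce a warning, not a
#' failure. Excluding a donor's own sample (and family members) from
#' the panel before imputing that donor avoids unrealistically accurate
#' self-imputation; family membership is supplied explicitly, never
#' inferred.
#'
#' @param panel a [PanelMatrix-class].
#' @param excludedIds character vector of sample ids to remove.
#' @return the reduced [PanelMatrix-class].
#' @export
excludeSamples <- function(panel, excludedIds) {
    absent <- setdiff(excludedIds, panel@sampleIds)
    if (length(absent))
        warning("id(s) not in panel, ignored: ",
                paste(absent, collapse = ", "))
    drop <- panel@sampleIds %in% excludedIds
    if (all(drop))
        stop("excluding all samples would leave an empty panel")
    rows <- rep(!drop, each = 2L)
    new("PanelMatrix", sites = panel@sites,
        haplotypes = panel@haplotypes[rows, , drop = FALSE],
        sampleIds = panel@sampleIds[!drop])
}

#' Impute a phased diploid from rough calls and a haplotype panel
#'
#' Panel sites are partitioned into consecutive chunks of `chunkSize`.
#' Within each chunk, every ordered pair of distinct panel haplotypes
#' is scored by weighted agreement with the rough calls: a rough
#' genotype agrees with a candidate pair at a site when the allele
#' multisets coincide, and contributes `min(qual, 50)` to the score
#' (sites without a rough call contribute nothing). The best pair wins;
#' ties go to the lowest (row, row) pair, so with no informative calls
#' the result is deterministic. Adjacent chunks are stitched by keeping
#' or swapping the new chunk's haplotype labels, whichever maximizes
#' allele agreement over the 10 sites flanking each side of the
#' junction — a lightweight ligation of windowed phased calls.
#'
#' Rough calls at non-panel sites are ignored (their number is
#' reported via a message); rough calls whose alleles disagree with
#' the panel site's REF/ALT are likewise ignored.
#'
#' @param rough rough call data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `h1`, `h2`, `qual`).
#' @param panel a [PanelMatrix-class] with at least two haplotypes.
#' @param chunkSize number of sites per chunk (>= 1).
#' @return phased variant data.frame defined at every panel site.
#' @export
imputePhasedGenotypes <- function(rough, panel, chunkSize = 100L) {
    if (chunkSize < 1L) stop("chunkSize must be >= 1")
    H <- nrow(panel@haplotypes)
    if (H < 2L) stop("panel must contain at least two haplotypes")
    s <- panel@sites
    S <- nrow(s)
    skey <- paste(s$chrom, s$pos, s$ref, s$alt)
    rkey <- paste(rough$chrom, rough$pos, rough$ref, rough$alt)
    idx <- match(rkey, skey)
    nIgnored <- sum(is.na(idx))
    if (nIgnored)
        message(nIgnored, " rough call(s) at non-panel sites ignored")
    dose <- rep(NA_integer_, S)     # called dosage at panel sites
    wgt <- rep(0, S)
    hit <- !is.na(idx)
    dose[idx[hit]] <- rough$h1[hit] + rough$h2[hit]
    wgt[idx[hit]] <- pmin(rough$qual[hit], 50)
    hap <- panel@haplotypes
    chunks <- split(seq_len(S),
                    ceiling(seq_len(S) / chunkSize))
    pairPrev <- NULL
    h1 <- integer(S); h2 <- integer(S)
    for (ci in seq_along(chunks)) {
        cs <- chunks[[ci]]
        called <- cs[!is.na(dose[cs]) & wgt[cs] > 0]
        best <- c(1L, 2L); bestScore <- -Inf
        for (i in seq_len(H)) for (j in seq_len(H)) {
            if (i == j) next
            sc <- if (length(called))
                sum(wgt[called] *
                    ((hap[i, called] + hap[j, called]) == dose[called]))
            else 0
            if (sc > bestScore) { bestScore <- sc; best <- c(i, j) }
        }
        if (!is.null(pairPrev)) {
            prevCs <- chunks[[ci - 1L]]
            flank <- c(tail(prevCs, 10L), head(cs, 10L))
            agree <- function(a, b)
                sum(hap[a[1L], flank] == hap[b[1L], flank]) +
                sum(hap[a[2L], flank] == hap[b[2L], flank])
            if (agree(pairPrev, c(best[2L], best[1L])) >
                agree(pairPrev, best))
                best <- c(best[2L], best[1L])
        }
        h1[cs] <- hap[best[1L], cs]
        h2[cs] <- hap[best[2L], cs]
        pairPrev <- best
    }
    out <- s
    out$h1 <- h1; out$h2 <- h2
    rownames(out) <- NULL
    out
}

#' Run an external imputation engine through an adapter command
#'
#' The adapter command template receives `{rough}`, `{panel}` and
#' `{out}` placeholders; it must produce a phased single-sample VCF at
#' the panel sites. The output is parsed and validated: a nonzero exit
#' status, unparseable output, or any unphased genotype is a distinct,
#' loud failure.
#'
#' @param roughVcf path to the rough calls VCF.
#' @param panelVcf path to the panel VCF.
#' @param adapterCommand shell command template.
#' @return phased variant data.frame parsed from the adapter output.
#' @export
runExternalImputer <- function(roughVcf, panelVcf, adapterCommand) {
    out <- tempfile(fileext = ".vcf")
    cmd <- gsub("{rough}", roughVcf, adapterCommand, fixed = TRUE)
    cmd <- gsub("{panel}", panelVcf, cmd, fixed = TRUE)
    cmd <- gsub("{out}", out, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L)
        stop("external imputer exited with status ", status,
             " (command: ", cmd, ")")
    if (!file.exists(out))
        stop("external imputer produced no output file")
    calls <- tryCatch(readVcfCalls(out, requirePhased = TRUE),
                      error = function(e)
        stop("external imputer output invalid: ",
             conditionMessage(e), call. = FALSE))
    calls
}
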