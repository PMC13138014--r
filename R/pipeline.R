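# Two-phase workflow orchestration: personalization (sample ->
# genotype -> impute -> build diploid reference) then downstream
# (project/lift/reconcile alignments -> evaluate), with JSON manifests
# and per-stage logging.

#' Randomly subsample reads
#'
#' Each read is independently retained with probability `fraction`;
#' retained order is preserved and the outcome is a pure function of
#' the seed.
#'
#' @param reads data.frame with `qname`, `seq` (extra columns kept).
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed.
#' @return the retained subset.
#' @export
subsampleReads <- function(reads, fraction, seed = 1L) {
    if (fraction <= 0 || fraction > 1)
        stop("fraction must be in (0, 1]")
    withSeed(deriveSeed(seed, "subsample"), {
        keep <- runif(nrow(reads)) < fraction
        out <- reads[keep, , drop = FALSE]
        rownames(out) <- NULL
        out
    })
}

# matches - 4*mismatches - 6*gap-ops over M segments of a record
# against the sequence it targets; BWA-flavoured so the correct
# haplotype outscores the other at variant loci.
alignmentScores <- function(records, targets) {
    vapply(seq_len(nrow(records)), function(i) {
        if (bitwAnd(records$flag[i], 4L) != 0L) return(NA_integer_)
        tseq <- targets[[records$rname[i]]]
        p <- parseCigar(records$cigar[i])
        rpos <- records$pos[i]; qpos <- 1L
        match <- 0L; mism <- 0L; gaps <- 0L
        for (k in seq_along(p$ops)) {
            op <- p$ops[k]; len <- p$lens[k]
            if (op == "M") {
                a <- utf8ToInt(substring(records$seq[i], qpos,
                                         qpos + len - 1L))
                b <- utf8ToInt(substring(tseq, rpos, rpos + len - 1L))
                match <- match + sum(a == b)
                mism <- mism + sum(a != b)
                rpos <- rpos + len; qpos <- qpos + len
            } else if (op == "I") {
                gaps <- gaps + 1L; qpos <- qpos + len
            } else if (op == "D") {
                gaps <- gaps + 1L; rpos <- rpos + len
            } else if (op == "S") {
                qpos <- qpos + len
            }
        }
        as.integer(match - 4L * mism - 6L * gaps)
    }, integer(1))
}

#' Project truth-haplotype reads onto the bare reference, ungapped
#'
#' Models an idealized gap-unaware linear mapping: each read is placed
#' at the better of its left- or right-anchored projected position
#' (fewest mismatches, ties to the left anchor) with an all-match
#' CIGAR. Reads whose span maps nowhere are emitted unmapped. This is
#' the package's bare-linear-reference baseline for reference-bias
#' measurements: reads carrying non-reference indels keep their bases
#' but show no gap operations, exactly the evidence loss a gap-unaware
#' placement entails.
#'
#' @param aln truth alignment data.frame (haplotype coordinates).
#' @param chains named list of [Chain-class], one per haplotype name.
#' @param reference named character vector (the bare reference).
#' @return alignment data.frame in reference coordinates, with `score`
#'   = matches minus four per mismatch.
#' @export
projectReadsUngapped <- function(aln, chains, reference) {
    maps <- lapply(chains, provenanceMap)
    refName <- chains[[1L]]@target
    refSeq <- reference[[refName]]
    L <- nchar(refSeq)
    out <- aln
    out$rname <- refName
    for (i in seq_len(nrow(aln))) {
        m <- maps[[aln$rname[i]]]
        rl <- nchar(aln$seq[i])
        span <- aln$pos[i]:(aln$pos[i] + rl - 1L)
        mm <- m[span]
        ok <- which(!is.na(mm))
        if (!length(ok)) {
            out$flag[i] <- bitwOr(aln$flag[i], 4L)
            out$rname[i] <- "*"; out$pos[i] <- 0L; out$cigar[i] <- "*"
            out$mapq[i] <- 0L; out$score[i] <- NA_integer_
            next
        }
        first <- ok[1L]; last <- ok[length(ok)]
        cand <- unique(pmin(pmax(
            c(mm[first] - (first - 1L), mm[last] - (last - 1L)),
            1L), L - rl + 1L))
        nm <- vapply(cand, function(p0)
            countMismatches(aln$seq[i],
                            substring(refSeq, p0, p0 + rl - 1L)),
            numeric(1))
        best <- cand[which.min(nm)]
        out$pos[i] <- best
        out$cigar[i] <- paste0(rl, "M")
        out$score[i] <- as.integer(rl - min(nm) - 4L * min(nm))
    }
    out
}

validatePipelineConfig <- function(config) {
    if (is.null(config$outDir)) stop("config$outDir is required")
    ps <- config$personalization
    if (!is.null(ps$subsampleFraction) &&
        (ps$subsampleFraction <= 0 || ps$subsampleFraction > 1))
        stop("personalization subsampleFraction must be in (0, 1]")
    if (!is.null(config$evaluation$window) &&
        config$evaluation$window <= 0)
        stop("evaluation window must be > 0")
    for (p in unlist(config$paths))
        if (!file.exists(p))
            stop("configured path does not exist: ", p)
    invisible(TRUE)
}

writeManifest <- function(dir, stage, params, inputs, outputs, seed) {
    man <- list(stage = stage, params = params, seed = seed,
                inputs = as.list(tools::md5sum(inputs)),
                outputs = as.list(tools::md5sum(outputs)),
                package = as.character(utils::packageVersion("imputeref")))
    jsonlite::write_json(man,
                         file.path(dir, paste0(stage, ".manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE)
}

writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the impute-first workflow end to end
#'
#' Executes: synthetic data generation, read subsampling, rough
#' genotyping on reference-projected alignments, QUAL/DP filtering,
#' panel-based imputation, diploid reference construction with chains,
#' re-expression of the full read set against the personalized
#' haplotypes, liftover back to reference coordinates, reconciliation,
#' and the full evaluation suite. Every stage writes its outputs plus a
#' JSON manifest (parameters, input/output digests, seed, package
#' version); rerunning the same configuration reproduces identical
#' evaluation tables.
#'
#' @param config either a configuration list or a path to a YAML file.
#'   Recognized sections: `outDir`, `seed`, `sim` (arguments to
#'   [simConfig()]), `personalization` (`subsampleFraction`, `minQual`,
#'   `maxDepth`, `callerErrorRate`, `chunkSize`, `excludeIds`,
#'   `imputerAdapter`), `evaluation` (`window`, `rocThresholds`).
#' @return invisibly, a list with the run directory and the main
#'   evaluation tables.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    validatePipelineConfig(config)
    outDir <- config$outDir
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    simArgs <- config$sim
    simArgs$seed <- seed
    cfg <- do.call(simConfig, simArgs)
    ps <- config$personalization
    frac <- if (is.null(ps$subsampleFraction)) 0.2
            else ps$subsampleFraction
    minQual <- if (is.null(ps$minQual)) 20 else ps$minQual
    maxDepth <- if (is.null(ps$maxDepth)) 100 else ps$maxDepth
    cErr <- if (is.null(ps$callerErrorRate)) 0.01 else ps$callerErrorRate
    chunkSize <- if (is.null(ps$chunkSize)) 100L else ps$chunkSize
    excludeIds <- ps$excludeIds
    window <- if (is.null(config$evaluation$window)) 200L
              else config$evaluation$window
    rocThr <- if (is.null(config$evaluation$rocThresholds))
        c(0, 10, 20, 30, 50) else config$evaluation$rocThresholds

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(outDir, "run.log")
    logMsg <- function(...) cat(paste0(..., "\n"), file = logFile,
                                append = TRUE)
    runStage <- function(stage, fn) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(fn(), error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        logMsg(stage, ": ", sprintf("%.2f", proc.time()[["elapsed"]] - t0),
               "s")
        res
    }

    # --- stage: syndata -------------------------------------------------
    sdDir <- file.path(outDir, "syndata")
    sd <- runStage("syndata", function() writeSynData(cfg, sdDir))
    truth <- sd$truth; panel <- sd$panel
    refVec <- setNames(truth@reference, truth@refName)
    refLen <- setNames(nchar(truth@reference), truth@refName)
    writeManifest(outDir, "syndata",
                  params = list(refLength = cfg@refLength,
                                coverage = cfg@coverage,
                                seed = cfg@seed),
                  inputs = character(),
                  outputs = file.path(sdDir, c("ref.fasta", "truth.vcf",
                                               "panel.vcf",
                                               "reads.fastq",
                                               "truth.sam")),
                  seed = seed)
    # truth chains: map each truth haplotype to the reference
    truthDr <- buildDiploidReference(refVec, truth@variants)
    truthChains <- list(hap1 = truthDr@chain1, hap2 = truthDr@chain2)

    # --- stage: subsample ----------------------------------------------
    subAln <- runStage("subsample", function() {
        keep <- subsampleReads(sd$alignments, frac, seed)
        writeFastq(keep[, c("qname", "seq")],
                   file.path(outDir, "subsampled.fastq"))
        logMsg("subsample: ", nrow(keep), "/", nrow(sd$alignments),
               " reads retained")
        keep
    })
    writeManifest(outDir, "subsample",
                  params = list(fraction = frac),
                  inputs = file.path(sdDir, "reads.fastq"),
                  outputs = file.path(outDir, "subsampled.fastq"),
                  seed = seed)

    # --- stage: genotype ------------------------------------------------
    filtered <- runStage("genotype", function() {
        subRef <- rbind(
            liftAlignments(truthChains$hap1,
                           subAln[subAln$rname == "hap1", ,
                                  drop = FALSE]),
            liftAlignments(truthChains$hap2,
                           subAln[subAln$rname == "hap2", ,
                                  drop = FALSE]))
        pile <- pileupFromAlignments(subRef, refVec)
        rough <- callRoughGenotypes(pile, refVec, errorRate = cErr)
        writeVcf(rough, refLen, file.path(outDir, "rough.vcf"),
                 phased = FALSE, sampleName = "ROUGH")
        filt <- filterRoughCalls(rough, minQual, maxDepth)
        writeVcf(filt, refLen, file.path(outDir, "rough.filtered.vcf"),
                 phased = FALSE, sampleName = "ROUGH")
        logMsg("genotype: ", nrow(rough), " rough calls, ",
               nrow(filt), " after QUAL>=", minQual, " DP<=", maxDepth)
        filt
    })
    writeManifest(outDir, "genotype",
                  params = list(minQual = minQual, maxDepth = maxDepth,
                                callerErrorRate = cErr),
                  inputs = file.path(outDir, "subsampled.fastq"),
                  outputs = file.path(outDir,
                                      c("rough.vcf",
                                        "rough.filtered.vcf")),
                  seed = seed)

    # --- stage: impute ---------------------------------------------------
    imputed <- runStage("impute", function() {
        pan <- panel
        if (length(excludeIds)) pan <- excludeSamples(pan, excludeIds)
        imp <- if (!is.null(ps$imputerAdapter)) {
            runExternalImputer(file.path(outDir, "rough.filtered.vcf"),
                               file.path(sdDir, "panel.vcf"),
                               ps$imputerAdapter)
        } else {
            imputePhasedGenotypes(filtered, pan, chunkSize)
        }
        writeVcf(imp, refLen, file.path(outDir, "imputed.vcf"),
                 phased = TRUE, sampleName = "IMPUTED")
        imp
    })
    writeManifest(outDir, "impute",
                  params = list(chunkSize = chunkSize,
                                excludeIds = excludeIds),
                  inputs = file.path(outDir, "rough.filtered.vcf"),
                  outputs = file.path(outDir, "imputed.vcf"),
                  seed = seed)

    # --- stage: personalize ----------------------------------------------
    dr <- runStage("personalize", function() {
        d <- buildDiploidReference(refVec, imputed)
        writeDiploidReference(d, file.path(outDir, "personalized"))
        d
    })
    writeManifest(outDir, "personalize",
                  params = list(),
                  inputs = file.path(outDir, "imputed.vcf"),
                  outputs = paste0(file.path(outDir, "personalized"),
                                   c(".hap1.fasta", ".hap2.fasta",
                                     ".hap1.chain", ".hap2.chain")),
                  seed = seed)

    # --- stage: downstream (lift + reconcile) ----------------------------
    reconciled <- runStage("downstream", function() {
        persSeqs <- list(hap1 = dr@hap1, hap2 = dr@hap2)
        persChains <- list(hap1 = dr@chain1, hap2 = dr@chain2)
        # full read set in reference coordinates via truth chains
        refAln <- rbind(
            liftAlignments(truthChains$hap1,
                           sd$alignments[sd$alignments$rname == "hap1",
                                         , drop = FALSE]),
            liftAlignments(truthChains$hap2,
                           sd$alignments[sd$alignments$rname == "hap2",
                                         , drop = FALSE]))
        refAln <- refAln[order(refAln$qname), , drop = FALSE]
        refUnmapped <- refAln[bitwAnd(refAln$flag, 4L) != 0L, ,
                              drop = FALSE]
        refAln <- refAln[bitwAnd(refAln$flag, 4L) == 0L, , drop = FALSE]
        candidates <- lapply(c("hap1", "hap2"), function(hp) {
            inv <- invertChain(persChains[[hp]])
            onHap <- liftAlignments(inv, refAln)
            onHap$rname[bitwAnd(onHap$flag, 4L) == 0L] <- hp
            onHap$score <- alignmentScores(onHap, persSeqs)
            lifted <- liftAlignments(persChains[[hp]],
                                     onHap[bitwAnd(onHap$flag, 4L) == 0L,
                                           , drop = FALSE])
            unmapped <- onHap[bitwAnd(onHap$flag, 4L) != 0L, ,
                              drop = FALSE]
            if (nrow(unmapped)) lifted <- rbind(lifted, unmapped)
            lifted
        })
        if (nrow(refUnmapped)) {
            refUnmapped$score <- NA_integer_
            candidates[[1L]] <- rbind(candidates[[1L]], refUnmapped)
        }
        rec <- reconcileAlignments(candidates, labels = c("hap1", "hap2"))
        writeSam(rec, refLen, file.path(outDir, "reconciled.sam"),
                 comments = "reconciled best-of-2 personalized-haplotype alignments")
        logMsg("downstream: ", sum(bitwAnd(rec$flag, 4L) == 0L),
               " mapped / ", nrow(rec), " total")
        rec
    })
    writeManifest(outDir, "downstream",
                  params = list(candidates = c("hap1", "hap2")),
                  inputs = file.path(sdDir, "truth.sam"),
                  outputs = file.path(outDir, "reconciled.sam"),
                  seed = seed)

    # --- stage: evaluate ---------------------------------------------------
    tables <- runStage("evaluate", function() {
        sites <- panel@sites
        vt <- truth@variants
        confA <- alleleAltConfusion(imputed, vt, sites)
        confH <- hetConfusion(imputed, vt, sites)
        confusion <- data.frame(
            level = c("allele", "het"),
            rbind(confA, confH), row.names = NULL)
        prf <- data.frame(
            level = c("allele", "het"),
            rbind(prfFromCounts(confA), prfFromCounts(confH)),
            row.names = NULL)
        wins <- buildPivotWindows(sites, window)
        waImp <- windowAccuracy(imputed, vt, wins, sites)
        waRough <- windowAccuracy(filtered, vt, wins, sites)
        waImp$callset <- "imputed"; waRough$callset <- "rough"
        wa <- rbind(waImp, waRough)
        hets <- vt[vt$h1 != vt$h2, , drop = FALSE]
        balPers <- siteAllelicBalance(reconciled, hets)
        linAln <- projectReadsUngapped(sd$alignments, truthChains,
                                       refVec)
        balLin <- siteAllelicBalance(linAln, hets)
        binsPers <- biasLengthBins(balPers)
        binsLin <- biasLengthBins(balLin)
        binsPers$reference <- "personalized"
        binsLin$reference <- "linear"
        roc <- qualRocTable(filtered, vt, rocThr)
        evalDir <- file.path(outDir, "evaluation")
        dir.create(evalDir, showWarnings = FALSE)
        writeTsv(confusion, file.path(evalDir, "confusion.tsv"))
        writeTsv(prf, file.path(evalDir, "prf.tsv"))
        writeTsv(wa, file.path(evalDir, "window_accuracy.tsv"))
        writeTsv(rbind(binsPers, binsLin),
                 file.path(evalDir, "balance_bins.tsv"))
        writeTsv(roc, file.path(evalDir, "roc.tsv"))
        list(confusion = confusion, prf = prf, windowAccuracy = wa,
             balancePersonalized = balPers, balanceLinear = balLin,
             roc = roc)
    })
    writeManifest(outDir, "evaluate",
                  params = list(window = window,
                                rocThresholds = rocThr),
                  inputs = file.path(outDir,
                                     c("imputed.vcf", "reconciled.sam")),
                  outputs = file.path(outDir, "evaluation",
                                      c("confusion.tsv", "prf.tsv",
                                        "window_accuracy.tsv",
                                        "balance_bins.tsv", "roc.tsv")),
                  seed = seed)
    invisible(c(list(outDir = outDir, truth = truth, panel = panel,
                     imputed = imputed, filtered = filtered,
                     diploid = dr, reconciled = reconciled), tables))
}
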