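# -- end-to-end pipeline ----------------------------------------------------

.connDefaults <- function(measure) {
    if (measure %in% c("MIP", "MIBP")) c(nTop = 25L, cutoff = 3L)
    else c(nTop = 75L, cutoff = 5L)
}

#' Write a PairScoreMatrix to TSV
#'
#' @param psm a [PairScoreMatrix-class] object.
#' @param path output path.
#' @param layout \code{"long"} (one row per pair: \code{col_k, col_l, raw,
#'   normalized, measure}) or \code{"square"} (the symmetric normalized
#'   matrix with original column numbers as row/column labels).
#' @param digits rounding applied to the written scores (3, matching the
#'   conventional reporting precision; internal values keep full
#'   precision).
#' @return \code{path}, invisibly.
#' @export
writePairScores <- function(psm, path, layout = c("long", "square"),
                            digits = 3) {
    layout <- match.arg(layout)
    if (layout == "long") {
        df <- as.data.frame(psm)
        df$raw <- round(df$raw, digits)
        df$normalized <- round(df$normalized, digits)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        m <- round(normalizedScores(psm), digits)
        utils::write.table(cbind(col = rownames(m), as.data.frame(m)),
                           path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Write a ConnTable to TSV
#'
#' Machine output keeps all sites (including sub-threshold ones) so a
#' different cutoff can be applied without recomputation.
#'
#' @param ct a [ConnTable-class] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConnTable <- function(ct, path) {
    e <- ct@entries
    df <- data.frame(site = e$site, conn = e$conn, n_top = ct@nTop,
                     cutoff = ct@cutoff, measure = ct@measure)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full covariation pipeline
#'
#' Executes read, identity clustering, gap-column filtering, depth check,
#' pair scoring for each requested measure, and conn(k) analysis, writing
#' per-measure pair-score TSVs, conn TSVs, the filtered alignment and a
#' run manifest into \code{outDir}. All reported column numbers are in
#' original alignment coordinates. Warnings (shallow alignment, degenerate
#' columns) never abort the run unless \code{strict = TRUE}.
#'
#' @param input path to the alignment file.
#' @param format \code{"fasta"} or \code{"stockholm"}.
#' @param outDir output directory (created if missing).
#' @param identityThreshold redundancy-removal identity level in (0, 1],
#'   or NULL to skip redundancy removal (needed e.g. to score a reference
#'   alignment that deliberately contains duplicate rows).
#' @param maxGapFraction maximum tolerated per-column gap fraction.
#' @param minSequences depth bound (warn-only unless \code{strict}).
#' @param measures subset of \code{c("MI", "MIB", "MIP", "MIBP")}.
#' @param nTop,cutoff optional overrides of the per-measure conn(k)
#'   defaults (recycled across measures when length 1).
#' @param includeTies admit tied pairs at the top-n boundary.
#' @param matrixLayout pair-score TSV layout, \code{"long"} or
#'   \code{"square"}.
#' @param seed optional integer recorded in the manifest and applied to
#'   the RNG (the pipeline itself is deterministic; the seed matters only
#'   when callers mix in simulated inputs).
#' @param strict upgrade warnings to errors.
#' @return invisibly, a list with the filtered alignment, the per-measure
#'   [PairScoreMatrix-class] and [ConnTable-class] objects, the manifest
#'   lines and the output paths.
#' @examples
#' f <- tempfile(fileext = ".fasta"); writeMsa(toyMsa(), f)
#' out <- tempfile(); res <- runPipeline(f, outDir = out, measures = "MI")
#' read.delim(res$paths[["MI_pairs"]])[1, ]
#' @export
runPipeline <- function(input, format = c("fasta", "stockholm"),
                        outDir = ".",
                        identityThreshold = 0.9, maxGapFraction = 0.25,
                        minSequences = 125,
                        measures = c("MI", "MIB", "MIP", "MIBP"),
                        nTop = NULL, cutoff = NULL, includeTies = FALSE,
                        matrixLayout = c("long", "square"),
                        seed = NULL, strict = FALSE) {
    format <- match.arg(format)
    matrixLayout <- match.arg(matrixLayout)
    measures <- match.arg(measures, several.ok = TRUE)
    if (length(measures) < 1L)
        stop("at least one measure must be selected")
    warn <- function(msg) {
        if (strict) stop(msg, call. = FALSE)
        warning(msg, call. = FALSE)
        msg
    }
    warnings <- character(0)
    if (!is.null(seed)) set.seed(seed)

    msa0 <- readMsa(input, format)
    msa1 <- if (is.null(identityThreshold)) msa0 else
        clusterByIdentity(msa0, identityThreshold)
    msa <- withCallingHandlers(
        filterGapColumns(msa1, maxGapFraction),
        warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    if (length(warnings) && strict)
        stop(warnings[[1L]], call. = FALSE)
    if (!validateDepth(msa, minSequences))
        warnings <- c(warnings, warn(sprintf(
            "alignment depth %d does not exceed %d; MI estimates may be noisy",
            nSequences(msa), minSequences)))
    if (nColumns(msa) < 2L)
        stop("fewer than 2 columns survive preprocessing; nothing to score")

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(filtered = file.path(outDir, "filtered_alignment.fasta"))
    writeMsa(msa, paths[["filtered"]])

    scores <- list()
    conns <- list()
    for (i in seq_along(measures)) {
        meas <- measures[i]
        defs <- .connDefaults(meas)
        nt <- if (is.null(nTop)) defs[["nTop"]] else
            as.integer(rep_len(nTop, length(measures))[i])
        co <- if (is.null(cutoff)) defs[["cutoff"]] else
            as.integer(rep_len(cutoff, length(measures))[i])
        psm <- scoreAllPairs(msa, meas)
        ct <- connAnalysis(psm, nTop = nt, cutoff = co,
                           includeTies = includeTies)
        scores[[meas]] <- psm
        conns[[meas]] <- ct
        pPath <- file.path(outDir, paste0(meas, "_pairs.tsv"))
        cPath <- file.path(outDir, paste0(meas, "_conn.tsv"))
        writePairScores(psm, pPath, layout = matrixLayout)
        writeConnTable(ct, cPath)
        paths[paste0(meas, "_pairs")] <- pPath
        paths[paste0(meas, "_conn")] <- cPath
    }

    manifest <- c(
        paste0("input=", input),
        paste0("format=", format),
        paste0("identity_threshold=",
               if (is.null(identityThreshold)) "none" else identityThreshold),
        paste0("max_gap_fraction=", maxGapFraction),
        paste0("min_sequences=", minSequences),
        paste0("measures=", paste(measures, collapse = ",")),
        paste0("n_top=", paste(vapply(conns, function(x) x@nTop, integer(1)),
                               collapse = ",")),
        paste0("cutoff=", paste(vapply(conns, function(x) x@cutoff,
                                       integer(1)), collapse = ",")),
        paste0("include_ties=", includeTies),
        paste0("matrix_layout=", matrixLayout),
        paste0("seed=", if (is.null(seed)) "none" else seed),
        paste0("strict=", strict),
        paste0("sequences_input=", nSequences(msa0)),
        paste0("sequences_after_clustering=", nSequences(msa1)),
        paste0("columns_input=", nColumns(msa0)),
        paste0("columns_after_gap_filter=", nColumns(msa)),
        paste0("depth_check_passed=", validateDepth(msa, minSequences)),
        paste0("warnings=", length(warnings)),
        if (length(warnings)) paste0("warning_", seq_along(warnings), "=",
                                     warnings))
    paths[["manifest"]] <- file.path(outDir, "manifest.txt")
    writeLines(manifest, paths[["manifest"]])

    invisible(list(alignment = msa, scores = scores, conn = conns,
                   manifest = manifest, paths = paths,
                   warnings = warnings))
}

#' Read a flat key=value configuration file for the pipeline
#'
#' Lines of the form \code{key=value}; blank lines and lines starting with
#' \code{#} are ignored. Keys mirror the [runPipeline()] arguments in
#' snake_case (e.g. \code{identity_threshold=0.9},
#' \code{measures=MI,MIB}). Command-line flags override file values in
#' the shipped CLI.
#'
#' @param path path to the configuration file.
#' @return named list of character values.
#' @export
readPipelineConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE),
                     invert = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad))
        stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
    stats::setNames(lapply(kv, function(x) trimws(x[2L])),
                    vapply(kv, function(x) trimws(x[1L]), character(1)))
}
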