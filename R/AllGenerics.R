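#' Number of sequences in an alignment
#'
#' @param x a [CoevolMSA-class] object.
#' @return integer scalar.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Number of retained columns in an alignment
#'
#' @param x a [CoevolMSA-class] object.
#' @return integer scalar.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' Sequence identifiers
#'
#' @param x a [CoevolMSA-class] object.
#' @return character vector.
#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))

#' Original column numbers of retained columns
#'
#' @param x a [CoevolMSA-class] or [PairScoreMatrix-class] object.
#' @return integer vector of 1-based original column positions.
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' Measure that produced a score object
#'
#' @param x a [PairScoreMatrix-class] or [ConnTable-class] object.
#' @return character scalar, one of \code{"MI"}, \code{"MIB"}, \code{"MIP"},
#'   \code{"MIBP"}.
#' @export
setGeneric("measure", function(x) standardGeneric("measure"))

#' Normalized (primed) score matrix
#'
#' @param x a [PairScoreMatrix-class] object.
#' @return symmetric numeric matrix of MI', MIB', MIP' or MIBP' scores,
#'   dimnames set to original column numbers.
#' @export
setGeneric("normalizedScores", function(x) standardGeneric("normalizedScores"))

#' Raw (unnormalized) score matrix
#'
#' @param x a [PairScoreMatrix-class] object.
#' @return symmetric numeric matrix of raw MI, MIB, MIP or MIBP values.
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname nSequences
#' @export
setMethod("nSequences", "CoevolMSA", function(x) nrow(x@seqs))

#' @rdname nColumns
#' @export
setMethod("nColumns", "CoevolMSA", function(x) ncol(x@seqs))

#' @rdname sequenceIds
#' @export
setMethod("sequenceIds", "CoevolMSA", function(x) rownames(x@seqs))

#' @rdname columnMap
#' @export
setMethod("columnMap", "CoevolMSA", function(x) x@columnMap)

#' @rdname columnMap
#' @export
setMethod("columnMap", "PairScoreMatrix", function(x) x@columnMap)

#' @rdname measure
#' @export
setMethod("measure", "PairScoreMatrix", function(x) x@measure)

#' @rdname measure
#' @export
setMethod("measure", "ConnTable", function(x) x@measure)

#' @rdname normalizedScores
#' @export
setMethod("normalizedScores", "PairScoreMatrix", function(x) x@normalized)

#' @rdname rawScores
#' @export
setMethod("rawScores", "PairScoreMatrix", function(x) x@raw)

#' Coerce a CoevolMSA to a character matrix
#'
#' @param x a [CoevolMSA-class] object.
#' @param ... ignored.
#' @return character matrix of aligned symbols with sequence ids as
#'   rownames and original column numbers as colnames.
#' @export
setMethod("as.matrix", "CoevolMSA", function(x, ...) {
    m <- x@seqs
    colnames(m) <- x@columnMap
    m
})

setMethod("show", "CoevolMSA", function(object) {
    cat("CoevolMSA with", nSequences(object), "sequences and",
        nColumns(object), "columns\n")
    n <- min(nSequences(object), 6L)
    w <- min(nColumns(object), 60L)
    for (i in seq_len(n)) {
        s <- paste(object@seqs[i, seq_len(w)], collapse = "")
        cat(sprintf("  %-12s %s%s\n",
                    substr(sequenceIds(object)[i], 1L, 12L), s,
                    if (w < nColumns(object)) "..." else ""))
    }
    if (nSequences(object) > n)
        cat("  ...", nSequences(object) - n, "more sequences\n")
})

setMethod("show", "PairScoreMatrix", function(object) {
    nc <- ncol(object@normalized)
    np <- nc * (nc - 1L) / 2L
    ndeg <- sum(is.na(object@normalized[upper.tri(object@normalized)]))
    cat(sprintf("PairScoreMatrix: %s' scores over %d columns (%d pairs%s)\n",
                object@measure, nc, np,
                if (ndeg) paste0(", ", ndeg, " degenerate") else ""))
    ok <- object@normalized[upper.tri(object@normalized)]
    ok <- ok[!is.na(ok)]
    if (length(ok))
        cat(sprintf("  normalized score range: [%.3f, %.3f]\n",
                    min(ok), max(ok)))
})

setMethod("show", "ConnTable", function(object) {
    cat(sprintf("ConnTable (%s'): top %d pairs used, cutoff %d\n",
                object@measure, object@nUsed, object@cutoff))
    above <- object@entries[object@entries$conn >= object@cutoff, , drop = FALSE]
    cat(" ", nrow(above), "site(s) at or above the cutoff\n")
    if (nrow(above))
        print(utils::head(above, 10L), row.names = FALSE)
})
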