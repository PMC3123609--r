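#' @import methods
NULL

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.GAP <- "-"

#' CoevolMSA: a validated protein multiple sequence alignment
#'
#' Rectangular alignment of protein sequences over the 20 canonical
#' amino-acid one-letter codes plus the gap symbol \code{"-"}. The object
#' remembers, for every retained column, its 1-based position in the
#' original alignment (\code{columnMap}), so that sites reported after
#' gap-column filtering keep their original numbering.
#'
#' @slot seqs character matrix, one row per sequence, one column per
#'   alignment column; rownames are the sequence identifiers.
#' @slot columnMap integer vector, strictly increasing; original 1-based
#'   column number of each retained column.
#'
#' @seealso [readMsa()], [toyMsa()], [simulateMsa()]
#' @export
setClass("CoevolMSA",
         representation(seqs = "matrix", columnMap = "integer"))

setValidity("CoevolMSA", function(object) {
    msgs <- character(0)
    s <- object@seqs
    if (!is.character(s))
        msgs <- c(msgs, "'seqs' must be a character matrix")
    if (nrow(s) < 1L)
        msgs <- c(msgs, "alignment must contain at least one sequence")
    if (is.character(s) && length(s) > 0L) {
        bad <- setdiff(unique(as.vector(s)), c(.AA, .GAP))
        if (length(bad))
            msgs <- c(msgs, paste0("invalid symbols in alignment: ",
                                   paste(bad, collapse = " ")))
    }
    if (length(object@columnMap) != ncol(s))
        msgs <- c(msgs, "'columnMap' length must equal the number of columns")
    if (length(object@columnMap) > 1L && any(diff(object@columnMap) <= 0L))
        msgs <- c(msgs, "'columnMap' must be strictly increasing")
    if (is.null(rownames(s)))
        msgs <- c(msgs, "'seqs' must have sequence identifiers as rownames")
    if (length(msgs)) msgs else TRUE
})

#' Construct a CoevolMSA from aligned sequence strings
#'
#' Symbols are uppercased, the gap characters \code{"."}, \code{"-"} and
#' \code{"~"} are normalized to \code{"-"}, and the ambiguity/non-standard
#' codes B, Z, X, J, U and O are mapped to the gap symbol, because the
#' frequency model underlying all measures is defined on the 20-letter
#' alphabet.
#'
#' @param sequences character vector of equal-length aligned sequences.
#' @param ids character vector of sequence identifiers (default
#'   \code{seq1, seq2, ...}).
#' @param columnMap optional integer vector of original column numbers
#'   (default: identity).
#' @return A [CoevolMSA-class] object.
#' @examples
#' msa <- CoevolMSA(c("ACD-", "AC-E"), ids = c("s1", "s2"))
#' nSequences(msa)
#' @export
CoevolMSA <- function(sequences, ids = NULL, columnMap = NULL) {
    if (length(sequences) == 0L)
        stop("empty alignment: no sequences")
    sequences <- toupper(as.character(sequences))
    widths <- nchar(sequences)
    if (length(unique(widths)) != 1L)
        stop("ragged alignment: sequences have unequal lengths (",
             paste(unique(widths), collapse = ", "), ")")
    if (widths[1L] == 0L)
        stop("empty alignment: sequences have zero length")
    if (is.null(ids))
        ids <- paste0("seq", seq_along(sequences))
    m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    m[m %in% c(".", "~")] <- .GAP
    m[m %in% c("B", "Z", "X", "J", "U", "O")] <- .GAP
    rownames(m) <- as.character(ids)
    if (is.null(columnMap))
        columnMap <- seq_len(ncol(m))
    new("CoevolMSA", seqs = m, columnMap = as.integer(columnMap))
}

#' PairScoreMatrix: covariation scores for all column pairs
#'
#' Symmetric matrices of raw and normalized covariation scores for every
#' unordered pair of retained alignment columns, produced by one of the
#' measures MI, MIB, MIP or MIBP. The diagonal is 0 by convention.
#' Pairs with no jointly gap-free rows are degenerate and stored as
#' \code{NA}; they are excluded from ranking.
#'
#' @slot raw numeric matrix of raw scores (natural-log scale by default).
#' @slot normalized numeric matrix of normalized (primed) scores.
#' @slot measure one of \code{"MI"}, \code{"MIB"}, \code{"MIP"},
#'   \code{"MIBP"}.
#' @slot columnMap integer vector of original 1-based column numbers used
#'   as dimnames of both matrices.
#'
#' @seealso [scoreAllPairs()], [topPairs()]
#' @export
setClass("PairScoreMatrix",
         representation(raw = "matrix", normalized = "matrix",
                        measure = "character", columnMap = "integer"))

setValidity("PairScoreMatrix", function(object) {
    msgs <- character(0)
    if (!object@measure %in% c("MI", "MIB", "MIP", "MIBP"))
        msgs <- c(msgs, "'measure' must be one of MI, MIB, MIP, MIBP")
    d <- dim(object@normalized)
    if (d[1L] != d[2L])
        msgs <- c(msgs, "'normalized' must be square")
    if (!identical(dim(object@raw), d))
        msgs <- c(msgs, "'raw' and 'normalized' must have identical dimensions")
    if (length(object@columnMap) != d[1L])
        msgs <- c(msgs, "'columnMap' length must match matrix dimension")
    nm <- object@normalized
    if (!isTRUE(all.equal(nm, t(nm), tolerance = 1e-8, check.attributes = FALSE)))
        msgs <- c(msgs, "'normalized' must be symmetric")
    if (length(msgs)) msgs else TRUE
})

#' ConnTable: per-site conn(k) covariation connectivity
#'
#' For each alignment site, conn(k) counts how many of the top-n
#' high-scoring column pairs the site participates in. Sites are reported
#' in original alignment coordinates. The full table keeps sub-threshold
#' sites so a different cutoff can be applied without recomputation;
#' [reportSites()] applies the cutoff.
#'
#' @slot entries data.frame with columns \code{site} (original 1-based
#'   column number) and \code{conn} (non-negative integer), ordered by
#'   decreasing conn, ties by increasing site.
#' @slot nTop number of top pairs requested.
#' @slot nUsed number of pairs actually used (less than \code{nTop} when
#'   the matrix has fewer valid pairs).
#' @slot cutoff reporting threshold for [reportSites()].
#' @slot measure provenance tag of the score matrix.
#'
#' @seealso [connScores()], [reportSites()]
#' @export
setClass("ConnTable",
         representation(entries = "data.frame", nTop = "integer",
                        nUsed = "integer", cutoff = "integer",
                        measure = "character"))

setValidity("ConnTable", function(object) {
    e <- object@entries
    msgs <- character(0)
    if (!all(c("site", "conn") %in% names(e)))
        msgs <- c(msgs, "'entries' must have columns 'site' and 'conn'")
    else {
        if (any(e$conn < 0L))
            msgs <- c(msgs, "conn values must be non-negative")
        if (sum(e$conn) != 2L * object@nUsed)
            msgs <- c(msgs, "sum(conn) must equal 2 * number of pairs used")
    }
    if (length(msgs)) msgs else TRUE
})
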