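# -- conn(k): per-site covariation connectivity ----------------------------

#' Top-scoring column pairs of a score matrix
#'
#' Selects the \code{n} pairs with the highest normalized scores among the
#' non-degenerate pairs. Ties are broken deterministically by (score
#' descending, smaller column ascending, larger column ascending); with
#' \code{includeTies = TRUE} the whole cohort tied with the n-th score is
#' admitted instead of cutting it.
#'
#' @param psm a [PairScoreMatrix-class] object.
#' @param n number of pairs to select (all valid pairs when fewer exist).
#' @param includeTies admit all pairs tied with the n-th score.
#' @return data.frame with columns \code{col_k}, \code{col_l} (original
#'   numbers) and \code{score}, ordered as described.
#' @examples
#' topPairs(scoreAllPairs(toyMsa(), "MI"), 3)
#' @export
topPairs <- function(psm, n, includeTies = FALSE) {
    stopifnot(is(psm, "PairScoreMatrix"), n >= 1L)
    df <- as.data.frame(psm)
    df <- df[!is.na(df$normalized), , drop = FALSE]
    if (nrow(df) == 0L) {
        warning("no valid pairs in the score matrix")
        return(data.frame(col_k = integer(0), col_l = integer(0),
                          score = numeric(0)))
    }
    df <- df[order(-df$normalized, df$col_k, df$col_l), , drop = FALSE]
    if (nrow(df) > n) {
        if (includeTies)
            df <- df[df$normalized >= df$normalized[n] - 1e-12, , drop = FALSE]
        else
            df <- df[seq_len(n), , drop = FALSE]
    }
    data.frame(col_k = df$col_k, col_l = df$col_l, score = df$normalized,
               row.names = NULL)
}

#' conn(k) scores from a set of top pairs
#'
#' conn(k) is the number of selected top pairs in which site \code{k}
#' occurs. Because the pairs are unordered and distinct, this equals the
#' number of distinct partners of \code{k} among the top pairs. Individual
#' covariation scores can be misleading; a site linked to many top pairs
#' is a more robust covariation signal than a single high-scoring pair.
#'
#' @param pairs data.frame as returned by [topPairs()].
#' @param nTop number of top pairs that was requested (recorded in the
#'   table; conventional defaults are 75 for the residue measures MI'/MIB'
#'   and 25 for the property measures MIP'/MIBP').
#' @param cutoff reporting threshold recorded in the table (conventional
#'   defaults 5 for residue measures, 3 for property measures).
#' @param measure provenance tag.
#' @return A [ConnTable-class] with one entry per site occurring in at
#'   least one selected pair, ordered by decreasing conn then increasing
#'   site; sub-threshold sites are retained (the human-readable report
#'   hides them, see [reportSites()]). The handshake identity
#'   \code{sum(conn) == 2 * nrow(pairs)} always holds.
#' @examples
#' tp <- topPairs(scoreAllPairs(toyMsa(), "MI"), 3)
#' connScores(tp, nTop = 3, cutoff = 2, measure = "MI")
#' @export
connScores <- function(pairs, nTop, cutoff, measure = "MI") {
    stopifnot(is.data.frame(pairs),
              all(c("col_k", "col_l") %in% names(pairs)))
    sites <- c(pairs$col_k, pairs$col_l)
    tab <- table(sites)
    entries <- data.frame(site = as.integer(names(tab)),
                          conn = as.integer(tab))
    entries <- entries[order(-entries$conn, entries$site), , drop = FALSE]
    rownames(entries) <- NULL
    new("ConnTable", entries = entries, nTop = as.integer(nTop),
        nUsed = nrow(pairs), cutoff = as.integer(cutoff),
        measure = measure)
}

#' Ranked report of covariation hub sites
#'
#' Returns the sites whose conn(k) reaches the table's cutoff, ranked by
#' decreasing conn then increasing site number, with the column headers
#' \code{k} and \code{conn(k)} used in covariation hub tables.
#'
#' @param ct a [ConnTable-class] object.
#' @param cutoff optional override of the table's recorded cutoff.
#' @return data.frame with columns \code{k} and \code{conn(k)}.
#' @examples
#' tp <- connAnalysis(scoreAllPairs(toyMsa(), "MI"), nTop = 3, cutoff = 2)
#' reportSites(tp)
#' @export
reportSites <- function(ct, cutoff = NULL) {
    stopifnot(is(ct, "ConnTable"))
    if (is.null(cutoff)) cutoff <- ct@cutoff
    e <- ct@entries[ct@entries$conn >= cutoff, , drop = FALSE]
    out <- data.frame(k = e$site, conn = e$conn, row.names = NULL)
    names(out) <- c("k", "conn(k)")
    out
}

#' Full conn(k) analysis of a score matrix
#'
#' Convenience wrapper: [topPairs()] followed by [connScores()], with the
#' conventional per-measure defaults (top 75 pairs / cutoff 5 for the
#' residue measures MI' and MIB'; top 25 pairs / cutoff 3 for the property
#' measures MIP' and MIBP', whose ten-letter alphabet saturates sooner).
#'
#' @param psm a [PairScoreMatrix-class] object.
#' @param nTop number of top pairs (default depends on the measure).
#' @param cutoff reporting threshold (default depends on the measure).
#' @param includeTies see [topPairs()].
#' @return A [ConnTable-class] object.
#' @examples
#' connAnalysis(scoreAllPairs(toyMsa(), "MIB"))
#' @export
connAnalysis <- function(psm, nTop = NULL, cutoff = NULL,
                         includeTies = FALSE) {
    stopifnot(is(psm, "PairScoreMatrix"))
    propertyLevel <- measure(psm) %in% c("MIP", "MIBP")
    if (is.null(nTop)) nTop <- if (propertyLevel) 25L else 75L
    if (is.null(cutoff)) cutoff <- if (propertyLevel) 3L else 5L
    tp <- suppressWarnings(topPairs(psm, nTop, includeTies = includeTies))
    connScores(tp, nTop = nTop, cutoff = cutoff, measure = measure(psm))
}
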