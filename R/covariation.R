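# -- position-specific distributions ---------------------------------------

#' Position-specific amino-acid distribution of one column
#'
#' Frequencies are taken over the non-gap rows of the column; gaps are
#' ignored, they contribute neither to counts nor to the denominator.
#'
#' @param msa a [CoevolMSA-class] object.
#' @param k column index in the retained alignment (1-based).
#' @return list with components \code{frequencies} (named 20-vector summing
#'   to 1 when any residue is present) and \code{effectiveCount} (number of
#'   non-gap rows). An all-gap column yields an all-zero vector and
#'   \code{effectiveCount = 0}.
#' @examples
#' columnDistribution(toyMsa(), 6)$frequencies[c("D", "E", "F", "T")]
#' @export
columnDistribution <- function(msa, k) {
    stopifnot(is(msa, "CoevolMSA"), k >= 1L, k <= nColumns(msa))
    x <- msa@seqs[, k]
    x <- x[x != .GAP]
    n <- length(x)
    counts <- table(factor(x, levels = .AA))
    freqs <- if (n > 0L) as.numeric(counts) / n else numeric(length(.AA))
    names(freqs) <- .AA
    list(frequencies = freqs, effectiveCount = n)
}

#' Joint amino-acid distribution of a column pair
#'
#' Counts are taken over the rows that are non-gap at \emph{both} columns
#' and normalized by that row count, so the joint distribution and the
#' marginals derived from it live on the same sample of rows.
#'
#' @param msa a [CoevolMSA-class] object.
#' @param k,l distinct column indices in the retained alignment.
#' @return list with components \code{frequencies} (20 x 20 matrix, rows =
#'   residue in column \code{k}) and \code{effectiveCount}. A pair with no
#'   jointly non-gap row yields an all-zero matrix and
#'   \code{effectiveCount = 0} (degenerate).
#' @examples
#' j <- jointDistribution(toyMsa(), 3, 4)
#' j$frequencies["W", "A"]
#' @export
jointDistribution <- function(msa, k, l) {
    stopifnot(is(msa, "CoevolMSA"), k != l,
              k >= 1L, k <= nColumns(msa), l >= 1L, l <= nColumns(msa))
    x <- msa@seqs[, k]
    y <- msa@seqs[, l]
    ok <- x != .GAP & y != .GAP
    n <- sum(ok)
    tab <- table(factor(x[ok], levels = .AA), factor(y[ok], levels = .AA))
    freqs <- if (n > 0L) unclass(tab) / n else
        matrix(0, length(.AA), length(.AA), dimnames = list(.AA, .AA))
    list(frequencies = freqs, effectiveCount = n)
}

#' Background-modified marginal distribution
#'
#' Divides the observed position-specific frequencies by the background
#' and renormalizes: \eqn{\hat p(i) = (p_i / q_i) / \sum_j (p_j / q_j)},
#' the sum running over the residues observed in the column. Dividing by
#' the background removes the amino-acid evolutionary pressure from the
#' marginal: a fully conserved column keeps a point mass of 1 on its
#' residue whatever the residue is, which is what lets the
#' background-aware measure score conserved columns consistently. With a
#' uniform background the marginal is unchanged.
#'
#' @param frequencies named numeric vector of observed frequencies (as in
#'   [columnDistribution()]).
#' @param q background distribution, e.g. [blosum62Background()].
#' @return named numeric vector of modified frequencies summing to 1.
#' @examples
#' cd <- columnDistribution(toyMsa(), 5)
#' modifiedMarginal(cd$frequencies, blosum62Background())[c("E", "M")]
#' @export
modifiedMarginal <- function(frequencies, q) {
    if (sum(frequencies) <= 0)
        stop("degenerate distribution: no observed residues")
    w <- ifelse(frequencies > 0, frequencies / q[names(frequencies)], 0)
    w / sum(w)
}

#' Joint entropy of a distribution
#'
#' \eqn{H = -\sum p \log p} over the non-zero cells, with the convention
#' \eqn{0 \log 0 = 0}.
#'
#' @param x a matrix or vector of probabilities, or the list returned by
#'   [jointDistribution()].
#' @param base logarithm base (default natural log).
#' @return non-negative numeric scalar.
#' @examples
#' jointEntropy(jointDistribution(toyMsa(), 3, 4), base = 2)  # 1 bit
#' @export
jointEntropy <- function(x, base = exp(1)) {
    if (is.list(x)) x <- x$frequencies
    p <- x[x > 0]
    -sum(p * log(p)) / log(base)
}

# -- internal scoring core --------------------------------------------------

# Residue-level scores for one pair. x, y: symbol vectors already
# restricted to jointly non-gap rows. Returns c(raw, normalized) in nat.
.scoreResiduePair <- function(x, y, modify, q) {
    n <- length(x)
    fx <- factor(x, levels = .AA)
    fy <- factor(y, levels = .AA)
    J <- unclass(table(fx, fy)) / n
    px <- rowSums(J)
    py <- colSums(J)
    if (modify) {
        mx <- ifelse(px > 0, px / q, 0); mx <- mx / sum(mx)
        my <- ifelse(py > 0, py / q, 0); my <- my / sum(my)
    } else {
        mx <- px
        my <- py
    }
    nz <- which(J > 0, arr.ind = TRUE)
    p <- J[nz]
    # raw = sum p log[p / (mx my)], computed as cross-entropy minus joint
    # entropy; summing log mx and log my separately keeps the bijective
    # case exact (MI' is then 1 to the last bit)
    crossH <- -sum(p * (log(mx[nz[, 1L]]) + log(my[nz[, 2L]])))
    H <- -sum(p * log(p))
    raw <- crossH - H
    c(raw = raw, normalized = if (H > 0) raw / H else 0, H = H)
}

# Property-level scores for one pair. gm: 20 x 10 membership matrix.
.scorePropertyPair <- function(x, y, modify, gm, qp) {
    n <- length(x)
    X <- gm[x, , drop = FALSE] # n x 10 logical
    Y <- gm[y, , drop = FALSE]
    ppx <- colSums(X) / n
    ppy <- colSums(Y) / n
    J <- crossprod(X + 0, Y + 0) / n # 10 x 10 joint fractional frequencies
    consX <- nrow(unique(X)) == 1L
    consY <- nrow(unique(Y)) == 1L
    Hp <- {
        p <- J[J > 0]
        -sum(p * log(p))
    }
    if (modify) {
        mx <- ifelse(ppx > 0, ppx / qp, 0); mx <- mx / sum(mx)
        my <- ifelse(ppy > 0, ppy / qp, 0); my <- my / sum(my)
    } else {
        mx <- ppx
        my <- ppy
    }
    nz <- which(J > 0, arr.ind = TRUE)
    p <- J[nz]
    crossH <- -sum(p * (log(mx[nz[, 1L]]) + log(my[nz[, 2L]])))
    raw <- crossH - Hp
    if (!modify) {
        # property-level analogue of the conserved-column convention:
        # a column with one membership pattern has zero property variation
        if (consX || consY)
            c(raw = 0, normalized = 0, H = Hp)
        else
            c(raw = raw, normalized = if (Hp > 0) raw / Hp else 0, H = Hp)
    } else {
        # the background-corrected measure deliberately has no conserved
        # short-circuit; when the property joint entropy vanishes the raw
        # value itself is reported (finite and informative for doubly
        # conserved pairs)
        c(raw = raw, normalized = if (Hp > 0) raw / Hp else raw, H = Hp)
    }
}

.MEASURES <- c("MI", "MIB", "MIP", "MIBP")

.scorePair <- function(x, y, measure, q, gm, qp, base) {
    ok <- x != .GAP & y != .GAP
    if (!any(ok))
        return(c(raw = NA_real_, normalized = NA_real_, H = NA_real_))
    s <- switch(measure,
        MI   = .scoreResiduePair(x[ok], y[ok], modify = FALSE, q = q),
        MIB  = .scoreResiduePair(x[ok], y[ok], modify = TRUE,  q = q),
        MIP  = .scorePropertyPair(x[ok], y[ok], modify = FALSE, gm = gm, qp = qp),
        MIBP = .scorePropertyPair(x[ok], y[ok], modify = TRUE,  gm = gm, qp = qp))
    s[["raw"]] <- s[["raw"]] / log(base)
    s[["H"]] <- s[["H"]] / log(base)
    # the normalized score is a ratio of same-base logarithms for every
    # measure except MIBP on a zero-entropy pair, where the raw value (in
    # the requested base) is passed through
    if (measure == "MIBP" && s[["H"]] == 0)
        s[["normalized"]] <- s[["raw"]]
    s
}

# -- exported scoring -------------------------------------------------------

#' Covariation score of one column pair
#'
#' Computes one of the four measures for a single pair of columns:
#' \describe{
#'   \item{MI}{classical mutual information; the normalized form MI' =
#'     MI / H(K,L) lies in [0, 1] and is 0 whenever one column is fully
#'     conserved.}
#'   \item{MIB}{MI with both marginals replaced by the background-modified
#'     marginals of [modifiedMarginal()]; MIB' = MIB / H(K,L) can exceed 1
#'     and distinguishes pairs with one conserved column.}
#'   \item{MIP}{MI over the 10 x 10 joint distribution of Taylor group
#'     memberships; MIP' = MIP / H_p(K,L), defined as 0 when either
#'     column is property-conserved.}
#'   \item{MIBP}{the property measure with group marginals divided by the
#'     property background q_p and renormalized; MIBP' = MIBP / H_p(K,L)
#'     when H_p > 0 and the raw MIBP otherwise, so doubly conserved pairs
#'     receive a finite informative score.}
#' }
#' Marginals are computed from the pair's jointly non-gap rows, which
#' guarantees MI >= 0 and the entropy identity MI = H(K) + H(L) - H(K,L);
#' on gap-free input this coincides with the per-column definition.
#'
#' @param msa a [CoevolMSA-class] object.
#' @param k,l distinct column indices in the retained alignment.
#' @param measure one of \code{"MI"}, \code{"MIB"}, \code{"MIP"},
#'   \code{"MIBP"}.
#' @param q amino-acid background (used by MIB; see
#'   [blosum62Background()]).
#' @param groups property group scheme (used by MIP/MIBP; see
#'   [taylorGroups()]).
#' @param qp property background (used by MIBP; defaults to
#'   \code{groupBackground(groups, q)}).
#' @param base logarithm base for the raw score; normalized scores are
#'   base-invariant.
#' @return list with components \code{columnK}, \code{columnL} (original
#'   1-based numbers), \code{raw}, \code{normalized}, \code{jointEntropy},
#'   \code{measure} and \code{degenerate} (TRUE when the pair has no
#'   jointly non-gap row; scores are then NA).
#' @examples
#' pairScore(toyMsa(), 3, 4, "MI")$normalized   # 1: perfect covariation
#' pairScore(toyMsa(), 1, 2, "MIBP")$normalized # conserved pair, nonzero
#' @export
pairScore <- function(msa, k, l, measure = .MEASURES,
                      q = blosum62Background(), groups = taylorGroups(),
                      qp = groupBackground(groups, q), base = exp(1)) {
    measure <- match.arg(measure)
    stopifnot(is(msa, "CoevolMSA"), k != l)
    gm <- .groupMembership(groups)
    s <- .scorePair(msa@seqs[, k], msa@seqs[, l], measure, q, gm, qp, base)
    list(columnK = msa@columnMap[k], columnL = msa@columnMap[l],
         raw = unname(s[["raw"]]), normalized = unname(s[["normalized"]]),
         jointEntropy = unname(s[["H"]]), measure = measure,
         degenerate = is.na(s[["raw"]]))
}

#' Covariation scores for all column pairs
#'
#' Applies one measure to every unordered pair of retained columns and
#' returns the symmetric score matrices. The diagonal is 0 by convention;
#' degenerate pairs (no jointly non-gap rows) are NA and are skipped by
#' the ranking functions rather than scored 0.
#'
#' @inheritParams pairScore
#' @return A [PairScoreMatrix-class] object; dimnames of its matrices are
#'   the original 1-based column numbers.
#' @examples
#' psm <- scoreAllPairs(toyMsa(), "MI")
#' round(normalizedScores(psm)[3, 4], 3)
#' @export
scoreAllPairs <- function(msa, measure = .MEASURES,
                          q = blosum62Background(), groups = taylorGroups(),
                          qp = groupBackground(groups, q), base = exp(1)) {
    measure <- match.arg(measure)
    stopifnot(is(msa, "CoevolMSA"))
    L <- nColumns(msa)
    if (L < 2L)
        stop("need at least 2 retained columns to score pairs")
    gm <- .groupMembership(groups)
    lab <- as.character(msa@columnMap)
    raw <- matrix(0, L, L, dimnames = list(lab, lab))
    norm <- matrix(0, L, L, dimnames = list(lab, lab))
    for (k in seq_len(L - 1L)) {
        for (l in seq((k + 1L), L)) {
            s <- .scorePair(msa@seqs[, k], msa@seqs[, l], measure,
                            q, gm, qp, base)
            raw[k, l] <- raw[l, k] <- s[["raw"]]
            norm[k, l] <- norm[l, k] <- s[["normalized"]]
        }
    }
    new("PairScoreMatrix", raw = raw, normalized = norm,
        measure = measure, columnMap = msa@columnMap)
}

#' Long-format view of a PairScoreMatrix
#'
#' @param x a [PairScoreMatrix-class] object.
#' @param row.names,optional ignored (S3 compatibility).
#' @param ... ignored.
#' @return data.frame with columns \code{col_k}, \code{col_l} (original
#'   numbers, \code{col_k < col_l}), \code{raw}, \code{normalized},
#'   \code{measure}, one row per unordered pair.
#' @export
as.data.frame.PairScoreMatrix <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    L <- length(x@columnMap)
    idx <- which(upper.tri(x@normalized), arr.ind = TRUE)
    df <- data.frame(
        col_k = x@columnMap[idx[, 1L]],
        col_l = x@columnMap[idx[, 2L]],
        raw = x@raw[idx],
        normalized = x@normalized[idx],
        measure = x@measure)
    df[order(df$col_k, df$col_l), , drop = FALSE]
}
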