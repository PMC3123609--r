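# BLOSUM62 amino-acid background distribution, as distributed with the
# Capra & Singh conservation toolkit. The widely quoted 4-decimal BLOSUM62
# marginals are a different rounding of the same frequencies and do NOT
# reproduce the reference scores this package is validated against; this
# 3-decimal table does. The raw table sums to 1.002 and is renormalized to
# sum exactly to 1 (every measure in the package is invariant to that
# scale factor, because the modified marginals are renormalized).
.BLOSUM62_BG_RAW <- c(
    A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
    Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
    L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
    S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072)

# Taylor's ten overlapping physicochemical groups, in the conventional
# order. M occurs only in hydrophobic and Q only in polar; that asymmetry
# is part of the classification and must not be "fixed".
.TAYLOR_GROUPS <- list(
    hydrophobic = c("A", "G", "C", "T", "I", "V", "L", "K", "H", "F",
                    "Y", "W", "M"),
    aromatic    = c("F", "Y", "W", "H"),
    aliphatic   = c("I", "V", "L"),
    tiny        = c("A", "S", "G", "C"),
    small       = c("P", "N", "D", "T", "C", "A", "G", "S", "V"),
    proline     = "P",
    charged     = c("K", "H", "R", "D", "E"),
    negative    = c("D", "E"),
    polar       = c("N", "Q", "S", "D", "E", "C", "T", "K", "R", "H",
                    "Y", "W"),
    positive    = c("K", "H", "R"))

#' BLOSUM62 amino-acid background distribution
#'
#' The background frequency of each amino acid estimates its evolutionary
#' pressure: residues under weak pressure are replaced readily and show up
#' with low frequency. The BLOSUM62 marginal frequencies serve as this
#' background, following common practice in conservation scoring. The table
#' is embedded as a constant (renormalized to sum exactly to 1) and also
#' shipped as a machine-readable JSON resource in
#' \code{system.file("extdata", "blosum62_background.json", package =
#' "CoevolMI")}.
#'
#' @return named numeric vector of length 20 (names are the one-letter
#'   codes in alphabetical order) summing to 1.
#' @examples
#' q <- blosum62Background()
#' sum(q)
#' q["W"] < q["L"]  # tryptophan is rare, leucine common
#' @export
blosum62Background <- function() {
    q <- .BLOSUM62_BG_RAW / sum(.BLOSUM62_BG_RAW)
    q[order(names(q))]
}

#' Taylor's ten overlapping physicochemical property groups
#'
#' Amino acids are classified into ten overlapping groups (hydrophobic,
#' aromatic, aliphatic, tiny, small, proline, charged, negative, polar,
#' positive). Because the groups overlap, several residues are
#' indistinguishable at the property level: W and Y share exactly the
#' groups \{hydrophobic, aromatic, polar\}, as do G/A and I/L within their
#' respective memberships. A column whose residues all share one membership
#' pattern is property-conserved even when it is not residue-conserved.
#'
#' @return named list of 10 character vectors; names are the group names
#'   in the conventional order, values the member one-letter codes.
#' @examples
#' g <- taylorGroups()
#' g$aliphatic
#' @export
taylorGroups <- function() .TAYLOR_GROUPS

#' Background distribution of physicochemical properties
#'
#' The property background \eqn{q_p(a)} of group \eqn{a} is the summed
#' amino-acid background mass of its members, \eqn{q_p(a) = \sum_{i \in a}
#' q_i}. Because the groups overlap, the ten values do not sum to 1 and
#' are deliberately not renormalized; the measures that consume them
#' renormalize their modified marginals instead.
#'
#' @param groups group scheme as returned by [taylorGroups()].
#' @param q amino-acid background as returned by [blosum62Background()].
#' @return named numeric vector of length \code{length(groups)}, each value
#'   in (0, 1].
#' @examples
#' qp <- groupBackground()
#' qp["proline"] == blosum62Background()["P"]
#' @export
groupBackground <- function(groups = taylorGroups(), q = blosum62Background()) {
    vapply(groups, function(mem) sum(q[mem]), numeric(1))
}

# 20 x 10 logical membership matrix, rows in .AA order
.groupMembership <- function(groups = taylorGroups()) {
    m <- vapply(groups, function(mem) .AA %in% mem, logical(length(.AA)))
    rownames(m) <- .AA
    m
}
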