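# -- built-in toy alignment and synthetic-MSA generator --------------------

#' The built-in 6 x 6 toy alignment
#'
#' A small gap-free alignment designed so that every measure behaves
#' differently on it: columns 1 and 2 are fully conserved (D and A),
#' columns 3-5 covary perfectly at the residue level but differ at the
#' property level (column 3 holds W/Y, which share all Taylor group
#' memberships and are therefore property-conserved), and column 6 is an
#' irregular column.
#'
#' @return A [CoevolMSA-class] with rows DAWAEE, DAWAEF, DAWAED, DAYCMD,
#'   DAYCMT, DAYCMT.
#' @examples
#' toyMsa()
#' @export
toyMsa <- function() {
    CoevolMSA(c("DAWAEE", "DAWAEF", "DAWAED", "DAYCMD", "DAYCMT", "DAYCMT"),
              ids = paste0("toy", 1:6))
}

#' Simulate an alignment with controlled coevolution structure
#'
#' Generates a gap-free alignment in which, by default, every column is
#' drawn i.i.d. from the background distribution. Selected columns can be
#' made fully conserved, and selected column pairs can be coupled: for a
#' pair with coupling strength \eqn{c}, each row of the second column is,
#' with probability \eqn{c}, the image of the first column's residue under
#' a fixed random permutation of the alphabet, and otherwise an
#' independent draw from the background. Coupling 1 therefore yields
#' bijective covariation (MI' exactly 1 on gap-free data) and coupling 0
#' independence.
#'
#' All randomness is driven by R's RNG; supplying \code{seed} makes the
#' alignment reproducible bit for bit.
#'
#' @param nSequences number of rows.
#' @param nColumns number of columns.
#' @param background named amino-acid distribution (default
#'   [blosum62Background()]).
#' @param coevolvingPairs data.frame with columns \code{colA}, \code{colB},
#'   \code{coupling} (each coupling in [0, 1]), or NULL.
#' @param conservedColumns data.frame with columns \code{col},
#'   \code{residue}, or NULL.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return A [CoevolMSA-class] object.
#' @examples
#' msa <- simulateMsa(50, 8, seed = 1,
#'                    coevolvingPairs = data.frame(colA = 1, colB = 2,
#'                                                 coupling = 1))
#' pairScore(msa, 1, 2, "MI")$normalized
#' @export
simulateMsa <- function(nSequences, nColumns,
                        background = blosum62Background(),
                        coevolvingPairs = NULL, conservedColumns = NULL,
                        seed = NULL) {
    if (nSequences < 1L || nColumns < 1L)
        stop("'nSequences' and 'nColumns' must be positive")
    if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
        stop("'background' must be a positive distribution summing to 1")
    roles <- integer(0)
    if (!is.null(coevolvingPairs)) {
        stopifnot(all(c("colA", "colB", "coupling") %in%
                          names(coevolvingPairs)))
        if (any(coevolvingPairs$coupling < 0 | coevolvingPairs$coupling > 1))
            stop("coupling strengths must lie in [0, 1]")
        roles <- c(roles, coevolvingPairs$colA, coevolvingPairs$colB)
    }
    if (!is.null(conservedColumns)) {
        stopifnot(all(c("col", "residue") %in% names(conservedColumns)))
        roles <- c(roles, conservedColumns$col)
    }
    if (length(roles) && (anyDuplicated(roles) || any(roles < 1L) ||
                          any(roles > nColumns)))
        stop("special columns must be within range and mutually disjoint")
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        }
        set.seed(seed)
    }
    aa <- names(background)
    m <- matrix(sample(aa, nSequences * nColumns, replace = TRUE,
                       prob = background),
                nrow = nSequences, ncol = nColumns)
    if (!is.null(conservedColumns))
        for (i in seq_len(nrow(conservedColumns)))
            m[, conservedColumns$col[i]] <-
                toupper(conservedColumns$residue[i])
    if (!is.null(coevolvingPairs)) {
        for (i in seq_len(nrow(coevolvingPairs))) {
            a <- coevolvingPairs$colA[i]
            b <- coevolvingPairs$colB[i]
            cpl <- coevolvingPairs$coupling[i]
            perm <- sample(aa)
            names(perm) <- aa
            copy <- stats::runif(nSequences) < cpl
            m[copy, b] <- perm[m[copy, a]]
        }
    }
    CoevolMSA(apply(m, 1L, paste, collapse = ""),
              ids = paste0("sim", seq_len(nSequences)))
}
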