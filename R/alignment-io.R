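#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm 1.0 (PFAM) file into a
#' [CoevolMSA-class]. Symbols are uppercased; the gap characters \code{"."}
#' and \code{"-"} (and \code{"~"}) are normalized to \code{"-"}; the
#' ambiguity codes B, Z, X, J, U and O are mapped to the gap symbol. Only
#' sequence lines of a Stockholm file are consumed; annotation lines are
#' ignored. The column map of a freshly read alignment is the identity.
#'
#' @param path path to the alignment file.
#' @param format \code{"fasta"} or \code{"stockholm"}.
#' @return A [CoevolMSA-class] object.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeMsa(toyMsa(), f)
#' msa <- readMsa(f)
#' nColumns(msa)
#' @export
readMsa <- function(path, format = c("fasta", "stockholm")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("cannot read alignment: file not found: ", path)
    aln <- tryCatch(
        Biostrings::readAAMultipleAlignment(path, format = format),
        error = function(e)
            stop("failed to parse ", format, " alignment '", path, "': ",
                 conditionMessage(e), call. = FALSE))
    if (nrow(aln) == 0L)
        stop("empty alignment: no sequences in ", path)
    CoevolMSA(as.character(Biostrings::unmasked(aln)),
              ids = rownames(aln))
}

#' Write an alignment to FASTA
#'
#' @param msa a [CoevolMSA-class] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMsa <- function(msa, path) {
    stopifnot(is(msa, "CoevolMSA"))
    seqs <- apply(msa@seqs, 1L, paste, collapse = "")
    x <- Biostrings::AAStringSet(seqs)
    names(x) <- sequenceIds(msa)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

# fraction of identical non-gap residues over columns where both rows are
# non-gap; 0 when no such column exists
.pairIdentity <- function(a, b) {
    both <- a != .GAP & b != .GAP
    n <- sum(both)
    if (n == 0L) return(0)
    sum(a[both] == b[both]) / n
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Sequences are scanned in input order; a sequence is removed when its
#' pairwise identity to an earlier-retained representative is at or above
#' \code{threshold}. Identity between two rows is the fraction of identical
#' residues over the columns where both rows are non-gap (0 when no such
#' column exists). This greedy representative selection (CD-HIT-like) is
#' deterministic and preserves the input order of retained sequences.
#'
#' @param msa a [CoevolMSA-class] object.
#' @param threshold identity fraction in (0, 1]; the conventional
#'   redundancy-removal level is 0.9.
#' @return A [CoevolMSA-class] with redundant sequences removed.
#' @examples
#' msa <- CoevolMSA(c("ACDEF", "ACDEF", "TWYVH"))
#' nSequences(clusterByIdentity(msa, 0.9))
#' @export
clusterByIdentity <- function(msa, threshold = 0.9) {
    stopifnot(is(msa, "CoevolMSA"))
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold <= 0 || threshold > 1)
        stop("'threshold' must be a single number in (0, 1]")
    m <- msa@seqs
    keep <- integer(0)
    for (i in seq_len(nrow(m))) {
        redundant <- FALSE
        for (j in keep) {
            if (.pairIdentity(m[i, ], m[j, ]) >= threshold) {
                redundant <- TRUE
                break
            }
        }
        if (!redundant) keep <- c(keep, i)
    }
    new("CoevolMSA", seqs = m[keep, , drop = FALSE],
        columnMap = msa@columnMap)
}

#' Remove columns with too many gaps
#'
#' Retains exactly the columns whose gap fraction is at most
#' \code{maxGapFraction}; columns with strictly more gaps are removed
#' (so a 4-row column with one gap survives the conventional 25% level).
#' The column map is updated to the surviving original positions.
#'
#' @param msa a [CoevolMSA-class] object.
#' @param maxGapFraction allowed gap fraction in [0, 1]; conventional
#'   value 0.25.
#' @return A [CoevolMSA-class] with high-gap columns removed. If no column
#'   survives, a 0-column alignment is returned with a warning.
#' @examples
#' msa <- CoevolMSA(c("A-C", "AAC", "A-C", "AAC"))
#' columnMap(filterGapColumns(msa, 0.25))
#' @export
filterGapColumns <- function(msa, maxGapFraction = 0.25) {
    stopifnot(is(msa, "CoevolMSA"))
    if (!is.numeric(maxGapFraction) || length(maxGapFraction) != 1L ||
        is.na(maxGapFraction) || maxGapFraction < 0 || maxGapFraction > 1)
        stop("'maxGapFraction' must be a single number in [0, 1]")
    gapFrac <- colMeans(msa@seqs == .GAP)
    keep <- which(gapFrac <= maxGapFraction)
    if (length(keep) == 0L)
        warning("all columns exceed the gap threshold; ",
                "returning a 0-column alignment")
    new("CoevolMSA", seqs = msa@seqs[, keep, drop = FALSE],
        columnMap = msa@columnMap[keep])
}

#' Check that an alignment is deep enough for reliable MI estimates
#'
#' Mutual-information estimates from shallow alignments are dominated by
#' finite-sample noise; a commonly used rule requires strictly more than
#' 125 sequences. This check never aborts: the pipeline warns and
#' proceeds, so small illustrative alignments remain runnable.
#'
#' @param msa a [CoevolMSA-class] object.
#' @param minSequences depth bound; the alignment passes when it has
#'   strictly more sequences than this.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' validateDepth(toyMsa())       # FALSE: 6 sequences
#' @export
validateDepth <- function(msa, minSequences = 125) {
    stopifnot(is(msa, "CoevolMSA"))
    nSequences(msa) > minSequences
}
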