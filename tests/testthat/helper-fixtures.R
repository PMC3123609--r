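# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdir().

toyRows <- c("DAWAEE", "DAWAEF", "DAWAED", "DAYCMD", "DAYCMT", "DAYCMT")

writeToyFasta <- function(rows = toyRows, ids = paste0("toy", seq_along(rows))) {
    f <- tempfile(fileext = ".fasta")
    writeLines(c(rbind(paste0(">", ids), rows)), f)
    f
}

writeToyStockholm <- function(rows = toyRows,
                              ids = paste0("toy", seq_along(rows))) {
    f <- tempfile(fileext = ".sto")
    writeLines(c("# STOCKHOLM 1.0",
                 "#=GF ID toy",
                 paste(ids, rows),
                 "//"), f)
    f
}

# brute-force pairwise identity oracle, independent of the package internals
bruteIdentity <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    both <- av != "-" & bv != "-"
    if (!sum(both)) return(0)
    mean(av[both] == bv[both])
}

randomMsa <- function(n, L, seed) simulateMsa(n, L, seed = seed)

# Reference score tables for the built-in toy alignment (3-decimal values
# of all four normalized measures; upper triangle, columns 1..6).
toyExpected <- list(
    MI = rbind(
        c(0, 0, 0,     0,     0,     0),
        c(0, 0, 0,     0,     0,     0),
        c(0, 0, 0,     1,     1,     0.296),
        c(0, 0, 1,     0,     1,     0.296),
        c(0, 0, 1,     1,     0,     0.296),
        c(0, 0, 0.296, 0.296, 0.296, 0)),
    MIB = rbind(
        c(0,     0,     0.138, 0.237, 0.141, 0.003),
        c(0,     0,     0.138, 0.237, 0.141, 0.003),
        c(0.138, 0.138, 0,     1.375, 1.279, 0.360),
        c(0.237, 0.237, 1.375, 0,     1.378, 0.404),
        c(0.141, 0.141, 1.279, 1.378, 0,     0.362),
        c(0.003, 0.003, 0.360, 0.404, 0.362, 0)),
    MIP = rbind(
        c(0, 0, 0, 0,     0,     0),
        c(0, 0, 0, 0,     0,     0),
        c(0, 0, 0, 0,     0,     0),
        c(0, 0, 0, 0,     0.077, 0.037),
        c(0, 0, 0, 0.077, 0,     0.053),
        c(0, 0, 0, 0.037, 0.053, 0)),
    MIBP = rbind(
        c(0,      33.425, 36.015, 29.586, 3.655, 5.364),
        c(33.425, 0,      23.395, 25.528, 3.075, 4.642),
        c(36.015, 23.395, 0,      27.707, 3.387, 5.030),
        c(29.586, 25.528, 27.707, 0,      3.431, 4.476),
        c(3.655,  3.075,  3.387,  3.431,  0,     1.854),
        c(5.364,  4.642,  5.030,  4.476,  1.854, 0)))

# a PairScoreMatrix with given normalized upper-triangle scores, for conn
# tests that need arbitrary matrices
makeScoreMatrix <- function(L, scores, measure = "MI") {
    m <- matrix(0, L, L, dimnames = list(seq_len(L), seq_len(L)))
    m[upper.tri(m)] <- scores
    m <- m + t(m)
    new("PairScoreMatrix", raw = m, normalized = m, measure = measure,
        columnMap = seq_len(L))
}
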