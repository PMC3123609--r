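test_that("FASTA reading yields a validated, normalized alignment", {
    msa <- readMsa(writeToyFasta())
    expect_s4_class(msa, "CoevolMSA")
    expect_equal(nSequences(msa), 6L)
    expect_equal(nColumns(msa), 6L)
    expect_equal(columnMap(msa), 1:6)
    expect_equal(unname(apply(as.matrix(msa), 1, paste, collapse = "")),
                 toyRows)

    # minimal well-formed input: a single sequence is not an error at read
    one <- readMsa(writeToyFasta("acd", "s1"))
    expect_equal(dim(as.matrix(one)), c(1L, 3L))
    expect_equal(as.vector(as.matrix(one)), c("A", "C", "D")) # uppercased

    # ambiguity codes are mapped to the gap symbol
    amb <- readMsa(writeToyFasta("AXBZ", "s1"))
    expect_equal(as.vector(as.matrix(amb)), c("A", "-", "-", "-"))
})

test_that("malformed input is rejected with an informative error", {
    expect_error(readMsa(tempfile()), "not found")
    ragged <- tempfile(fileext = ".fasta")
    writeLines(c(">a", "ACDE", ">b", "AC"), ragged)
    expect_error(readMsa(ragged))
    empty <- tempfile(fileext = ".fasta")
    writeLines(character(0), empty)
    expect_error(readMsa(empty))
})

test_that("Stockholm gaps '.' and '-' are normalized and round-trip", {
    f <- writeToyStockholm(c("AC.D-", "AC-DW"), c("s1", "s2"))
    msa <- readMsa(f, format = "stockholm")
    expect_equal(as.vector(t(as.matrix(msa))),
                 c("A", "C", "-", "D", "-", "A", "C", "-", "D", "W"))
    # read -> write -> read is a fixed point on symbols and ids
    out <- tempfile(fileext = ".fasta")
    writeMsa(msa, out)
    again <- readMsa(out)
    expect_identical(as.matrix(again), as.matrix(msa))
    expect_identical(sequenceIds(again), sequenceIds(msa))

    f2 <- writeToyFasta()
    msa2 <- readMsa(f2)
    out2 <- tempfile(fileext = ".fasta")
    writeMsa(msa2, out2)
    expect_identical(as.matrix(readMsa(out2)), as.matrix(msa2))
})

test_that("identity clustering removes redundant sequences greedily", {
    dup <- CoevolMSA(c("ACDEFGHIKL", "ACDEFGHIKL", "WYYWVTSRQP"))
    expect_equal(nSequences(clusterByIdentity(dup, 0.9)), 2L)
    # retained order preserved, first-in-wins
    expect_equal(sequenceIds(clusterByIdentity(dup, 0.9)),
                 c("seq1", "seq3"))

    # the toy alignment carries one exact duplicate (rows 5 and 6); all
    # other pairs are at identity 5/6 < 0.9, so clustering at 0.9 keeps 5
    toy <- toyMsa()
    expect_equal(nSequences(clusterByIdentity(toy, 0.9)), 5L)
    ids <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
        bruteIdentity(toyRows[i], toyRows[j])))
    expect_equal(max(ids[upper.tri(ids)]), 1)        # rows 5 == 6
    ids[5, 6] <- ids[6, 5] <- 0
    expect_equal(max(ids[upper.tri(ids)]), 5 / 6)    # everything else

    # threshold 1.0 is a no-op in the absence of exact duplicates
    noDup <- CoevolMSA(toyRows[1:5])
    expect_equal(nSequences(clusterByIdentity(noDup, 1.0)), 5L)

    expect_error(clusterByIdentity(toy, 0), "single number")
    expect_error(clusterByIdentity(toy, 1.2), "single number")
})

test_that("every removed sequence is close to a retained representative", {
    for (seed in 1:5) {
        set.seed(seed)
        msa <- simulateMsa(30, 12, seed = seed)
        m <- as.matrix(msa)
        rows <- apply(m, 1, paste, collapse = "")
        # plant near-duplicates of row 1 (identity 11/12) to force removals
        for (i in sample(2:30, 8)) {
            v <- strsplit(rows[1], "")[[1]]
            pos <- (i %% 12) + 1
            v[pos] <- setdiff(c("A", "W"), v[pos])[1]
            rows[i] <- paste(v, collapse = "")
        }
        thr <- 0.8
        kept <- clusterByIdentity(CoevolMSA(rows), thr)
        keptRows <- apply(as.matrix(kept), 1, paste, collapse = "")
        removed <- setdiff(rows, keptRows)
        expect_gt(length(removed), 0)
        for (r in removed)
            expect_true(any(vapply(keptRows, bruteIdentity, numeric(1),
                                   a = r) >= thr))
    }
})

test_that("gap-column filtering uses a strict greater-than boundary", {
    msa <- CoevolMSA(c("A-CA", "AACA", "A-C-", "AAC-"))
    # col2: 50% gaps (removed); col4: 50% (removed); col1/3: 0%
    kept <- filterGapColumns(msa, 0.25)
    expect_equal(columnMap(kept), c(1L, 3L))

    # exactly 25% gaps in a 4-row column is retained
    msa2 <- CoevolMSA(c("A-", "AA", "AA", "AA"))
    expect_equal(columnMap(filterGapColumns(msa2, 0.25)), c(1L, 2L))

    # gap-free alignment unchanged, identity column map
    toy <- filterGapColumns(toyMsa(), 0.25)
    expect_equal(columnMap(toy), 1:6)

    # filtered gap fractions all within bound (direct invariant)
    msa3 <- simulateMsa(20, 10, seed = 3)
    m <- as.matrix(msa3)
    m[sample(length(m), 60)] <- "-"
    msa3 <- CoevolMSA(apply(m, 1, paste, collapse = ""))
    out <- filterGapColumns(msa3, 0.25)
    if (nColumns(out) > 0)
        expect_true(all(colMeans(as.matrix(out) == "-") <= 0.25))

    # all columns removed: 0-column alignment plus a warning
    allgap <- CoevolMSA(c("A-", "--", "--", "--"))
    expect_warning(res <- filterGapColumns(allgap, 0.25), "0-column")
    expect_equal(nColumns(res), 0L)
})

test_that("depth validation is a strict inequality and never aborts", {
    big <- simulateMsa(126, 3, seed = 1)
    expect_true(validateDepth(big, 125))
    expect_false(validateDepth(simulateMsa(125, 3, seed = 1), 125))
    expect_false(validateDepth(toyMsa()))
})
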