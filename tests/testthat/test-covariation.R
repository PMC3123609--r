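test_that("column distributions ignore gaps and sum to one", {
    toy <- toyMsa()
    c1 <- columnDistribution(toy, 1)
    expect_equal(unname(c1$frequencies["D"]), 1)
    expect_equal(sum(c1$frequencies), 1)
    c6 <- columnDistribution(toy, 6)
    expect_equal(unname(c6$frequencies[c("E", "F", "D", "T")]),
                 c(1, 1, 2, 2) / 6)

    gappy <- CoevolMSA(c("A", "-", "A", "-"))
    cd <- columnDistribution(gappy, 1)
    expect_equal(unname(cd$frequencies["A"]), 1)
    expect_equal(cd$effectiveCount, 2L)
})

test_that("joint distributions are taken over jointly non-gap rows", {
    toy <- toyMsa()
    j34 <- jointDistribution(toy, 3, 4)
    expect_equal(j34$frequencies["W", "A"], 0.5)
    expect_equal(j34$frequencies["Y", "C"], 0.5)
    expect_equal(sum(j34$frequencies), 1)
    expect_equal(jointDistribution(toy, 1, 2)$frequencies["D", "A"], 1)

    # marginalization identity on gap-free input
    j <- jointDistribution(toy, 3, 6)
    expect_equal(rowSums(j$frequencies),
                 columnDistribution(toy, 3)$frequencies)
    expect_equal(colSums(j$frequencies),
                 columnDistribution(toy, 6)$frequencies)

    # restriction to jointly non-gap rows
    g <- CoevolMSA(c("AC", "A-", "-C", "WD"))
    jg <- jointDistribution(g, 1, 2)
    expect_equal(jg$effectiveCount, 2L)
    expect_equal(jg$frequencies["A", "C"], 0.5)
})

test_that("joint entropy follows the 0 log 0 convention", {
    toy <- toyMsa()
    expect_equal(jointEntropy(jointDistribution(toy, 1, 2)), 0)
    expect_equal(jointEntropy(jointDistribution(toy, 3, 4)), log(2))
    expect_equal(jointEntropy(jointDistribution(toy, 3, 4), base = 2), 1)
    # H(K,L) >= max(H(K), H(L)) on all toy pairs
    for (k in 1:5) for (l in (k + 1):6) {
        hkl <- jointEntropy(jointDistribution(toy, k, l))
        hk <- jointEntropy(columnDistribution(toy, k)$frequencies)
        hl <- jointEntropy(columnDistribution(toy, l)$frequencies)
        expect_gte(hkl + 1e-12, max(hk, hl))
    }
})

test_that("the modified marginal removes the background tilt", {
    q <- blosum62Background()
    cd <- columnDistribution(toyMsa(), 5)$frequencies
    m <- modifiedMarginal(cd, q)
    expect_equal(sum(m), 1)
    # the rarer residue (M) is up-weighted relative to E after dividing
    # out the background
    expect_gt(m[["M"]], cd[["M"]])
    expect_gt(m[["M"]], m[["E"]])
    # a conserved column keeps a point mass wherever it is conserved
    cons <- modifiedMarginal(columnDistribution(toyMsa(), 1)$frequencies, q)
    expect_equal(unname(cons["D"]), 1)
    # uniform background leaves the marginal unchanged
    u <- setNames(rep(1 / 20, 20), names(q))
    expect_equal(modifiedMarginal(cd, u)[cd > 0], cd[cd > 0])
    expect_error(modifiedMarginal(cd * 0, q), "degenerate")
})

test_that("MI' matches the reference values and conventions on the toy", {
    toy <- toyMsa()
    mi <- normalizedScores(scoreAllPairs(toy, "MI"))
    expect_equal(mi[3, 4], 1)
    expect_equal(round(mi[3, 6], 3), 0.296)
    expect_equal(mi[1, 3], 0)   # conserved column forces MI' = 0
    expect_true(all(mi >= 0 & mi <= 1))
})

test_that("MIB' distinguishes conserved columns; MIP'/MIBP' follow their conventions", {
    toy <- toyMsa()
    mib <- normalizedScores(scoreAllPairs(toy, "MIB"))
    expect_equal(round(mib[1, 4], 3), 0.237)
    expect_equal(round(mib[4, 5], 3), 1.378)  # MIB' may exceed 1
    mip <- normalizedScores(scoreAllPairs(toy, "MIP"))
    expect_equal(round(mip[4, 5], 3), 0.077)
    expect_equal(round(mip[5, 6], 3), 0.053)
    # W/Y are property-identical, so column 3 is property-conserved
    expect_equal(unname(mip[3, ]), rep(0, 6))
    mibp <- normalizedScores(scoreAllPairs(toy, "MIBP"))
    expect_equal(round(mibp[1, 2], 3), 33.425)  # no conserved short-circuit
    expect_equal(round(mibp[4, 6], 3), 4.476)
})

test_that("property-identical alphabets force MIP' to zero", {
    # columns over {G,A} and over {I,L} are property-conserved
    set.seed(7)
    ga <- paste0(sample(c("G", "A"), 30, TRUE))
    il <- paste0(sample(c("I", "L"), 30, TRUE))
    other <- sample(c("D", "K", "W", "S"), 30, TRUE)
    msa <- CoevolMSA(paste0(ga, il, other))
    mip <- normalizedScores(scoreAllPairs(msa, "MIP"))
    expect_equal(unname(mip[1, ]), rep(0, 3))
    expect_equal(unname(mip[2, ]), rep(0, 3))
})

test_that("raw MI obeys the entropy identity on gap-free pairs", {
    for (seed in 1:10) {
        msa <- randomMsa(25, 6, seed)
        raw <- rawScores(scoreAllPairs(msa, "MI"))
        for (k in 1:5) for (l in (k + 1):6) {
            hk <- jointEntropy(columnDistribution(msa, k)$frequencies)
            hl <- jointEntropy(columnDistribution(msa, l)$frequencies)
            hkl <- jointEntropy(jointDistribution(msa, k, l))
            expect_equal(raw[k, l], hk + hl - hkl, tolerance = 1e-9)
        }
    }
})

test_that("all measures are symmetric and base-invariant", {
    msa <- randomMsa(40, 6, seed = 11)
    for (meas in c("MI", "MIB", "MIP", "MIBP")) {
        nat <- scoreAllPairs(msa, meas)
        bit <- scoreAllPairs(msa, meas, base = 2)
        expect_identical(normalizedScores(nat), t(normalizedScores(nat)))
        # raw scores scale with the base, normalized scores do not
        expect_equal(rawScores(bit), rawScores(nat) / log(2),
                     tolerance = 1e-12)
        expect_equal(normalizedScores(bit), normalizedScores(nat),
                     tolerance = 1e-12)
    }
    # MIBP on a doubly conserved pair reports the raw value, which is
    # base-dependent by construction
    cons <- CoevolMSA(c("DA", "DA", "DA"))
    n2 <- normalizedScores(scoreAllPairs(cons, "MIBP", base = 2))
    ne <- normalizedScores(scoreAllPairs(cons, "MIBP"))
    expect_equal(n2[1, 2], ne[1, 2] / log(2), tolerance = 1e-12)
})

test_that("uniform backgrounds collapse MIB' onto MI'", {
    u <- setNames(rep(1 / 20, 20), names(blosum62Background()))
    toy <- toyMsa()
    expect_equal(normalizedScores(scoreAllPairs(toy, "MIB", q = u)),
                 normalizedScores(scoreAllPairs(toy, "MI")),
                 ignore_attr = TRUE, tolerance = 1e-12)
    msa <- randomMsa(30, 5, seed = 2)
    expect_equal(normalizedScores(scoreAllPairs(msa, "MIB", q = u)),
                 normalizedScores(scoreAllPairs(msa, "MI")),
                 ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("degenerate pairs are flagged, not scored", {
    msa <- CoevolMSA(c("A-C", "A-C", "-AC"))  # cols 1,2 never jointly non-gap
    psm <- scoreAllPairs(msa, "MI")
    expect_true(is.na(normalizedScores(psm)[1, 2]))
    expect_false(is.na(normalizedScores(psm)[1, 3]))
    ps <- pairScore(msa, 1, 2, "MI")
    expect_true(ps$degenerate)
})

test_that("scoreAllPairs agrees with pairScore and handles minimal input", {
    msa <- randomMsa(20, 4, seed = 5)
    psm <- scoreAllPairs(msa, "MIB")
    for (k in 1:3) for (l in (k + 1):4)
        expect_equal(normalizedScores(psm)[k, l],
                     pairScore(msa, k, l, "MIB")$normalized)
    expect_equal(sum(upper.tri(normalizedScores(
        scoreAllPairs(randomMsa(10, 2, seed = 1), "MI")))), 1L)
    expect_error(scoreAllPairs(CoevolMSA("A"), "MI"), "at least 2")
    expect_true(all(diag(normalizedScores(psm)) == 0))
})
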