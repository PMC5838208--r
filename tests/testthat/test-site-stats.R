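test_that("pooled ecdf matches a sort-and-count oracle", {
    b <- matrix(c(0.2, 0.8, 0.5, 0.4), 2,
                dimnames = list(c("cg1", "cg2"), c("r1", "c1")))
    bs <- BetaSet(b, c(r1 = "REF", c1 = "CASE"))
    e <- pooledEcdf(bs, "REF")
    expect_equal(e$ecdf(0.2), 0.5)
    expect_equal(e$ecdf(0.8), 1.0)
    set.seed(5)
    bs2 <- make_toy_beta(10, 4, 6, seed = 5)
    e2 <- pooledEcdf(bs2, "CASE")
    v <- as.numeric(betaValues(bs2)[, sampleRole(bs2) == "CASE"])
    for (p in v)  # brute-force counting at every sample point
        expect_equal(e2$ecdf(p), mean(v <= p))
    b[ , 1] <- NA
    expect_error(pooledEcdf(BetaSet(b, c(r1 = "REF", c1 = "CASE")), "REF"),
                 "no non-missing")
})

test_that("Cohen's d follows the pooled-sd formula and is antisymmetric", {
    x <- c(1, 1, 3, 3); y <- c(0, 0, 2, 2)
    expect_equal(cohensD(x, y), sqrt(3) / 2, tolerance = 1e-12)
    expect_equal(cohensD(y, x), -cohensD(x, y))
    expect_equal(cohensD(x, x), 0)
    expect_error(cohensD(c(1, 1), c(1, 1)), "zero pooled variance")
    expect_error(cohensD(1, c(1, 2)), "at least 2")
})

test_that("Cramer's V: perfect association, permutation invariance, range", {
    expect_equal(cramersV(matrix(c(10, 0, 0, 10), 2))$V, 1)
    set.seed(8)
    for (i in 1:20) {
        tab <- matrix(rpois(9, 20) + 1, 3)
        v <- cramersV(tab)$V
        expect_gte(v, 0); expect_lte(v, 1)
        perm <- sample(3)
        expect_equal(cramersV(tab[perm, perm])$V, v)
    }
    expect_error(cramersV(matrix(c(0, 0, 1, 2), 2)), "degenerate margin")
})

test_that("one-sample test vs 0.5: exact enumeration cases", {
    # n = 5, all below 0.5: most extreme of the 2^5 sign assignments
    expect_equal(oneSampleTestVsHalf(c(0.1, 0.2, 0.3, 0.4, 0.45), "less"),
                 1 / 32)
    # single observation: one of two signs
    expect_equal(oneSampleTestVsHalf(0.6, "greater"), 0.5)
    # all values exactly 0.5: degenerate, p = 1
    p <- oneSampleTestVsHalf(c(0.5, 0.5), "greater")
    expect_equal(as.numeric(p), 1)
    expect_true(isTRUE(attr(p, "degenerate")))
    # exact-test identity on tie-free data: p_less + p_greater = 1 + P(T = t)
    set.seed(9)
    v <- runif(6)
    r <- rank(abs(v - 0.5)); vstat <- sum(r[v > 0.5])
    pl <- oneSampleTestVsHalf(v, "less")
    pg <- oneSampleTestVsHalf(v, "greater")
    expect_equal(as.numeric(pl + pg), 1 + dsignrank(vstat, length(v)),
                 tolerance = 1e-12)
})

test_that("signed-rank p-values agree with stats::wilcox.test and enumeration", {
    set.seed(10)
    for (i in 1:25) {
        n <- sample(2:8, 1)
        v <- round(runif(n), 3)
        v <- v[v != 0.5]
        for (side in c("less", "greater")) {
            mine <- oneSampleTestVsHalf(v, side)
            refp <- suppressWarnings(
                wilcox.test(v, mu = 0.5, alternative = side)$p.value)
            expect_equal(as.numeric(mine), refp, tolerance = 1e-12)
            expect_equal(as.numeric(mine), sr_enum_oracle(v, 0.5, side),
                         tolerance = 1e-12)
        }
    }
    # tied data: tie-corrected normal approximation matches wilcox.test
    v <- c(0.4, 0.4, 0.6, 0.7, 0.7, 0.7, 0.2, 0.9)
    for (side in c("less", "greater"))
        expect_equal(as.numeric(oneSampleTestVsHalf(v, side)),
                     suppressWarnings(wilcox.test(v, mu = 0.5, correct = TRUE,
                         alternative = side)$p.value), tolerance = 1e-12)
})

test_that("two-sample shift test: exact values, identities, wilcox.test parity", {
    expect_equal(twoSampleShiftTest(c(3, 4), c(1, 2), 0, "greater"), 1 / 6)
    # no separation: p >= 0.5 both sides
    x <- c(0.2, 0.4, 0.6)
    expect_gte(twoSampleShiftTest(x, x, 0, "greater"), 0.5)
    expect_gte(twoSampleShiftTest(x, x, 0, "less"), 0.5)
    expect_error(twoSampleShiftTest(numeric(0), x), "empty group")
    set.seed(12)
    for (i in 1:25) {
        m <- sample(2:6, 1); n <- sample(2:6, 1)
        case <- runif(m); ref <- runif(n)
        shift <- sample(c(0, 0.05, 0.2), 1)
        for (side in c("greater", "less")) {
            mine <- twoSampleShiftTest(case, ref, shift, side)
            refp <- suppressWarnings(wilcox.test(case, ref, mu = shift,
                alternative = side)$p.value)
            expect_equal(mine, refp, tolerance = 1e-12)
        }
    }
    # tied data falls back to the tie-corrected normal approximation
    case <- c(0.3, 0.3, 0.5, 0.8); ref <- c(0.3, 0.5, 0.5, 0.1)
    for (side in c("greater", "less"))
        expect_equal(twoSampleShiftTest(case, ref, 0, side),
                     suppressWarnings(wilcox.test(case, ref, correct = TRUE,
                         alternative = side)$p.value), tolerance = 1e-12)
    # Welch alternative
    expect_equal(twoSampleShiftTest(case, ref, 0.1, "greater", family = "t"),
                 t.test(case, ref, mu = 0.1, alternative = "greater")$p.value)
})

test_that("shift test at the true offset is calibrated (conservative)", {
    # planted location shift of 0.05; testing at that same shift must keep
    # the rejection rate at or below the nominal one-sided level
    set.seed(13)
    n_rep <- 2000; alpha <- 0.025
    rej <- logical(n_rep)
    for (i in seq_len(n_rep)) {
        ref <- rbeta(5, 30, 70)
        case <- rbeta(14, 30, 70) + 0.05
        rej[i] <- twoSampleShiftTest(case, ref, 0.05, "greater") < alpha
    }
    mc_se <- sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(rej), alpha + 2 * mc_se)
})

test_that("Hodges-Lehmann equals the exhaustive pairwise-median oracle", {
    expect_equal(hodgesLehmann(c(0.6, 0.7), c(0.5, 0.55)), 0.125)
    expect_equal(hodgesLehmann(c(0.3), c(0.3)), 0)
    set.seed(14)
    for (i in 1:50) {
        case <- runif(sample(1:8, 1)); ref <- runif(sample(1:8, 1))
        expect_equal(hodgesLehmann(case, ref), hl_oracle(case, ref))
        expect_equal(hodgesLehmann(ref, case), -hodgesLehmann(case, ref))
    }
})

test_that("Storey q-values: BH equality at pi0 = 1, monotonicity, bounds", {
    set.seed(15)
    p <- c(runif(80), runif(20, 0, 0.01))
    q1 <- storeyQvalues(p, pi0 = 1)$q
    expect_equal(q1, p.adjust(p, "BH"), tolerance = 1e-12)
    st <- storeyQvalues(p)
    expect_gt(st$pi0, 0); expect_lte(st$pi0, 1)
    expect_true(all(st$q >= 0 & st$q <= 1))
    o <- order(p)
    expect_true(all(diff(st$q[o]) >= -1e-12))       # monotone in p
    expect_true(all(st$q <= q1 + 1e-12))            # pi0 <= 1 shrinks q
    pe <- rep(0.2, 5)
    expect_equal(length(unique(storeyQvalues(pe)$q)), 1L)  # ties stay tied
    expect_lte(storeyQvalues(0.02)$q, 0.02)
    expect_error(storeyQvalues(c(0.5, 1.2)), "in \\[0,1\\]")
})

test_that("Dice index handles identical, disjoint and published-size overlaps", {
    expect_equal(diceIndex(c("a", "b"), c("a", "b")), 1)
    expect_equal(diceIndex(c("a"), c("b")), 0)
    expect_equal(diceIndex(character(), character()), 0)
    # two detectors of 28089 and 29609 sites sharing 18367
    a <- sprintf("s%05d", 1:28089)
    b <- sprintf("s%05d", c(1:18367, 40000:51241))
    expect_equal(diceIndex(a, b), 2 * 18367 / (28089 + 29609),
                 tolerance = 1e-12)
    expect_equal(round(diceIndex(a, b), 2), 0.64)
})

test_that("skewness matches the moment definition", {
    set.seed(16)
    x <- rgamma(500, 2)
    m3 <- mean((x - mean(x))^3); m2 <- mean((x - mean(x))^2)
    expect_equal(skewness(x), m3 / m2^1.5, tolerance = 1e-12)
    expect_equal(skewness(c(-1, 0, 1)), 0)
})

test_that("siteTests assembles HL, p, q and status columns consistently", {
    bs <- make_toy_beta(12, 5, 14, seed = 17)
    res <- siteTests(bs)
    expect_identical(nrow(res), 12L)
    b <- betaValues(bs); refc <- sampleRole(bs) == "REF"
    i <- 7
    expect_equal(res$hl[i], hodgesLehmann(b[i, !refc], b[i, refc]))
    expect_equal(res$p_up[i],
                 twoSampleShiftTest(b[i, !refc], b[i, refc], 0, "greater"))
    expect_true(all(res$status_case %in% c("low", "medium", "high")))
    # CASE group has 14 samples: status must match the one-sample calls
    expect_identical(res$status_case,
                     ifelse(res$p_low_case < 0.025, "low",
                            ifelse(res$p_high_case < 0.025, "high", "medium")))
    expect_error(siteTests(bs[0, ]), "empty")
    f <- tempfile(fileext = ".tsv")
    writeSiteResults(res, f)
    res2 <- readSiteResults(f)
    expect_equal(res2$hl, res$hl)
    expect_identical(res2$status_ref, res$status_ref)
})
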