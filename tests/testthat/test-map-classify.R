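test_that("weighted-density crossings solve the quadratic exactly", {
    # equal sigma, equal weight: single crossing at the midpoint
    expect_equal(componentIntersections(c(0, 1, 0.5), c(2, 1, 0.5)), 1)
    expect_error(componentIntersections(c(0, 1, 0.5), c(0, 1, 0.5)),
                 "identical components")
    # equal mean and sigma, different weight: parallel, no crossing
    expect_length(componentIntersections(c(0, 1, 0.3), c(0, 1, 0.7)), 0L)
    set.seed(30)
    for (i in 1:50) {
        c1 <- c(runif(1, -0.3, 0.3), runif(1, 0.005, 0.2), runif(1, 0.1, 0.9))
        c2 <- c(runif(1, -0.3, 0.3), runif(1, 0.005, 0.2), runif(1, 0.1, 0.9))
        r <- componentIntersections(c1, c2)
        for (x in r) {
            d1 <- c1[3] * dnorm(x, c1[1], c1[2])
            d2 <- c2[3] * dnorm(x, c2[1], c2[2])
            expect_lt(abs(d1 - d2), 1e-12)
        }
    }
})

test_that("the published-model component pair crosses near the medium cutoff", {
    r <- componentIntersections(c(0.0019, 0.0051, 0.2148),
                                c(0.0128, 0.0189, 0.2645))
    upper <- max(r)
    expect_lt(abs(upper - 0.0096), 0.002)
})

test_that("MAP partition equals the dense-grid argmax oracle", {
    # two equal components: boundary at the midpoint
    m <- GaussianMixture1D(c(-0.1, 0.1), c(0.05, 0.05), c(0.5, 0.5))
    part <- mapPartition(m)
    expect_equal(part$boundary, 0, tolerance = 1e-12)
    expect_identical(part$left, 1L)
    expect_identical(part$right, 2L)
    for (s in 1:30) {
        mm <- random_mixture(sample(2:8, 1), seed = 100 + s)
        part <- mapPartition(mm)
        oracle <- grid_partition_oracle(mm, 200001L)
        # every grid transition lies within a grid step of an analytic boundary
        if (length(oracle$change_at) && nrow(part))
            for (g in oracle$change_at)
                expect_lt(min(abs(part$boundary - g)), 1.5 * oracle$step)
        # the dominant component between consecutive boundaries is as recorded
        pts <- c(min(mm@mu - 6 * mm@sigma), part$boundary,
                 max(mm@mu + 6 * mm@sigma))
        mids <- (pts[-1] + pts[-length(pts)]) / 2
        dom <- max.col(componentLogDensity(mm, mids), ties.method = "first")
        expect_identical(dom, as.integer(attr(part, "dominant")))
    }
})

test_that("tier cutoffs: order, symmetry, permutation invariance, errors", {
    # mirrored mixture: down cutoffs are the negatives of the up cutoffs
    m <- GaussianMixture1D(mu = c(-0.15, -0.06, -0.02, -0.005,
                                  0.005, 0.02, 0.06, 0.15),
                           sigma = rep(c(0.08, 0.03, 0.012, 0.004), 2)[c(1:4, 4:1)],
                           w = rep(0.125, 8))
    co <- deriveTierCutoffs(m)
    expect_equal(downCutoffs(co), -upCutoffs(co), tolerance = 1e-9)
    expect_true(all(diff(upCutoffs(co)) > 0))
    # permuting the component input order changes nothing (constructor sorts)
    perm <- sample(8)
    m2 <- GaussianMixture1D(m@mu[perm], m@sigma[perm], m@w[perm])
    expect_equal(upCutoffs(deriveTierCutoffs(m2)), upCutoffs(co))
    # a two-component model cannot support four tiers
    expect_error(deriveTierCutoffs(
        GaussianMixture1D(c(0, 0.1), c(0.01, 0.05), c(0.5, 0.5))),
        "too coarse")
})

test_that("cutoff JSON round-trips", {
    co <- deriveTierCutoffs(gse63409ShiftMixture())
    f <- tempfile(fileext = ".json")
    writeCutoffsJSON(co, f)
    co2 <- readCutoffsJSON(f)
    expect_equal(upCutoffs(co2), upCutoffs(co))
    expect_equal(downCutoffs(co2), downCutoffs(co))
})

make_call_frame <- function() {
    # hand-built site results around cutoffs (0.0096, 0.0372, 0.0819)
    data.frame(
        site_id = c("none", "sig", "medium", "high", "extreme", "down_med"),
        hl = c(0.2, 0.005, 0.02, 0.05, 0.10, -0.03),
        p_up = c(0.5, 0.01, 0.01, 0.01, 0.01, 0.99),
        p_down = c(0.5, 0.99, 0.99, 0.99, 0.99, 0.01),
        q_up = c(0.5, 0.01, 0.01, 0.01, 0.01, 0.99),
        q_down = c(0.5, 0.99, 0.99, 0.99, 0.99, 0.01),
        p_up_shift1 = c(0.5, 0.5, 0.01, 0.01, 0.01, 0.99),
        p_up_shift2 = c(0.5, 0.5, 0.50, 0.01, 0.01, 0.99),
        p_up_shift3 = c(0.5, 0.5, 0.50, 0.50, 0.01, 0.99),
        p_down_shift1 = c(0.5, 0.9, 0.9, 0.9, 0.9, 0.01),
        p_down_shift2 = c(0.5, 0.9, 0.9, 0.9, 0.9, 0.60),
        p_down_shift3 = c(0.5, 0.9, 0.9, 0.9, 0.9, 0.60),
        stringsAsFactors = FALSE)
}

test_that("site classification climbs the tier ladder with nesting", {
    co <- deriveTierCutoffs(gse63409ShiftMixture())
    res <- make_call_frame()
    calls <- classifySites(res, co)
    expect_identical(as.character(calls$tier),
                     c("none", "significant", "medium", "high", "extreme",
                       "medium"))
    expect_identical(calls$direction,
                     c("none", "up", "up", "up", "up", "down"))
    # hl below the cutoff blocks the tier even if the shifted test fires
    res2 <- res
    res2$hl[3] <- 0.005   # below the medium cutoff
    expect_identical(as.character(classifySites(res2, co)$tier)[3],
                     "significant")
    # hl_filter rule ignores shifted tests, uses the point estimate only:
    # the down site (hl = -0.03, beyond the second down cutoff -0.026)
    # climbs to "high" where the shifted test had stopped it at "medium"
    calls_f <- classifySites(res, co, tier_rule = "hl_filter")
    expect_identical(as.character(calls_f$tier),
                     c("none", "significant", "medium", "high", "extreme",
                       "high"))
    expect_error(classifySites(res[, -7], co), "shifted-test")
})

test_that("classification is monotone in HL and the tier sets nest", {
    co <- deriveTierCutoffs(gse63409ShiftMixture())
    res <- make_call_frame()
    base <- classifySites(res, co)
    for (i in seq_len(nrow(res))) {
        res_up <- res
        res_up$hl[i] <- res_up$hl[i] + 0.05  # raise HL, keep p-values
        up_calls <- classifySites(res_up, co)
        if (base$direction[i] == "up")
            expect_gte(as.integer(up_calls$tier[i]), as.integer(base$tier[i]))
    }
    counts <- table(base$tier)
    n_sig <- sum(base$direction == "up")
    expect_lte(counts[["extreme"]], counts[["extreme"]] + counts[["high"]])
    at_least_medium <- sum(as.character(base$tier) %in%
                           c("medium", "high", "extreme") &
                           base$direction == "up")
    expect_lte(at_least_medium, n_sig)
})

test_that("dynamics classes cross-tabulate baseline status and direction", {
    res <- data.frame(
        status_ref = c("high", "low", "low", "medium", "high", "low"),
        status_case = c("high", "low", "medium", "medium", "low", "high"),
        direction = c("up", "down", "up", "up", "down", "none"))
    sc <- statusContingency(res)
    # REF-high & up and REF-low & down are enhancement/diminution
    expect_equal(unname(sc$dynamics["enhancement"]), 2)
    # REF-low & up and REF-high & down are compensation
    expect_equal(unname(sc$dynamics["compensation"]), 2)
    expect_equal(sum(sc$status), nrow(res))
    expect_equal(sum(sc$dynamics_table), nrow(res))
    expect_equal(unname(sc$dynamics_table["high", "up"]), 1)
})
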