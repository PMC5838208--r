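# Per-site and whole-distribution statistics.
#
# The rank tests are computed directly on base R's exact null distributions
# (pwilcox / psignrank) when the sample is small and tie-free, and with the
# tie-corrected normal approximation (continuity correction 0.5) otherwise.
# This matches stats::wilcox.test (asserted in the test suite) while being an
# order of magnitude faster per call and supporting the shifted alternative
# needed for tier testing.

# shared numerical constants
.P_CLIP <- 1e-15          # p clipped to [.P_CLIP, 1-.P_CLIP] before qnorm
.EXACT_N_MAX <- 25L       # exact rank-test enumeration up to this many obs

#' Pooled empirical distribution of beta values
#'
#' Pools every non-missing beta value of one group's samples (optionally over
#' a subset of sites) into a single sample and summarizes it. Beta values are
#' fully observed, so the Kaplan-Meier estimate of the cdf reduces to the
#' plain empirical cdf returned here.
#'
#' @param x a [BetaSet].
#' @param group `"REF"` or `"CASE"`.
#' @param sites optional character vector of site ids to restrict to.
#' @return List with `n`, `mean`, `sd`, `skewness` (moment coefficient
#'   \eqn{\gamma_1}) and `ecdf` (a [stats::ecdf] step function).
#' @export
pooledEcdf <- function(x, group = c("REF", "CASE"), sites = NULL) {
    group <- match.arg(group)
    b <- betaValues(x)[, sampleRole(x) == group, drop = FALSE]
    if (!is.null(sites)) {
        if (!length(sites)) stop("empty site subset")
        b <- b[rownames(b) %in% sites, , drop = FALSE]
    }
    v <- as.numeric(b[!is.na(b)])
    if (!length(v)) stop("no non-missing beta values in group ", group)
    list(n = length(v), mean = mean(v), sd = sd(v), skewness = skewness(v),
         ecdf = ecdf(v))
}

#' Moment coefficient of skewness
#'
#' \eqn{\gamma_1 = m_3 / m_2^{3/2}} with central sample moments.
#'
#' @param x numeric vector (NAs dropped).
#' @return Unitless skewness.
#' @export
skewness <- function(x) {
    x <- x[!is.na(x)]
    m <- mean(x)
    m2 <- mean((x - m)^2)
    mean((x - m)^3) / m2^1.5
}

#' Cohen's d effect size
#'
#' \eqn{d = (\bar x - \bar y) / s_p} with the pooled standard deviation
#' \eqn{s_p^2 = ((n_x-1)s_x^2 + (n_y-1)s_y^2)/(n_x+n_y-2)}.
#'
#' @param x,y numeric vectors with at least two values each.
#' @return Signed effect size.
#' @export
cohensD <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 values")
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
        (length(x) + length(y) - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    (mean(x) - mean(y)) / sqrt(sp2)
}

#' Cramer's V association coefficient
#'
#' Pearson chi-square association for an r x c contingency table:
#' \eqn{V = \sqrt{\chi^2 / (N (\min(r,c)-1))}}, with the chi-square p-value on
#' \eqn{(r-1)(c-1)} degrees of freedom. No continuity correction is applied.
#'
#' @param tab matrix of non-negative counts.
#' @return List with `V`, `chi2`, `df` and `p`.
#' @examples
#' cramersV(matrix(c(10, 0, 0, 10), 2))$V  # perfect association: 1
#' @export
cramersV <- function(tab) {
    tab <- as.matrix(tab)
    if (any(tab < 0)) stop("negative counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate margin: all-zero row or column")
    ch <- suppressWarnings(chisq.test(tab, correct = FALSE))
    N <- sum(tab)
    V <- sqrt(unname(ch$statistic) / (N * (min(dim(tab)) - 1)))
    list(V = V, chi2 = unname(ch$statistic), df = unname(ch$parameter),
         p = unname(ch$p.value))
}

# signed-rank test of H0: median(v) = mu against a one-sided alternative.
# Zero differences are dropped (the usual zero-difference convention).
.signedRankP <- function(v, mu, side, exact_n_max = .EXACT_N_MAX) {
    d <- v[!is.na(v)] - mu
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        return(structure(1, degenerate = TRUE))
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    ties <- any(duplicated(abs(d)))
    if (!ties && n <= exact_n_max) {
        p <- if (side == "greater") psignrank(V - 1, n, lower.tail = FALSE)
             else psignrank(V, n)
    } else {
        tt <- table(r)
        sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                      sum(tt^3 - tt) / 48)
        mu_V <- n * (n + 1) / 4
        z <- if (side == "greater") (V - mu_V - 0.5) / sigma
             else (V - mu_V + 0.5) / sigma
        p <- if (side == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
    }
    min(max(p, 0), 1)
}

#' One-sample Wilcoxon signed-rank test against beta = 0.5
#'
#' One-sided test of the site's median methylation within one group against
#' the "medium" level 0.5. Exact when the (tie-free) sample has at most
#' `exact_n_max` non-0.5 values, tie-corrected normal approximation with
#' continuity correction otherwise. Values exactly equal to 0.5 are dropped;
#' if nothing remains, p = 1 is returned with attribute `degenerate = TRUE`.
#'
#' @param values beta values of one site in one group.
#' @param side `"less"` (median < 0.5) or `"greater"` (median > 0.5).
#' @param exact_n_max sample-size bound for exact enumeration.
#' @return One-sided p-value.
#' @export
oneSampleTestVsHalf <- function(values, side = c("less", "greater"),
                                exact_n_max = .EXACT_N_MAX) {
    side <- match.arg(side)
    if (!sum(!is.na(values))) stop("no non-missing values")
    .signedRankP(values, 0.5, side, exact_n_max)
}

# Mann-Whitney p-value with a location-shift null, via the exact pwilcox
# distribution (tie-free, small n) or the tie-corrected normal approximation.
.mannWhitneyP <- function(case, ref, shift, side,
                          exact_n_max = .EXACT_N_MAX) {
    x <- case[!is.na(case)] - shift
    y <- ref[!is.na(ref)]
    m <- length(x); n <- length(y)
    if (!m || !n) stop("empty group")
    r <- rank(c(x, y))
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    ties <- any(duplicated(c(x, y)))
    if (!ties && m + n <= exact_n_max) {
        p <- if (side == "greater") pwilcox(U - 1, m, n, lower.tail = FALSE)
             else pwilcox(U, m, n)
    } else {
        tt <- table(r)
        sigma <- sqrt(m * n / 12 *
                      ((m + n + 1) - sum(tt^3 - tt) / ((m + n) * (m + n - 1))))
        if (sigma == 0) return(1)  # all values tied: no evidence either way
        mu_U <- m * n / 2
        z <- if (side == "greater") (U - mu_U - 0.5) / sigma
             else (U - mu_U + 0.5) / sigma
        p <- if (side == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
    }
    min(max(p, 0), 1)
}

#' Two-sample shift test (Mann-Whitney with an offset null)
#'
#' Tests H1: the CASE beta distribution exceeds the REF distribution by more
#' than `shift` (side `"greater"`; CASE values are reduced by `shift` before
#' ranking), or the mirrored `"less"` alternative. `shift = 0` reproduces the
#' ordinary one-sided Mann-Whitney test. Exact for small tie-free samples,
#' tie-corrected normal approximation otherwise. With
#' `family = "t"` a Welch t-test on the shifted values is used instead.
#'
#' @param case,ref numeric beta values of one site in each group.
#' @param shift the shift under the null hypothesis (delta-beta units).
#' @param side `"greater"` or `"less"`.
#' @param exact_n_max total-sample-size bound for exact enumeration.
#' @param family `"nonparametric"` (default) or `"t"`.
#' @return One-sided p-value.
#' @examples
#' twoSampleShiftTest(c(3, 4), c(1, 2), side = "greater")  # exact 1/6
#' @export
twoSampleShiftTest <- function(case, ref, shift = 0,
                               side = c("greater", "less"),
                               exact_n_max = .EXACT_N_MAX,
                               family = c("nonparametric", "t")) {
    side <- match.arg(side)
    family <- match.arg(family)
    if (family == "t") {
        x <- case[!is.na(case)]; y <- ref[!is.na(ref)]
        if (length(x) < 2L || length(y) < 2L)
            stop("t family needs at least 2 values per group")
        alt <- if (side == "greater") "greater" else "less"
        return(t.test(x, y, mu = shift, alternative = alt)$p.value)
    }
    .mannWhitneyP(case, ref, shift, side, exact_n_max)
}

#' Hodges-Lehmann shift estimate
#'
#' Median of all pairwise differences `case_i - ref_j`; a robust estimate of
#' the between-group location shift in beta (delta-beta). Positive values mean
#' up-methylation in the CASE group.
#'
#' @param case,ref numeric beta values of one site in each group.
#' @return The shift estimate, in \[-1, 1\] for beta inputs.
#' @examples
#' hodgesLehmann(c(0.6, 0.7), c(0.5, 0.55))  # 0.125
#' @export
hodgesLehmann <- function(case, ref) {
    case <- case[!is.na(case)]; ref <- ref[!is.na(ref)]
    if (!length(case) || !length(ref)) stop("empty group")
    median(outer(case, ref, "-"))
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\pi_0} on the lambda grid 0.05, 0.10,
#' ..., 0.95 with a natural cubic smoothing spline (df = 3) evaluated at the
#' largest grid point, then computes
#' \eqn{q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)} / j} (running-minimum
#' monotonicity), capped at 1. With `pi0 = 1` the q-values equal
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in \[0,1\].
#' @param lambda grid for the \eqn{\pi_0} estimate.
#' @param pi0 optional fixed \eqn{\pi_0} overriding the estimate.
#' @return List with `q` (same order as `p`) and `pi0`.
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
    if (!length(p)) stop("empty p-value vector")
    if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
    m <- length(p)
    if (is.null(pi0)) {
        pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
        fit <- smooth.spline(lambda, pi0_l, df = 3)
        pi0 <- predict(fit, x = max(lambda))$y
        pi0 <- min(max(pi0, 1 / m), 1)  # clipped into (0, 1]
    } else {
        if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0,1]")
    }
    o <- order(p)
    q_ord <- pi0 * m * p[o] / seq_len(m)
    q_ord <- rev(cummin(rev(pmin(q_ord, 1))))
    q <- numeric(m)
    q[o] <- q_ord
    list(q = q, pi0 = pi0)
}

#' Dice overlap index of two site sets
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 0 when both sets are empty.
#'
#' @param a,b character vectors of site ids (duplicates ignored).
#' @return Fraction in \[0,1\].
#' @export
diceIndex <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) && !length(b)) return(0)
    2 * length(intersect(a, b)) / (length(a) + length(b))
}

# low/medium/high status from the two one-sample p-values (alpha one-sided)
.statusCall <- function(p_low, p_high, alpha = 0.025) {
    ifelse(p_low < alpha, "low", ifelse(p_high < alpha, "high", "medium"))
}

#' Per-site test battery
#'
#' For each CpG site: the Hodges-Lehmann shift (CASE - REF), one-sided
#' Mann-Whitney p-values for up- and down-methylation, Storey q-values across
#' sites, and (optionally) the low/medium/high methylation status of each
#' group from the one-sample test against beta = 0.5 at one-sided level
#' `alpha`.
#'
#' @param x a [BetaSet].
#' @param alpha one-sided significance level used for the status calls.
#' @param include_status compute per-group status columns (4 extra rank tests
#'   per site).
#' @param exact_n_max,family passed to the underlying tests.
#' @return `data.frame` with one row per site: `site_id`, `hl`, `p_up`,
#'   `p_down`, `q_up`, `q_down`, and when requested `p_low_ref`, `p_high_ref`,
#'   `p_low_case`, `p_high_case`, `status_ref`, `status_case`.
#' @export
siteTests <- function(x, alpha = 0.025, include_status = TRUE,
                      exact_n_max = .EXACT_N_MAX,
                      family = c("nonparametric", "t")) {
    family <- match.arg(family)
    b <- betaValues(x)
    if (!nrow(b)) stop("empty beta matrix")
    refcols <- sampleRole(x) == "REF"
    res <- data.frame(site_id = rownames(b),
                      hl = NA_real_, p_up = NA_real_, p_down = NA_real_,
                      stringsAsFactors = FALSE)
    n <- nrow(b)
    hl <- numeric(n); pu <- numeric(n); pd <- numeric(n)
    if (include_status) {
        plr <- numeric(n); phr <- numeric(n)
        plc <- numeric(n); phc <- numeric(n)
    }
    for (i in seq_len(n)) {
        ref <- b[i, refcols]; case <- b[i, !refcols]
        hl[i] <- hodgesLehmann(case, ref)
        pu[i] <- twoSampleShiftTest(case, ref, 0, "greater", exact_n_max,
                                    family)
        pd[i] <- twoSampleShiftTest(case, ref, 0, "less", exact_n_max, family)
        if (include_status) {
            plr[i] <- oneSampleTestVsHalf(ref, "less", exact_n_max)
            phr[i] <- oneSampleTestVsHalf(ref, "greater", exact_n_max)
            plc[i] <- oneSampleTestVsHalf(case, "less", exact_n_max)
            phc[i] <- oneSampleTestVsHalf(case, "greater", exact_n_max)
        }
    }
    res$hl <- hl; res$p_up <- pu; res$p_down <- pd
    res$q_up <- storeyQvalues(pu)$q
    res$q_down <- storeyQvalues(pd)$q
    if (include_status) {
        res$p_low_ref <- plr; res$p_high_ref <- phr
        res$p_low_case <- plc; res$p_high_case <- phc
        res$status_ref <- .statusCall(plr, phr, alpha)
        res$status_case <- .statusCall(plc, phc, alpha)
    }
    res
}

#' @rdname siteTests
#' @param results site results data.frame.
#' @param path output TSV path.
#' @export
writeSiteResults <- function(results, path) {
    fwrite(as.data.table(results), path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' @rdname siteTests
#' @export
readSiteResults <- function(path) {
    as.data.frame(fread(path, sep = "\t", header = TRUE))
}
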