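# Maximum-probability (MAP) partition of the shift axis and tier calling.
#
# Boundaries are computed analytically: the crossing points of two weighted
# Gaussian densities solve a quadratic in x, and the MAP boundaries are the
# subset of pairwise crossings at which the argmax of the weighted component
# densities actually changes (decided by evaluating the argmax at interval
# midpoints between consecutive candidate crossings). A dense-grid argmax
# scan -- which chatters in floating point near tangential crossings -- is
# retained in the test suite as the independent oracle.

#' Crossing points of two weighted Gaussian densities
#'
#' Solves \eqn{w_1 \phi(x; \mu_1, \sigma_1) = w_2 \phi(x; \mu_2, \sigma_2)}
#' exactly via the quadratic in x: two roots when the standard deviations
#' differ and the discriminant is positive, one when they are equal (and the
#' means differ), possibly none. Roots are Newton-polished to machine
#' precision and returned sorted.
#'
#' @param c1,c2 numeric vectors `c(mu, sigma, w)` describing each component.
#' @return Sorted numeric vector of crossing points (possibly empty).
#' @examples
#' componentIntersections(c(0, 1, 0.5), c(2, 1, 0.5))  # midpoint: 1
#' @export
componentIntersections <- function(c1, c2) {
    m1 <- c1[1]; s1 <- c1[2]; w1 <- c1[3]
    m2 <- c2[1]; s2 <- c2[2]; w2 <- c2[3]
    if (s1 <= 0 || s2 <= 0) stop("sigma must be positive")
    same_s <- abs(s1 - s2) <= 1e-14 * (s1 + s2)
    if (same_s && abs(m1 - m2) <= 1e-14 * (abs(m1) + abs(m2) + 1)) {
        if (abs(w1 - w2) <= 1e-14 * (w1 + w2))
            stop("identical components: infinitely many crossing points")
        return(numeric(0))  # parallel log-densities, never equal
    }
    # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
    A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    B <- m1 / s1^2 - m2 / s2^2
    C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
    if (same_s) {
        if (abs(B) < 1e-300) return(numeric(0))
        roots <- -C / B
    } else {
        disc <- B^2 - 4 * A * C
        if (disc < 0) return(numeric(0))
        sq <- sqrt(disc)
        # numerically stable quadratic roots (avoid cancellation)
        qq <- -(B + sign(B + (B == 0)) * sq) / 2
        roots <- if (qq == 0) c(0, 0) else c(qq / A, C / qq)
        roots <- unique(roots)
    }
    # Newton polish on the quadratic (exact derivative)
    for (i in seq_along(roots)) {
        for (it in 1:3) {
            f <- A * roots[i]^2 + B * roots[i] + C
            fp <- 2 * A * roots[i] + B
            if (fp == 0) break
            roots[i] <- roots[i] - f / fp
        }
    }
    sort(roots)
}

#' Maximum-probability partition of the real line
#'
#' Partitions the shift axis by \eqn{\arg\max_k w_k \phi_k(x)}: each interval
#' is dominated by one weighted component, and the boundaries are the points
#' where the dominant component changes. Candidate points are all pairwise
#' density crossings inside `[min(mu - 6 sigma), max(mu + 6 sigma)]`; the
#' dominant component is evaluated at every interval midpoint and consecutive
#' intervals with the same argmax are merged.
#'
#' @param m a [GaussianMixture1D] with at least two components.
#' @return `data.frame` with one row per boundary: `boundary`, `left`, `right`
#'   (indices of the dominating components, in mean-sorted order, on each
#'   side). An attribute `"dominant"` carries the left-to-right sequence of
#'   dominating components.
#' @export
mapPartition <- function(m) {
    K <- nComponents(m)
    if (K < 2L) stop("at least two components required")
    lo <- min(m@mu - 6 * m@sigma)
    hi <- max(m@mu + 6 * m@sigma)
    cand <- numeric(0)
    for (i in seq_len(K - 1L))
        for (j in (i + 1L):K) {
            r <- tryCatch(
                componentIntersections(c(m@mu[i], m@sigma[i], m@w[i]),
                                       c(m@mu[j], m@sigma[j], m@w[j])),
                error = function(e) numeric(0))
            cand <- c(cand, r[r > lo & r < hi])
        }
    cand <- sort(cand)
    if (length(cand) > 1L)  # coalesce numerically identical crossings
        cand <- cand[c(TRUE, diff(cand) > 1e-12)]
    pts <- c(lo, cand, hi)
    mids <- (pts[-1L] + pts[-length(pts)]) / 2
    dom <- max.col(componentLogDensity(m, mids), ties.method = "first")
    keep <- which(diff(dom) != 0L)
    data.frame(boundary = cand[keep], left = dom[keep], right = dom[keep + 1L],
               row.names = NULL) -> out
    attr(out, "dominant") <- c(dom[keep], dom[length(dom)])
    out
}

#' Data-driven tier cutoffs from a fitted mixture
#'
#' The up-methylation cutoffs are the first three positive MAP-partition
#' boundaries (ascending): no-change/medium, medium/high and high/extreme;
#' every MAP region beyond the third boundary is merged into the extreme tier.
#' Down-methylation cutoffs are derived by the same rule on the negative side
#' whenever at least one negative-mean component dominates a region there
#' (reported separately; no published reference values exist for them).
#'
#' @param m a [GaussianMixture1D] fitted to the genome-wide shift
#'   distribution.
#' @return A [TierCutoffs-class] object; its `provenance` records which
#'   component pair produced each boundary.
#' @export
deriveTierCutoffs <- function(m) {
    if (nComponents(m) < 2L)
        stop("mixture too coarse for 4 up-methylation tiers: a single ",
             "component has no MAP boundaries; refit with more components")
    part <- mapPartition(m)
    pos <- part[part$boundary > 1e-12, , drop = FALSE]
    if (nrow(pos) < 3L)
        stop("mixture too coarse for 4 up-methylation tiers: only ",
             nrow(pos), " positive MAP boundaries (need 3); refit with more ",
             "components")
    up <- pos$boundary[1:3]
    neg <- part[part$boundary < -1e-12, , drop = FALSE]
    down <- numeric(0)
    prov <- pos[1:3, ]
    prov$side <- "up"
    dom <- attr(part, "dominant")
    neg_dominates <- any(m@mu[dom] < 0)
    if (nrow(neg) && neg_dominates) {
        o <- order(neg$boundary, decreasing = TRUE)  # from 0 outward
        take <- head(o, 3L)
        down <- neg$boundary[take]
        pn <- neg[take, ]; pn$side <- "down"
        prov <- rbind(prov, pn)
    }
    new("TierCutoffs", up = up, down = down, provenance = prov)
}

#' Classify sites into demethylation tiers
#'
#' A site's direction is `"up"` when its one-sided up-methylation p-value
#' (q-value with `use_q = TRUE`) is below `alpha`, `"down"` for the mirrored
#' test, else `"none"`. A directed site then climbs the tier ladder
#' significant -> medium -> high -> extreme: under the default
#' `tier_rule = "shifted_test"` it reaches a tier when the shifted rank test
#' at that cutoff is significant *and* its Hodges-Lehmann estimate exceeds the
#' cutoff; under `"hl_filter"` the shift-0 significance plus the HL estimate
#' alone decide. Tiers are "at least" sets and nest by construction.
#'
#' @param results site results containing `hl`, `p_up`, `p_down` (and
#'   `q_up`/`q_down` when `use_q`), plus the shifted-test columns added by
#'   [computeShiftedTests()] when `tier_rule = "shifted_test"`.
#' @param cutoffs a [TierCutoffs-class] object.
#' @param alpha one-sided significance level.
#' @param use_q gate direction calls on Storey q-values instead of raw p.
#' @param tier_rule `"shifted_test"` (default) or `"hl_filter"`.
#' @return `data.frame` with `site_id`, `direction` and ordered factor `tier`.
#' @export
classifySites <- function(results, cutoffs, alpha = 0.025, use_q = FALSE,
                          tier_rule = c("shifted_test", "hl_filter")) {
    tier_rule <- match.arg(tier_rule)
    up <- upCutoffs(cutoffs); down <- downCutoffs(cutoffs)
    pu <- if (use_q) results$q_up else results$p_up
    pd <- if (use_q) results$q_down else results$p_down
    if (is.null(pu) || is.null(pd) || is.null(results$hl))
        stop("results must carry hl, p_up and p_down columns")
    if (tier_rule == "shifted_test") {
        upcols <- paste0("p_up_shift", seq_along(up))
        if (!all(upcols %in% names(results)))
            stop("missing shifted-test column(s); run computeShiftedTests() ",
                 "with these cutoffs first")
        downcols <- paste0("p_down_shift", seq_along(down))
        if (length(down) && !all(downcols %in% names(results)))
            stop("missing shifted-test column(s) for down cutoffs")
    }
    n <- nrow(results)
    direction <- rep("none", n)
    direction[pd < alpha] <- "down"
    direction[pu < alpha] <- "up"
    lev <- tierLevels()
    tier_i <- rep(1L, n)  # "none"
    is_up <- direction == "up"
    tier_i[is_up] <- 2L   # "significant"
    for (j in seq_along(up)) {
        ok <- if (tier_rule == "shifted_test")
            results[[paste0("p_up_shift", j)]] < alpha else pu < alpha
        climb <- is_up & (tier_i == j + 1L) & ok & results$hl > up[j]
        tier_i[climb] <- j + 2L
    }
    is_down <- direction == "down"
    tier_i[is_down] <- 2L
    for (j in seq_along(down)) {
        ok <- if (tier_rule == "shifted_test")
            results[[paste0("p_down_shift", j)]] < alpha else pd < alpha
        climb <- is_down & (tier_i == j + 1L) & ok & results$hl < down[j]
        tier_i[climb] <- j + 2L
    }
    data.frame(site_id = results$site_id, direction = direction,
               tier = factor(lev[tier_i], levels = lev, ordered = TRUE),
               stringsAsFactors = FALSE)
}

#' Shifted one-sided tests at every tier cutoff
#'
#' For each site and each up cutoff c, the one-sided p-value for
#' "CASE exceeds REF by more than c" (and the mirrored test at each down
#' cutoff) is appended to the results as columns `p_up_shift1..k` /
#' `p_down_shift1..k`; the cutoffs used are attached as attribute
#' `"shift_cutoffs"`.
#'
#' @param x a [BetaSet].
#' @param results site results from [siteTests()] (row order must match the
#'   sites of `x` by `site_id`).
#' @param cutoffs a [TierCutoffs-class] object.
#' @param exact_n_max,family passed to [twoSampleShiftTest()].
#' @return `results` with the shifted-test columns added.
#' @export
computeShiftedTests <- function(x, results, cutoffs,
                                exact_n_max = .EXACT_N_MAX,
                                family = c("nonparametric", "t")) {
    family <- match.arg(family)
    b <- betaValues(x)[results$site_id, , drop = FALSE]
    refcols <- sampleRole(x) == "REF"
    up <- upCutoffs(cutoffs); down <- downCutoffs(cutoffs)
    for (j in seq_along(up)) {
        results[[paste0("p_up_shift", j)]] <- vapply(seq_len(nrow(b)),
            function(i) twoSampleShiftTest(b[i, !refcols], b[i, refcols],
                                           up[j], "greater", exact_n_max,
                                           family), 0)
    }
    for (j in seq_along(down)) {
        results[[paste0("p_down_shift", j)]] <- vapply(seq_len(nrow(b)),
            function(i) twoSampleShiftTest(b[i, !refcols], b[i, refcols],
                                           down[j], "less", exact_n_max,
                                           family), 0)
    }
    attr(results, "shift_cutoffs") <- list(up = up, down = down)
    results
}

#' Baseline-status vs change-direction cross-tabulations
#'
#' Emits (1) the 3x3 REF-status by CASE-status table, (2) the 3x3 REF-status
#' by change-direction table, and (3) the two dynamics classes:
#' *enhancement/diminution* (a REF-low site going further down, or a REF-high
#' site going further up) and *compensation* (a REF-low site coming up, or a
#' REF-high site coming down).
#'
#' @param results data.frame with `status_ref`, `status_case` and `direction`
#'   columns (see [siteTests()] and [classifySites()]).
#' @return List with `status` and `dynamics_table` matrices plus a `dynamics`
#'   named count vector.
#' @export
statusContingency <- function(results) {
    st <- factor(results$status_ref, levels = c("low", "medium", "high"))
    sc <- factor(results$status_case, levels = c("low", "medium", "high"))
    dr <- factor(results$direction, levels = c("down", "none", "up"))
    status <- table(REF = st, CASE = sc)
    dyn_tab <- table(REF = st, direction = dr)
    enhancement <- sum(st == "low" & dr == "down") +
        sum(st == "high" & dr == "up")
    compensation <- sum(st == "low" & dr == "up") +
        sum(st == "high" & dr == "down")
    list(status = unclass(status), dynamics_table = unclass(dyn_tab),
         dynamics = c(enhancement = enhancement,
                      compensation = compensation))
}

#' Serialize tier cutoffs to/from JSON
#'
#' Format: `{"up": [b1, b2, b3], "down": [...] | null, "provenance": [...]}`.
#'
#' @param cutoffs a [TierCutoffs-class] object.
#' @param path JSON file path.
#' @export
writeCutoffsJSON <- function(cutoffs, path) {
    obj <- list(up = upCutoffs(cutoffs),
                down = if (length(downCutoffs(cutoffs)))
                    downCutoffs(cutoffs) else NULL,
                provenance = cutoffs@provenance)
    jsonlite::write_json(obj, path, digits = NA, null = "null")
    invisible(path)
}

#' @rdname writeCutoffsJSON
#' @export
readCutoffsJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    prov <- if (!is.null(obj$provenance)) as.data.frame(obj$provenance)
            else data.frame()
    new("TierCutoffs", up = as.numeric(obj$up),
        down = as.numeric(if (is.null(obj$down)) numeric(0) else obj$down),
        provenance = prov)
}
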