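# Univariate Gaussian mixture fitting by EM with BIC model selection.
# The EM inner loop is compiled (src/em.cpp); this file holds initialization,
# restart logic, the BIC scan and (de)serialization.

.SIGMA_FLOOR <- 1e-4  # delta-beta units; narrower components are artifacts
.W_FLOOR <- 1e-4

#' Deterministic quantile initialization for EM
#'
#' Component means are placed at the `(k - 0.5)/K` sample quantiles, all
#' components share `sd(x)/K` as starting standard deviation (floored at
#' `1e-4`) and equal weights. The result is fully determined by the data and
#' `K`; `seed` only controls the jitter applied on EM restarts.
#'
#' @param x numeric sample.
#' @param K number of components (K <= length(x)).
#' @param seed integer kept in the returned attributes for reproducibility.
#' @return A [GaussianMixture1D] initial model.
#' @export
initializeComponents <- function(x, K, seed = 1L, tail_spread = 1) {
    x <- x[is.finite(x)]
    if (K > length(x)) stop("K exceeds the sample size")
    probs <- (seq_len(K) - 0.5) / K
    # tail_spread < 1 pushes the quantile levels toward 0/1 so that starting
    # means also cover low-mass tails (used by the multi-start strategy)
    if (tail_spread != 1) probs <- qbeta(probs, tail_spread, tail_spread)
    mu <- unname(quantile(x, probs = probs, type = 7))
    # strictly identical quantiles (heavily tied data) are nudged apart
    if (anyDuplicated(mu))
        mu <- mu + seq_len(K) * 1e-9 * max(diff(range(x)), 1)
    s <- max(sd(x) / K, .SIGMA_FLOOR)
    GaussianMixture1D(mu = mu, sigma = rep(s, K), w = rep(1 / K, K))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Standard E-step (responsibilities) / M-step (weighted mean, variance,
#' weight) iteration until the relative log-likelihood change drops below
#' `tol` or `max_iter` is reached. Component standard deviations are clamped
#' at `1e-4` (delta-beta units); if a component's weight collapses below
#' `1e-4` the fit restarts from a seed-jittered initialization, erroring after
#' `max_restarts` failures. The recorded log-likelihood trajectory is
#' non-decreasing (EM ascent).
#'
#' @param x numeric sample (e.g. genome-wide Hodges-Lehmann shifts).
#' @param K number of components.
#' @param init optional [GaussianMixture1D] starting model; defaults to
#'   [initializeComponents()].
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param max_restarts restarts allowed after component collapse.
#' @param seed integer driving the deterministic init and restart jitter.
#' @param strategy how to initialize when `init` is not given.
#'   `"greedy"` (default) builds the model incrementally: starting from the
#'   K = 1 moment fit, each stage splits an existing component (symmetric
#'   splits of the two largest-mass-times-variance components, plus
#'   directional tail seeds of the broadest one), scores the proposals by
#'   short EM runs and re-converges the winner. This reliably discovers
#'   low-weight broad tail components that single-start initializations
#'   absorb into the bulk. `"multistart"` runs short EM from the plain and
#'   tail-emphasized quantile initializations and converges the most likely
#'   one (the short-run "emEM" strategy).
#' @param short_iter iteration budget of each preliminary short run.
#' @return List with `model` (a mean-sorted [GaussianMixture1D]) and `report`
#'   (a `MixtureFitReport` with the BIC, log-likelihood trace, iteration count
#'   and convergence flag).
#' @export
emFit <- function(x, K, init = NULL, tol = 1e-8, max_iter = 1000L,
                  max_restarts = 5L, seed = 1L,
                  strategy = c("greedy", "multistart"), short_iter = 300L) {
    strategy <- match.arg(strategy)
    x <- x[is.finite(x)]
    if (length(x) <= 3L * K)
        stop("sample too small for K = ", K, " components")
    if (is.null(init)) {
        if (strategy == "greedy" && K > 1L) {
            ladder <- .greedyLadder(x, K, tol = tol, max_iter = max_iter,
                                    seed = seed, short_iter = short_iter)
            fit <- ladder[[K]]
            return(.fitResult(fit, K, length(x), seed))
        }
        init <- if (K == 1L) initializeComponents(x, 1L, seed)
                else .multistartInit(x, K, tol, short_iter, seed)
    }
    if (nComponents(init) != K) stop("init has wrong component count")
    cur <- init
    for (r in 0:max_restarts) {
        fit <- em_gauss1d_cpp(x, cur@mu, cur@sigma, cur@w,
                              tol, as.integer(max_iter),
                              .SIGMA_FLOOR, .W_FLOOR)
        if (!fit$collapsed)
            return(.fitResult(fit, K, length(x), seed, restarts = r))
        # jitter the quantile means, deterministic in (seed, restart)
        set.seed(seed * 1000L + r)
        base <- initializeComponents(x, K, seed)
        cur <- GaussianMixture1D(
            mu = base@mu + rnorm(K, 0, sd(x) / (2 * K)),
            sigma = base@sigma, w = base@w)
    }
    stop("EM failed for K = ", K, ": component weight collapsed in all ",
         max_restarts + 1L, " starts")
}

.fitResult <- function(fit, K, n, seed, restarts = 0L) {
    model <- GaussianMixture1D(fit$mu, fit$sigma, fit$w)
    b <- bic(fit$loglik, K, n)
    report <- new("MixtureFitReport", K = as.integer(K),
                  bic = setNames(b, as.character(K)),
                  logLik = fit$loglik, trace = fit$trace,
                  iterations = as.integer(fit$iterations),
                  converged = fit$converged,
                  restarts = as.integer(restarts), seed = as.integer(seed))
    list(model = model, report = report)
}

# short-run emEM over plain and tail-emphasized quantile initializations
.multistartInit <- function(x, K, tol, short_iter, seed) {
    spreads <- c(1, 0.5, 0.25, 2)
    starts <- lapply(spreads, function(a)
        initializeComponents(x, K, seed, tail_spread = a))
    short <- lapply(starts, function(s0)
        em_gauss1d_cpp(x, s0@mu, s0@sigma, s0@w, tol,
                       as.integer(short_iter), .SIGMA_FLOOR, .W_FLOOR))
    ok <- !vapply(short, `[[`, TRUE, "collapsed")
    if (!any(ok)) return(starts[[1L]])
    lls <- vapply(short, `[[`, 0, "loglik")
    lls[!ok] <- -Inf
    best <- short[[which.max(lls)]]
    GaussianMixture1D(best$mu, best$sigma, best$w)
}

# Incremental component splitting ("greedy EM"): fits all component counts
# 1..K_max; each stage's split proposals are scored by short EM runs on a
# subsample (deterministic given seed) and the winner is run to convergence
# on the full sample. Returns the list of converged per-K fits.
.greedyLadder <- function(x, K_max, tol = 1e-8, max_iter = 1000L, seed = 1L,
                          short_iter = 300L, subsample = 100000L) {
    n <- length(x)
    sub <- if (n > subsample) {
        set.seed(seed)
        x[sample.int(n, subsample)]
    } else x
    fits <- vector("list", K_max)
    fits[[1L]] <- em_gauss1d_cpp(x, mean(x), max(sd(x), .SIGMA_FLOOR), 1,
                                 tol, as.integer(max_iter), .SIGMA_FLOOR,
                                 .W_FLOOR)
    if (K_max == 1L) return(fits)
    for (k in 2:K_max) {
        f <- fits[[k - 1L]]
        mu <- f$mu; s <- f$sigma; w <- f$w
        heavy <- order(w * s^2, decreasing = TRUE)
        props <- list()
        for (j in heavy[seq_len(min(2L, k - 1L))])  # symmetric splits
            props[[length(props) + 1L]] <- list(
                mu = c(mu[-j], mu[j] - 0.7 * s[j], mu[j] + 0.7 * s[j]),
                s = c(s[-j], rep(s[j] * 0.7, 2)),
                w = c(w[-j], rep(w[j] / 2, 2)))
        j <- heavy[1L]                              # directional tail seeds
        for (dir in c(-1, 1))
            props[[length(props) + 1L]] <- list(
                mu = c(mu, mu[j] + dir * 2 * s[j]),
                s = c(s, s[j]), w = c(w * (1 - 0.1), 0.1 * 1))
        short <- lapply(props, function(p)
            em_gauss1d_cpp(sub, p$mu, p$s, p$w / sum(p$w), tol,
                           as.integer(short_iter), .SIGMA_FLOOR, .W_FLOOR))
        ok <- !vapply(short, `[[`, TRUE, "collapsed")
        if (!any(ok))
            stop("EM failed for K = ", k,
                 ": every split proposal collapsed")
        lls <- vapply(short, `[[`, 0, "loglik")
        lls[!ok] <- -Inf
        b <- short[[which.max(lls)]]
        fits[[k]] <- em_gauss1d_cpp(x, b$mu, b$sigma, b$w, tol,
                                    as.integer(max_iter), .SIGMA_FLOOR,
                                    .W_FLOOR)
    }
    fits
}

#' Bayesian information criterion
#'
#' `BIC = -2 ll + nu log(n)` with `nu = 3K - 1` free parameters (K means,
#' K standard deviations, K weights minus the simplex constraint). Lower is
#' better.
#'
#' @param ll maximized log-likelihood.
#' @param K number of mixture components.
#' @param n sample size.
#' @return BIC score.
#' @export
bic <- function(ll, K, n) {
    if (n <= 0) stop("n must be positive")
    -2 * ll + (3 * K - 1) * log(n)
}

#' Fit mixtures over a range of K and select by BIC
#'
#' Fits every K in `K_range` with [emFit()] and returns the model with the
#' smallest BIC, ties broken toward fewer components.
#'
#' @inheritParams emFit
#' @param K_range integer vector of component counts to scan.
#' @return List with `model`, `report` (the selected fit's report whose `bic`
#'   slot holds the full per-K scan) and `fits` (all per-K results).
#' @export
selectModel <- function(x, K_range = 1:10, tol = 1e-8, max_iter = 1000L,
                        max_restarts = 5L, seed = 1L,
                        strategy = c("greedy", "multistart")) {
    strategy <- match.arg(strategy)
    if (!length(K_range)) stop("K_range must be non-empty")
    K_range <- sort(unique(as.integer(K_range)))
    x <- x[is.finite(x)]
    fits <- list(); errs <- character()
    if (strategy == "greedy") {
        # one incremental ladder provides every K in the scan
        ladder <- tryCatch(
            .greedyLadder(x, max(K_range), tol = tol, max_iter = max_iter,
                          seed = seed),
            error = function(e) e)
        if (inherits(ladder, "error"))
            stop("all mixture fits failed: ", conditionMessage(ladder))
        for (K in K_range)
            if (length(x) > 3L * K)
                fits[[as.character(K)]] <- .fitResult(ladder[[K]], K,
                                                      length(x), seed)
    } else {
        for (K in K_range) {
            f <- tryCatch(emFit(x, K, tol = tol, max_iter = max_iter,
                                max_restarts = max_restarts, seed = seed,
                                strategy = "multistart"),
                          error = function(e) e)
            if (inherits(f, "error"))
                errs <- c(errs, sprintf("K=%d: %s", K, conditionMessage(f)))
            else fits[[as.character(K)]] <- f
        }
    }
    if (!length(fits))
        stop("all mixture fits failed:\n", paste(errs, collapse = "\n"))
    bics <- vapply(fits, function(f) unname(f$report@bic), 0)
    sel <- fits[[which.min(bics)]]  # which.min takes the first (smallest K)
    sel$report@bic <- bics
    list(model = sel$model, report = sel$report, fits = fits)
}

#' Mixture density and sampling
#'
#' @param m a [GaussianMixture1D].
#' @param x numeric vector of evaluation points.
#' @param log return the log density.
#' @return `mixtureDensity`: density values; `componentLogDensity`: matrix of
#'   per-component weighted log densities; `rmixture`: random sample.
#' @export
mixtureDensity <- function(m, x, log = FALSE) {
    ld <- componentLogDensity(m, x)
    mx <- apply(ld, 1L, max)
    out <- mx + base::log(rowSums(exp(ld - mx)))
    if (log) out else exp(out)
}

#' @rdname mixtureDensity
#' @export
componentLogDensity <- function(m, x) {
    K <- nComponents(m)
    ld <- vapply(seq_len(K),
                 function(k) base::log(m@w[k]) + dnorm(x, m@mu[k], m@sigma[k],
                                                       log = TRUE),
                 numeric(length(x)))
    matrix(ld, nrow = length(x), ncol = K)
}

#' @rdname mixtureDensity
#' @param n sample size to draw.
#' @export
rmixture <- function(m, n) {
    k <- sample.int(nComponents(m), n, replace = TRUE, prob = m@w)
    rnorm(n, m@mu[k], m@sigma[k])
}

#' Serialize a mixture model to/from JSON
#'
#' Format: `{"K": k, "components": [{"mean":, "sd":, "weight":}, ...]}`,
#' components sorted by mean.
#'
#' @param m a [GaussianMixture1D].
#' @param path JSON file path.
#' @export
writeMixtureJSON <- function(m, path) {
    obj <- list(K = nComponents(m),
                components = data.frame(mean = m@mu, sd = m@sigma,
                                        weight = m@w))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMixtureJSON
#' @export
readMixtureJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cm <- obj$components
    GaussianMixture1D(cm$mean, cm$sd, cm$weight)
}
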