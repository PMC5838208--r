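#' @import methods
#' @importFrom stats dnorm pnorm qnorm qbeta rnorm runif rbeta rbinom sd var
#'   median
#'   quantile chisq.test pchisq smooth.spline predict p.adjust pwilcox
#'   psignrank setNames ecdf t.test uniroot integrate
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @useDynLib methTier, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# BetaSet: a SummarizedExperiment holding one "beta" assay (CpG sites x
# samples, values in [0,1], NA allowed) and a two-level sample grouping.
# colData carries the original group labels plus a derived `role` factor with
# levels REF/CASE; all downstream shifts are CASE minus REF.
# ---------------------------------------------------------------------------

#' @rdname BetaSet
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- character()
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        bad <- which(!is.na(b) & (b < 0 | b > 1))
        if (length(bad))
            msg <- c(msg, sprintf("%d beta value(s) outside [0,1]",
                                  length(bad)))
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("group", "role") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'group' and 'role'")
    else {
        role <- cd$role
        if (!all(role %in% c("REF", "CASE")))
            msg <- c(msg, "role must be REF or CASE")
        if (sum(role == "REF") < 1 || sum(role == "CASE") < 1)
            msg <- c(msg, "both REF and CASE groups must be non-empty")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated site ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample ids")
    if (length(msg)) msg else TRUE
})

#' Container for a two-group beta-value matrix
#'
#' `BetaSet` wraps a [SummarizedExperiment::SummarizedExperiment] with a single
#' `"beta"` assay (CpG sites in rows, samples in columns, methylation fractions
#' in \[0,1\], missing values allowed) and a two-level sample grouping. The
#' reference level (healthy donors in a disease study) is stored as role
#' `"REF"`, the comparison group as `"CASE"`; every shift reported downstream
#' is CASE minus REF.
#'
#' @param beta numeric matrix of beta values with rownames (site ids) and
#'   colnames (sample ids).
#' @param groups named character vector or two-column data.frame mapping each
#'   sample id to its group label; exactly two distinct labels are required.
#' @param ref the group label to treat as the reference. Defaults to
#'   `"REF"`/`"HSC"`/`"control"` when one of those labels is present, otherwise
#'   it must be given explicitly.
#' @return A `BetaSet` object.
#' @examples
#' b <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:4)))
#' bs <- BetaSet(b, c(s1 = "HSC", s2 = "HSC", s3 = "AML", s4 = "AML"))
#' sampleRole(bs)
#' @export
BetaSet <- function(beta, groups, ref = NULL) {
    if (is.data.frame(groups)) {
        stopifnot(ncol(groups) >= 2)
        groups <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
    }
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("beta matrix must have site rownames and sample colnames")
    missing_grp <- setdiff(colnames(beta), names(groups))
    if (length(missing_grp))
        stop("sample(s) absent from the group map: ",
             paste(missing_grp, collapse = ", "))
    groups <- groups[colnames(beta)]
    lev <- unique(groups)
    if (length(lev) != 2L)
        stop("exactly two groups are required, got ", length(lev), ": ",
             paste(lev, collapse = ", "))
    if (is.null(ref)) {
        hit <- intersect(c("REF", "HSC", "control", "Control"), lev)
        if (!length(hit))
            stop("cannot infer the reference group from labels ",
                 paste(lev, collapse = "/"), "; supply `ref`")
        ref <- hit[1L]
    }
    if (!ref %in% lev) stop("ref level '", ref, "' not among group labels")
    bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("beta value out of [0,1] at site '%s', sample '%s'",
                     rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
    role <- factor(ifelse(groups == ref, "REF", "CASE"),
                   levels = c("REF", "CASE"))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta),
        colData = S4Vectors::DataFrame(group = unname(groups), role = role,
                                       row.names = colnames(beta)))
    new("BetaSet", se)
}

#' @describeIn BetaSet the beta-value matrix.
#' @param object,x a `BetaSet`.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn BetaSet factor of sample roles (REF/CASE).
#' @export
sampleRole <- function(x) SummarizedExperiment::colData(x)$role

#' @describeIn BetaSet sample ids of the reference group.
#' @export
refSamples <- function(x) colnames(x)[sampleRole(x) == "REF"]

#' @describeIn BetaSet sample ids of the case group.
#' @export
caseSamples <- function(x) colnames(x)[sampleRole(x) == "CASE"]

setMethod("show", "BetaSet", function(object) {
    cat(sprintf("BetaSet: %d CpG sites x %d samples (%d REF, %d CASE)\n",
                nrow(object), ncol(object),
                sum(sampleRole(object) == "REF"),
                sum(sampleRole(object) == "CASE")))
    callNextMethod()
})

# ---------------------------------------------------------------------------
# GaussianMixture1D
# ---------------------------------------------------------------------------

#' @rdname GaussianMixture1D
#' @export
setClass("GaussianMixture1D",
         representation(mu = "numeric", sigma = "numeric", w = "numeric"))

setValidity("GaussianMixture1D", function(object) {
    msg <- character()
    K <- length(object@mu)
    if (K < 1) msg <- c(msg, "at least one component required")
    if (length(object@sigma) != K || length(object@w) != K)
        msg <- c(msg, "mu, sigma and w must have equal length")
    if (any(object@sigma <= 0)) msg <- c(msg, "all sigma must be > 0")
    if (any(object@w <= 0)) msg <- c(msg, "all weights must be > 0")
    if (abs(sum(object@w) - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1 (tolerance 1e-9)")
    if (is.unsorted(object@mu)) msg <- c(msg, "components must be mean-sorted")
    if (length(msg)) msg else TRUE
})

#' Univariate Gaussian mixture
#'
#' Holds the parameters of a K-component univariate Gaussian mixture
#' \eqn{f(x) = \sum_k w_k \phi(x; \mu_k, \sigma_k)}. Components are always
#' stored sorted by mean; component identity elsewhere in the package refers to
#' this ordering.
#'
#' @param mu,sigma,w numeric vectors of equal length: component means,
#'   standard deviations (> 0) and mixing weights (> 0, summing to 1).
#' @return A `GaussianMixture1D` object.
#' @examples
#' m <- GaussianMixture1D(mu = c(0, 0.1), sigma = c(0.01, 0.02),
#'                        w = c(0.5, 0.5))
#' mixtureDensity(m, c(-0.01, 0, 0.05))
#' @export
GaussianMixture1D <- function(mu, sigma, w) {
    if (length(sigma) != length(mu) || length(w) != length(mu))
        stop("mu, sigma and w must have equal length")
    o <- order(mu)
    new("GaussianMixture1D", mu = as.numeric(mu[o]),
        sigma = as.numeric(sigma[o]), w = as.numeric(w[o]))
}

#' @describeIn GaussianMixture1D number of components.
#' @param x a `GaussianMixture1D`.
#' @export
nComponents <- function(x) length(x@mu)

#' @describeIn GaussianMixture1D component means (mean-sorted).
#' @export
mixtureMeans <- function(x) x@mu

#' @describeIn GaussianMixture1D component standard deviations.
#' @export
mixtureSigmas <- function(x) x@sigma

#' @describeIn GaussianMixture1D component weights.
#' @export
mixtureWeights <- function(x) x@w

setMethod("show", "GaussianMixture1D", function(object) {
    cat(sprintf("GaussianMixture1D with %d component(s):\n",
                nComponents(object)))
    print(data.frame(mean = object@mu, sd = object@sigma,
                     weight = object@w, row.names = NULL), digits = 4)
})

# ---------------------------------------------------------------------------
# MixtureFitReport
# ---------------------------------------------------------------------------

#' @rdname emFit
#' @export
setClass("MixtureFitReport",
         representation(K = "integer", bic = "numeric", logLik = "numeric",
                        trace = "numeric", iterations = "integer",
                        converged = "logical", restarts = "integer",
                        seed = "integer"))

setMethod("show", "MixtureFitReport", function(object) {
    cat(sprintf(
        "MixtureFitReport: K = %d, logLik = %.4f, BIC = %.4f\n",
        object@K, object@logLik, object@bic[as.character(object@K)]))
    cat(sprintf("  %d iteration(s), converged = %s, restarts = %d\n",
                object@iterations, object@converged, object@restarts))
    if (length(object@bic) > 1L) {
        cat("  BIC scan:\n")
        print(round(object@bic, 2))
    }
})

# ---------------------------------------------------------------------------
# TierCutoffs
# ---------------------------------------------------------------------------

#' @rdname deriveTierCutoffs
#' @export
setClass("TierCutoffs",
         representation(up = "numeric", down = "numeric",
                        provenance = "data.frame"))

setValidity("TierCutoffs", function(object) {
    msg <- character()
    if (length(object@up) < 3L)
        msg <- c(msg, "three up-methylation boundaries required")
    if (any(object@up <= 0)) msg <- c(msg, "up boundaries must be > 0")
    if (is.unsorted(object@up, strictly = TRUE))
        msg <- c(msg, "up boundaries must be strictly increasing")
    if (length(object@down)) {
        if (any(object@down >= 0)) msg <- c(msg, "down boundaries must be < 0")
        if (is.unsorted(rev(object@down), strictly = TRUE))
            msg <- c(msg, "down boundaries must decrease away from 0")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TierCutoffs", function(object) {
    cat("TierCutoffs (delta-beta units)\n")
    cat("  up  :", paste(sprintf("%.4f", object@up), collapse = " < "), "\n")
    if (length(object@down))
        cat("  down:", paste(sprintf("%.4f", object@down), collapse = " > "),
            "\n")
    else cat("  down: (absent)\n")
})

#' @describeIn deriveTierCutoffs positive (up-methylation) boundaries,
#'   ascending: medium, high, extreme-high.
#' @export
upCutoffs <- function(x) x@up

#' @describeIn deriveTierCutoffs negative (down-methylation) boundaries,
#'   descending from 0; may be empty.
#' @export
downCutoffs <- function(x) x@down

# Tier ladder used throughout: "none" < "significant" < "medium" < "high"
# < "extreme". Calls are "at least" sets, i.e. nested by construction.
tierLevels <- function() c("none", "significant", "medium", "high", "extreme")
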