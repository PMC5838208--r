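# End-to-end orchestration: site statistics -> mixture fit & cutoffs ->
# shifted tests, tier calls, dynamics -> gene/feature integration. The CLI in
# inst/scripts/methtier is a thin file-I/O wrapper around these functions.

#' Pipeline configuration
#'
#' @param alpha_one_sided significance level for one-sided tests (direction,
#'   status and tier calls).
#' @param alpha_two_sided significance level for two-sided summaries.
#' @param k_range component counts scanned by BIC model selection.
#' @param seed integer seed for every stochastic step.
#' @param tier_rule `"shifted_test"` (tier requires the shifted rank test at
#'   the cutoff to be significant) or `"hl_filter"` (shift-0 significance plus
#'   the HL point estimate only).
#' @param test_family `"nonparametric"` (rank tests, default) or `"t"`
#'   (Welch).
#' @param use_q gate direction calls on Storey q-values instead of raw
#'   one-sided p-values.
#' @param exact_n_max total-sample-size bound for exact rank-test enumeration.
#' @return A validated `PipelineConfig` (list).
#' @export
pipelineConfig <- function(alpha_one_sided = 0.025, alpha_two_sided = 0.05,
                           k_range = 1:10, seed = 1L,
                           tier_rule = c("shifted_test", "hl_filter"),
                           test_family = c("nonparametric", "t"),
                           use_q = FALSE, exact_n_max = 25L) {
    stopifnot(alpha_one_sided > 0, alpha_one_sided < 1,
              alpha_two_sided > 0, alpha_two_sided < 1,
              length(k_range) >= 1)
    structure(list(alpha_one_sided = alpha_one_sided,
                   alpha_two_sided = alpha_two_sided,
                   k_range = as.integer(k_range), seed = as.integer(seed),
                   tier_rule = match.arg(tier_rule),
                   test_family = match.arg(test_family),
                   use_q = use_q, exact_n_max = as.integer(exact_n_max)),
              class = "PipelineConfig")
}

#' Site-level analysis stage
#'
#' Runs the per-site test battery and, when an annotation is supplied,
#' summaries per region class (TSS / BODY / INTERGENIC): pooled Cohen's d
#' between CASE and REF beta values, skewness of the HL distribution, and the
#' Cramer's V of the REF-vs-CASE status table.
#'
#' @param x a [BetaSet].
#' @param anno optional site annotation ([readSiteAnnotation()]).
#' @param config a [pipelineConfig()].
#' @return List with `sites` (the [siteTests()] data.frame, plus a
#'   `region_classes` column when annotated) and `summary`.
#' @export
runSites <- function(x, anno = NULL, config = pipelineConfig()) {
    sites <- siteTests(x, alpha = config$alpha_one_sided,
                       include_status = TRUE,
                       exact_n_max = config$exact_n_max,
                       family = config$test_family)
    summary <- list(whole = .classSummary(x, sites, NULL))
    if (!is.null(anno)) {
        cls <- IRanges::CharacterList(
            anno$region_classes[match(sites$site_id, anno$site_id)])
        sites$region_classes <- vapply(cls, paste, "", collapse = ";")
        for (rc in c("TSS", "BODY", "INTERGENIC")) {
            ids <- sites$site_id[vapply(cls, function(z) rc %in% z, TRUE)]
            if (length(ids))
                summary[[rc]] <- .classSummary(x, sites, ids)
        }
    }
    list(sites = sites, summary = summary)
}

.classSummary <- function(x, sites, ids) {
    sel <- if (is.null(ids)) rep(TRUE, nrow(sites)) else
        sites$site_id %in% ids
    b <- betaValues(x)[sites$site_id[sel], , drop = FALSE]
    refcols <- sampleRole(x) == "REF"
    case_v <- as.numeric(b[, !refcols])[!is.na(as.numeric(b[, !refcols]))]
    ref_v <- as.numeric(b[, refcols])[!is.na(as.numeric(b[, refcols]))]
    st <- table(factor(sites$status_ref[sel], c("low", "medium", "high")),
                factor(sites$status_case[sel], c("low", "medium", "high")))
    V <- tryCatch(cramersV(st)$V, error = function(e) NA_real_)
    list(n_sites = sum(sel),
         cohens_d = cohensD(case_v, ref_v),
         hl_skewness = skewness(sites$hl[sel]),
         status_table = unclass(st),
         cramers_v = V)
}

#' Mixture-model stage
#'
#' Fits Gaussian mixtures to the genome-wide HL shift distribution by EM over
#' `config$k_range`, selects the component count by BIC and derives the MAP
#' tier cutoffs.
#'
#' @param sites site results from [runSites()] (or any data.frame with an
#'   `hl` column).
#' @param config a [pipelineConfig()].
#' @return List with `model`, `report` and `cutoffs`.
#' @export
runGmm <- function(sites, config = pipelineConfig()) {
    hl <- if (is.data.frame(sites)) sites$hl else as.numeric(sites)
    hl <- hl[is.finite(hl)]
    if (!length(hl)) stop("no finite HL values")
    sel <- selectModel(hl, K_range = config$k_range, seed = config$seed)
    cutoffs <- deriveTierCutoffs(sel$model)
    list(model = sel$model, report = sel$report, cutoffs = cutoffs)
}

#' Region-integration stage
#'
#' Computes the shifted tests at the tier cutoffs, calls site tiers and
#' dynamics classes, and integrates the one-sided site evidence to gene
#' TSS/Body regions and (optionally) interval features.
#'
#' @param x a [BetaSet].
#' @param sites site results from [runSites()].
#' @param cutoffs a [TierCutoffs-class] from [runGmm()].
#' @param anno site annotation.
#' @param features optional feature `GRanges` ([readIntervals()]) or a list
#'   of them.
#' @param config a [pipelineConfig()].
#' @return List with `sites` (tier calls appended), `genes`, `features`
#'   (NULL when none supplied) and `dynamics`.
#' @export
runRegions <- function(x, sites, cutoffs, anno, features = NULL,
                       config = pipelineConfig()) {
    sites <- computeShiftedTests(x, sites, cutoffs,
                                 exact_n_max = config$exact_n_max,
                                 family = config$test_family)
    calls <- classifySites(sites, cutoffs, alpha = config$alpha_one_sided,
                           use_q = config$use_q,
                           tier_rule = config$tier_rule)
    sites$direction <- calls$direction
    sites$tier <- calls$tier
    dynamics <- statusContingency(sites)
    genes <- integrateGeneRegions(sites, anno, cutoffs,
                                  alpha = config$alpha_one_sided)
    feat_res <- NULL
    if (!is.null(features)) {
        if (!is.list(features)) features <- list(features)
        feat_res <- do.call(rbind, lapply(features, function(f) {
            fmap <- mapSitesToFeatures(anno, f)
            integrateFeatures(sites, fmap, cutoffs,
                              alpha = config$alpha_one_sided)
        }))
    }
    list(sites = sites, genes = genes, features = feat_res,
         dynamics = dynamics)
}

#' Full pipeline
#'
#' [runSites()] + [runGmm()] + [runRegions()], with a structured log of every
#' parameter and seed.
#'
#' @inheritParams runRegions
#' @param anno site annotation ([readSiteAnnotation()]).
#' @return List with `sites`, `model`, `report`, `cutoffs`, `genes`,
#'   `features`, `dynamics`, `summary` and `log`.
#' @export
runAll <- function(x, anno, features = NULL, config = pipelineConfig()) {
    set.seed(config$seed)
    t0 <- Sys.time()
    s <- runSites(x, anno, config)
    g <- runGmm(s$sites, config)
    r <- runRegions(x, s$sites, g$cutoffs, anno, features, config)
    log <- list(config = unclass(config),
                n_sites = nrow(s$sites),
                n_ref = length(refSamples(x)), n_case = length(caseSamples(x)),
                selected_K = g$report@K,
                cutoffs_up = upCutoffs(g$cutoffs),
                cutoffs_down = downCutoffs(g$cutoffs),
                elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")))
    list(sites = r$sites, model = g$model, report = g$report,
         cutoffs = g$cutoffs, genes = r$genes, features = r$features,
         dynamics = r$dynamics, summary = s$summary, log = log)
}
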