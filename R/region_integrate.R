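# Stouffer integration of one-sided site p-values to genes (TSS / Body) and
# arbitrary interval features, with Storey correction per (kind, direction)
# and region-level tier calls.

#' Stouffer combination of one-sided p-values
#'
#' \eqn{z_i = \Phi^{-1}(1 - p_i)}, \eqn{Z = \sum z_i / \sqrt{k}},
#' \eqn{p = 1 - \Phi(Z)} (unweighted). p-values are clipped to
#' `[1e-15, 1 - 1e-15]` before the normal-quantile transform so a single
#' extreme site cannot produce an infinite z.
#'
#' @param p numeric vector of one-sided p-values (k >= 1).
#' @return List with `z` and `p`.
#' @examples
#' stoufferCombine(c(0.05, 0.05))  # Z = 1.6449 * sqrt(2)
#' @export
stoufferCombine <- function(p) {
    if (!length(p)) stop("empty p-value list")
    p <- pmin(pmax(p, .P_CLIP), 1 - .P_CLIP)
    z <- qnorm(p, lower.tail = FALSE)
    Z <- sum(z) / sqrt(length(z))
    list(z = Z, p = pnorm(Z, lower.tail = FALSE))
}

# Expand a site annotation into unique (site_id, feature_id, kind) membership
# rows, kind in gene-TSS / gene-Body. A site annotated to several genes (or
# to the same gene through both promoter and body groups) yields several rows.
.genePairs <- function(anno) {
    idx <- which(lengths(anno$gene_names) > 0L)
    if (!length(idx))
        return(data.frame(site_id = character(), feature_id = character(),
                          kind = character()))
    nper <- lengths(anno$gene_names[idx])
    site <- rep(anno$site_id[idx], nper)
    gene <- unlist(anno$gene_names[idx], use.names = FALSE)
    grp <- unlist(anno$gene_groups[idx], use.names = FALSE)
    kind <- ifelse(grp %in% .TSS_GROUPS, "gene-TSS",
                   ifelse(grp %in% .BODY_GROUPS, "gene-Body", NA))
    out <- data.frame(site_id = site, feature_id = gene, kind = kind,
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$kind), ]
    unique(out)
}

# Core combiner: `membership` has columns site_id, feature_id, kind.
.integrate <- function(results, membership, cutoffs = NULL, alpha = 0.025) {
    membership <- membership[membership$site_id %in% results$site_id, ]
    if (!nrow(membership))
        return(data.frame(feature_id = character(), kind = character(),
                          n_sites = integer(), z_up = numeric(),
                          p_up = numeric(), q_up = numeric(),
                          z_down = numeric(), p_down = numeric(),
                          q_down = numeric(), site_ids = I(list())))
    key <- paste(membership$kind, membership$feature_id, sep = "\r")
    sites_by_region <- split(membership$site_id, key)
    keys <- names(sites_by_region)
    kind <- sub("\r.*$", "", keys)
    fid <- sub("^[^\r]*\r", "", keys)
    ridx <- lapply(sites_by_region, function(s) match(s, results$site_id))
    comb <- function(col) {
        t(vapply(ridx, function(ii) {
            s <- stoufferCombine(results[[col]][ii])
            c(s$z, s$p)
        }, numeric(2)))
    }
    up <- comb("p_up"); dn <- comb("p_down")
    out <- data.frame(feature_id = fid, kind = kind,
                      n_sites = lengths(sites_by_region),
                      z_up = up[, 1], p_up = up[, 2], q_up = NA_real_,
                      z_down = dn[, 1], p_down = dn[, 2], q_down = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
    out$site_ids <- I(unname(sites_by_region))
    # Storey correction within each (region kind, direction) family
    for (k in unique(out$kind)) {
        sel <- out$kind == k
        out$q_up[sel] <- storeyQvalues(out$p_up[sel])$q
        out$q_down[sel] <- storeyQvalues(out$p_down[sel])$q
    }
    if (!is.null(cutoffs))
        out <- tierRegions(out, results, cutoffs, alpha)
    out
}

#' Integrate site evidence to gene TSS and Body regions
#'
#' Every (site, gene, RefGene-group) annotation pair assigns the site to that
#' gene's TSS or Body region; per (gene, region kind) the one-sided up and
#' down p-values of the member sites are combined separately with Stouffer's
#' method, and Storey q-values are computed across genes within each region
#' kind and direction. Genes with no annotated site are absent. A site
#' annotated to several overlapping genes contributes to each of them.
#'
#' @param results site results from [siteTests()] (optionally after
#'   [computeShiftedTests()]).
#' @param anno site annotation from [readSiteAnnotation()].
#' @param cutoffs optional [TierCutoffs-class]; when supplied (and `results`
#'   carries the shifted-test columns) region tiers are appended via
#'   [tierRegions()].
#' @param alpha one-sided significance level for tier calls.
#' @return `data.frame` with one row per (gene, kind): `feature_id`, `kind`
#'   (`gene-TSS`/`gene-Body`), `n_sites`, `z_up`, `p_up`, `q_up`, `z_down`,
#'   `p_down`, `q_down`, a `site_ids` list-column, and tier columns when
#'   `cutoffs` is given.
#' @export
integrateGeneRegions <- function(results, anno, cutoffs = NULL,
                                 alpha = 0.025) {
    .integrate(results, .genePairs(anno), cutoffs, alpha)
}

#' Integrate site evidence to interval features
#'
#' Same combination rule as [integrateGeneRegions()], applied to the
#' site-to-feature containment map of [mapSitesToFeatures()] (lincRNAs,
#' enhancers, transposable elements, custom BED features). Features
#' containing no site are excluded.
#'
#' @param results site results.
#' @param feature_map named list feature_id -> site ids, with a `"kind"`
#'   attribute ([mapSitesToFeatures()]).
#' @inheritParams integrateGeneRegions
#' @return As [integrateGeneRegions()], with `kind` from the feature map.
#' @export
integrateFeatures <- function(results, feature_map, cutoffs = NULL,
                              alpha = 0.025) {
    kinds <- attr(feature_map, "kind")
    if (is.null(kinds)) kinds <- rep("custom", length(feature_map))
    membership <- data.frame(
        site_id = as.character(unlist(feature_map, use.names = FALSE)),
        feature_id = rep(as.character(names(feature_map)),
                         lengths(feature_map)),
        kind = rep(as.character(kinds), lengths(feature_map)),
        stringsAsFactors = FALSE)
    .integrate(results, membership, cutoffs, alpha)
}

#' Tier regions from combined shifted-test evidence
#'
#' Per region and direction, the member sites' shifted-test p-values at each
#' cutoff are Stouffer-combined; the region's tier is the deepest cutoff whose
#' combined p-value is below `alpha`, with every shallower level also required
#' (tiers are "at least" sets and nest). The base "significant" level uses the
#' region's combined shift-0 p-value.
#'
#' @param regions region data.frame with `p_up`, `p_down` and a `site_ids`
#'   list-column (from the integrators).
#' @param results site results carrying the shifted-test columns from
#'   [computeShiftedTests()].
#' @param cutoffs a [TierCutoffs-class] object.
#' @param alpha one-sided significance level.
#' @return `regions` with ordered-factor columns `tier_up` and `tier_down`.
#' @export
tierRegions <- function(regions, results, cutoffs, alpha = 0.025) {
    up <- upCutoffs(cutoffs); down <- downCutoffs(cutoffs)
    upcols <- paste0("p_up_shift", seq_along(up))
    if (!all(upcols %in% names(results)))
        stop("site results lack shifted-test columns; run ",
             "computeShiftedTests() with these cutoffs first")
    lev <- tierLevels()
    ridx <- lapply(regions$site_ids, function(s) match(s, results$site_id))
    tier_dir <- function(base_p, cols) {
        vapply(seq_len(nrow(regions)), function(i) {
            t <- 1L
            if (base_p[i] < alpha) t <- 2L else return(lev[t])
            for (j in seq_along(cols)) {
                pj <- stoufferCombine(results[[cols[j]]][ridx[[i]]])$p
                if (pj < alpha) t <- j + 2L else break
            }
            lev[t]
        }, "")
    }
    regions$tier_up <- factor(tier_dir(regions$p_up, upcols),
                              levels = lev, ordered = TRUE)
    downcols <- paste0("p_down_shift", seq_along(down))
    if (length(down) && all(downcols %in% names(results)))
        regions$tier_down <- factor(tier_dir(regions$p_down, downcols),
                                    levels = lev, ordered = TRUE)
    else
        regions$tier_down <- factor(
            ifelse(regions$p_down < alpha, "significant", "none"),
            levels = lev, ordered = TRUE)
    regions
}

#' Write region results to TSV
#'
#' The `site_ids` list-column is collapsed with semicolons.
#'
#' @param regions region results data.frame.
#' @param path output path.
#' @export
writeRegionResults <- function(regions, path) {
    out <- regions
    if (!is.null(out$site_ids))
        out$site_ids <- vapply(out$site_ids, paste, "", collapse = ";")
    fwrite(as.data.table(out), path, sep = "\t", quote = FALSE)
    invisible(path)
}
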