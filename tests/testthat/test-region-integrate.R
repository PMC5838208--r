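test_that("Stouffer combination matches normal-quantile arithmetic", {
    expect_equal(stoufferCombine(0.123)$p, 0.123, tolerance = 1e-12)  # k = 1
    s <- stoufferCombine(c(0.05, 0.05))
    expect_equal(s$z, qnorm(0.95) * sqrt(2), tolerance = 1e-12)
    expect_equal(round(s$z, 4), 2.3262)
    expect_equal(round(s$p, 4), 0.0100)
    expect_equal(stoufferCombine(rep(0.5, 7))$z, 0)
    expect_equal(stoufferCombine(rep(0.5, 7))$p, 0.5)
    expect_error(stoufferCombine(numeric(0)), "empty")
    # clipping keeps extreme p-values finite
    expect_true(is.finite(stoufferCombine(c(0, 1))$z))
})

test_that("Stouffer evidence accumulates with k in the right direction", {
    p_low <- vapply(1:8, function(k) stoufferCombine(rep(0.1, k))$p, 0)
    expect_true(all(diff(p_low) < 0))   # strictly decreasing for p0 < 0.5
    p_high <- vapply(1:8, function(k) stoufferCombine(rep(0.8, k))$p, 0)
    expect_true(all(diff(p_high) > 0))  # increasing for p0 > 0.5
})

make_region_fixture <- function() {
    # 7 sites, 3 genes; cg5 is annotated to both B (Body) and C (TSS)
    anno <- S4Vectors::DataFrame(
        site_id = sprintf("cg%d", 1:7),
        chrom = "1", pos = as.integer(1:7 * 100),
        gene_names = IRanges::CharacterList(list(
            "A", "A", "B", "B", c("B", "C"), "C", character())),
        gene_groups = IRanges::CharacterList(list(
            "TSS200", "TSS1500", "Body", "1stExon", c("Body", "TSS200"),
            "5'UTR", character())),
        island_relation = "",
        region_classes = IRanges::CharacterList(list(
            "TSS", "TSS", "BODY", "BODY", c("BODY", "TSS"), "TSS",
            "INTERGENIC")),
        row.names = sprintf("cg%d", 1:7))
    results <- data.frame(
        site_id = sprintf("cg%d", 1:7),
        hl = c(0.05, 0.04, 0.01, 0.02, 0.06, 0.03, 0),
        p_up = c(0.01, 0.02, 0.3, 0.4, 0.005, 0.2, 0.5),
        p_down = c(0.99, 0.98, 0.7, 0.6, 0.995, 0.8, 0.5),
        stringsAsFactors = FALSE)
    list(anno = anno, results = results)
}

test_that("gene integration reproduces hand-computed Stouffer z-scores", {
    fx <- make_region_fixture()
    g <- integrateGeneRegions(fx$results, fx$anno)
    key <- paste(g$kind, g$feature_id)
    # gene A TSS: sites cg1, cg2
    zA <- (qnorm(1 - 0.01) + qnorm(1 - 0.02)) / sqrt(2)
    expect_equal(g$z_up[key == "gene-TSS A"], zA, tolerance = 1e-12)
    expect_equal(g$p_up[key == "gene-TSS A"], 1 - pnorm(zA),
                 tolerance = 1e-12)
    # gene B Body: cg3, cg4, cg5 (cg5 via its Body pairing)
    zB <- sum(qnorm(1 - c(0.3, 0.4, 0.005))) / sqrt(3)
    expect_equal(g$z_up[key == "gene-Body B"], zB, tolerance = 1e-12)
    # gene C TSS: cg5 (via its TSS pairing to C) and cg6
    zC <- sum(qnorm(1 - c(0.005, 0.2))) / sqrt(2)
    expect_equal(g$z_up[key == "gene-TSS C"], zC, tolerance = 1e-12)
    # the doubly annotated site contributed to both genes
    expect_true("cg5" %in% g$site_ids[key == "gene-Body B"][[1]])
    expect_true("cg5" %in% g$site_ids[key == "gene-TSS C"][[1]])
    # single-site region inherits the site p-value
    expect_equal(g$p_up[key == "gene-TSS A"] < 1, TRUE)
    # intergenic site cg7 appears nowhere
    expect_false(any(vapply(g$site_ids, function(s) "cg7" %in% s, TRUE)))
})

test_that("per-site membership counts are conserved", {
    fx <- make_region_fixture()
    g <- integrateGeneRegions(fx$results, fx$anno)
    # unique (site, gene, kind) pairs: cg1,cg2 -> A-TSS; cg3,cg4,cg5 -> B-Body;
    # cg5,cg6 -> C-TSS
    expect_equal(sum(g$n_sites), 7L)
    expect_setequal(g$feature_id, c("A", "B", "C"))
})

test_that("single-site genes reduce to the site test", {
    anno <- S4Vectors::DataFrame(
        site_id = "cg1", chrom = "1", pos = 100L,
        gene_names = IRanges::CharacterList(list("G")),
        gene_groups = IRanges::CharacterList(list("TSS200")),
        island_relation = "",
        region_classes = IRanges::CharacterList(list("TSS")),
        row.names = "cg1")
    res <- data.frame(site_id = "cg1", hl = 0.1, p_up = 0.0123,
                      p_down = 0.9877)
    g <- integrateGeneRegions(res, anno)
    expect_equal(g$p_up, 0.0123, tolerance = 1e-12)
})

test_that("feature integration equals gene integration on identical site sets", {
    fx <- make_region_fixture()
    fmap <- structure(list(featX = c("cg1", "cg2")), kind = "enhancer")
    f <- integrateFeatures(fx$results, fmap)
    g <- integrateGeneRegions(fx$results, fx$anno)
    zA <- g$z_up[g$feature_id == "A" & g$kind == "gene-TSS"]
    expect_equal(f$z_up, zA, tolerance = 1e-12)
    expect_identical(f$kind, "enhancer")
    # empty map yields an empty frame, not an error
    empty <- integrateFeatures(fx$results, structure(list(), kind = character()))
    expect_identical(nrow(empty), 0L)
})

test_that("region tiers combine shifted evidence and nest", {
    co <- deriveTierCutoffs(gse63409ShiftMixture())
    res <- data.frame(
        site_id = sprintf("cg%d", 1:6),
        hl = c(rep(0.12, 5), 0.0),
        p_up = c(rep(1e-4, 5), 0.5),
        p_down = c(rep(0.999, 5), 0.5),
        p_up_shift1 = c(rep(1e-4, 5), 0.5),
        p_up_shift2 = c(rep(1e-3, 5), 0.5),
        p_up_shift3 = c(rep(5e-3, 5), 0.5),
        p_down_shift1 = 0.9, p_down_shift2 = 0.9, p_down_shift3 = 0.9)
    regions <- data.frame(feature_id = c("all_extreme", "single"),
                          kind = "gene-TSS",
                          p_up = c(1e-6, 0.5), p_down = c(1, 0.5))
    regions$site_ids <- I(list(sprintf("cg%d", 1:5), "cg6"))
    tr <- tierRegions(regions, res, co)
    expect_identical(as.character(tr$tier_up), c("extreme", "none"))
    # mixing one strong and nine null sites: verify against direct formula
    res2 <- data.frame(
        site_id = sprintf("s%d", 1:10), hl = c(0.15, rep(0, 9)),
        p_up = c(1e-6, rep(0.5, 9)), p_down = 1,
        p_up_shift1 = c(1e-6, rep(0.5, 9)),
        p_up_shift2 = c(1e-5, rep(0.5, 9)),
        p_up_shift3 = c(1e-4, rep(0.5, 9)),
        p_down_shift1 = 0.9, p_down_shift2 = 0.9, p_down_shift3 = 0.9)
    regions2 <- data.frame(feature_id = "mixed", kind = "gene-TSS",
                           p_up = stoufferCombine(res2$p_up)$p, p_down = 1)
    regions2$site_ids <- I(list(res2$site_id))
    tr2 <- tierRegions(regions2, res2, co)
    expected <- "none"
    if (regions2$p_up < 0.025) {
        expected <- "significant"
        p1 <- 1 - pnorm(sum(qnorm(1 - res2$p_up_shift1)) / sqrt(10))
        if (p1 < 0.025) expected <- "medium"
        p2 <- 1 - pnorm(sum(qnorm(1 - res2$p_up_shift2)) / sqrt(10))
        if (expected == "medium" && p2 < 0.025) expected <- "high"
    }
    expect_identical(as.character(tr2$tier_up), expected)
})

test_that("planted up-shifted features are recovered end to end", {
    spec <- simulationSpec(n_sites = 400, n_ref = 5, n_case = 14,
                           effect_mixture = NULL, n_genes = 40,
                           sites_per_tss = 3, sites_per_body = 3,
                           planted_fraction = 0.1, planted_delta = 0.1,
                           overlap_fraction = 0, seed = 31)
    sim <- simulateDataset(spec)
    res <- siteTests(sim$beta, include_status = FALSE)
    g <- integrateGeneRegions(res, sim$annotation)
    tss <- g[g$kind == "gene-TSS", ]
    hit <- tss$feature_id[tss$q_up < 0.05]
    expect_gte(length(intersect(hit, sim$planted_genes)),
               0.75 * length(sim$planted_genes))
    fdp <- length(setdiff(hit, sim$planted_genes)) / max(1, length(hit))
    expect_lte(fdp, 0.15)
})

test_that("region results TSV writer collapses the site list", {
    fx <- make_region_fixture()
    g <- integrateGeneRegions(fx$results, fx$anno)
    f <- tempfile(fileext = ".tsv")
    writeRegionResults(g, f)
    back <- read.delim(f)
    expect_true(any(grepl(";", back$site_ids)))
    expect_equal(nrow(back), nrow(g))
})
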