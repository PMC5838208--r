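# Self-contained synthetic two-group methylation datasets with known ground
# truth. The generator emulates the shape of a 450K HSC-vs-AML comparison:
# a bimodal baseline (most sites near-unmethylated or near-fully methylated),
# per-site true shifts drawn from a genome-wide mixture, coherent planted
# shifts across the sites of selected genes, and beta-distributed per-sample
# noise that respects the [0,1] support.

#' Specification of a synthetic methylation dataset
#'
#' Defaults emulate the GSE63409 study shape: 5 reference vs 14 case samples
#' over 485,512 CpG sites, true shifts drawn from the published genome-wide
#' shift mixture ([gse63409ShiftMixture()]), 5% of genes carrying a coherent
#' planted up-shift of 0.1, a bimodal baseline with modes near 0.1 and 0.9,
#' and per-sample beta noise of concentration 100 (within-group sd of about
#' 0.03 at beta = 0.1).
#'
#' @param n_sites,n_ref,n_case dataset dimensions.
#' @param effect_mixture [GaussianMixture1D] of true per-site shifts for
#'   non-planted sites, or `NULL` for a global null (all true shifts 0).
#' @param baseline_modes,baseline_weights,baseline_conc parameters of the
#'   2-component beta mixture generating per-site baseline methylation.
#' @param noise_conc concentration of the per-sample beta noise (higher =
#'   less noise).
#' @param n_genes,sites_per_tss,sites_per_body synthetic gene structure;
#'   sites beyond `n_genes * (sites_per_tss + sites_per_body)` are
#'   intergenic.
#' @param overlap_fraction fraction of genic sites additionally annotated to
#'   the neighboring gene (gene overlap).
#' @param planted_fraction fraction of genes receiving a coherent regional
#'   shift.
#' @param planted_delta the planted shift (delta-beta).
#' @param seed integer seed; same seed, same dataset.
#' @return A validated `SimulationSpec` (list).
#' @export
simulationSpec <- function(n_sites = 485512L, n_ref = 5L, n_case = 14L,
                           effect_mixture = gse63409ShiftMixture(),
                           baseline_modes = c(0.1, 0.9),
                           baseline_weights = c(0.5, 0.5),
                           baseline_conc = 10,
                           noise_conc = 100,
                           n_genes = 200L, sites_per_tss = 2L,
                           sites_per_body = 2L,
                           overlap_fraction = 0.02,
                           planted_fraction = 0.05, planted_delta = 0.1,
                           seed = 1L) {
    spec <- list(n_sites = as.integer(n_sites), n_ref = as.integer(n_ref),
                 n_case = as.integer(n_case),
                 effect_mixture = effect_mixture,
                 baseline_modes = baseline_modes,
                 baseline_weights = baseline_weights / sum(baseline_weights),
                 baseline_conc = baseline_conc, noise_conc = noise_conc,
                 n_genes = as.integer(n_genes),
                 sites_per_tss = as.integer(sites_per_tss),
                 sites_per_body = as.integer(sites_per_body),
                 overlap_fraction = overlap_fraction,
                 planted_fraction = planted_fraction,
                 planted_delta = planted_delta, seed = as.integer(seed))
    with(spec, {
        stopifnot(n_sites > 0, n_ref > 0, n_case > 0, n_genes >= 0,
                  noise_conc > 0, baseline_conc > 0,
                  planted_fraction >= 0, planted_fraction <= 1,
                  overlap_fraction >= 0, overlap_fraction <= 1,
                  all(baseline_modes > 0), all(baseline_modes < 1))
    })
    n_genic <- spec$n_genes * (spec$sites_per_tss + spec$sites_per_body)
    if (n_genic > spec$n_sites)
        stop("gene structure requires ", n_genic, " sites but n_sites = ",
             spec$n_sites)
    structure(spec, class = "SimulationSpec")
}

# mean/concentration parameterization of the beta distribution
.rbetaMC <- function(n, mean, conc) rbeta(n, mean * conc, (1 - mean) * conc)

#' Simulate a two-group methylation dataset with known truth
#'
#' Per site a baseline methylation level is drawn from the bimodal baseline
#' mixture; a true shift delta comes from the planted gene effect (coherent
#' across all sites of a planted gene), from `effect_mixture` otherwise, or
#' is 0 under a null spec. REF samples are beta-distributed around the
#' baseline, CASE samples around `baseline + delta` (means clamped to
#' \[0.01, 0.99\]). Genes are laid out consecutively on autosomes with
#' promoter (TSS1500/TSS200/5'UTR) and body (1stExon/Body/3'UTR) sites;
#' enhancer-like intervals covering random site runs exercise the feature
#' machinery. The truth table records every site's true shift and its tier
#' under the published reference cutoffs.
#'
#' @param spec a [simulationSpec()].
#' @return List with `beta` ([BetaSet]), `annotation` (as
#'   [readSiteAnnotation()]), `features` (`GRanges`), `truth` (data.frame:
#'   `site_id`, `gene`, `region`, `delta`, `planted`, `true_tier`) and
#'   `planted_genes` (character).
#' @export
simulateDataset <- function(spec = simulationSpec()) {
    stopifnot(inherits(spec, "SimulationSpec"))
    set.seed(spec$seed)
    ns <- spec$n_sites
    site_id <- sprintf("cg%08d", seq_len(ns))

    # --- gene structure --------------------------------------------------
    spg <- spec$sites_per_tss + spec$sites_per_body
    n_genic <- spec$n_genes * spg
    gene_of <- rep(NA_character_, ns)
    group_of <- rep("", ns)
    if (spec$n_genes > 0L && spg > 0L) {
        genes <- sprintf("GENE%05d", seq_len(spec$n_genes))
        gene_of[seq_len(n_genic)] <- rep(genes, each = spg)
        tss_groups <- sample(.TSS_GROUPS, spec$n_genes * spec$sites_per_tss,
                             replace = TRUE)
        body_groups <- sample(.BODY_GROUPS, spec$n_genes * spec$sites_per_body,
                              replace = TRUE)
        group_of[seq_len(n_genic)] <- as.vector(t(cbind(
            matrix(tss_groups, spec$n_genes, spec$sites_per_tss),
            matrix(body_groups, spec$n_genes, spec$sites_per_body))))
    }
    n_chrom <- min(22L, max(1L, ceiling(ns / 50000)))
    per_chrom <- ceiling(ns / n_chrom)
    chrom <- as.character((seq_len(ns) - 1L) %/% per_chrom + 1L)
    pos <- as.integer(1000L + 100L * ((seq_len(ns) - 1L) %% per_chrom))

    gene_names <- lapply(seq_len(ns), function(i)
        if (is.na(gene_of[i])) character() else gene_of[i])
    gene_groups <- lapply(seq_len(ns), function(i)
        if (is.na(gene_of[i])) character() else group_of[i])
    # gene overlap: some genic sites also annotate to the next gene
    if (n_genic > 1L && spec$overlap_fraction > 0) {
        cand <- which(!is.na(gene_of[seq_len(n_genic)]))
        extra <- cand[runif(length(cand)) < spec$overlap_fraction]
        for (i in extra) {
            g2 <- sprintf("GENE%05d",
                          (match(gene_of[i], sprintf("GENE%05d",
                           seq_len(spec$n_genes))) %% spec$n_genes) + 1L)
            gene_names[[i]] <- c(gene_names[[i]], g2)
            gene_groups[[i]] <- c(gene_groups[[i]],
                                  sample(c(.TSS_GROUPS, .BODY_GROUPS), 1L))
        }
    }
    anno <- S4Vectors::DataFrame(
        site_id = site_id, chrom = chrom, pos = as.integer(pos),
        gene_names = IRanges::CharacterList(gene_names),
        gene_groups = IRanges::CharacterList(gene_groups),
        island_relation = sample(c("Island", "N_Shore", "S_Shore", "OpenSea"),
                                 ns, replace = TRUE),
        region_classes = IRanges::CharacterList(
            lapply(gene_groups, assignRegionClass)),
        row.names = site_id)

    # --- true shifts -----------------------------------------------------
    planted <- character()
    delta <- if (is.null(spec$effect_mixture)) numeric(ns) else
        rmixture(spec$effect_mixture, ns)
    is_planted_site <- rep(FALSE, ns)
    if (spec$n_genes > 0L && spec$planted_fraction > 0) {
        n_pl <- round(spec$planted_fraction * spec$n_genes)
        planted <- sort(sample(sprintf("GENE%05d", seq_len(spec$n_genes)),
                               n_pl))
        is_planted_site <- !is.na(gene_of) & gene_of %in% planted
        delta[is_planted_site] <- spec$planted_delta
    }

    # --- beta values -----------------------------------------------------
    mode_pick <- rbinom(ns, 1L, spec$baseline_weights[2L]) + 1L
    baseline <- .rbetaMC(ns, spec$baseline_modes[mode_pick],
                         spec$baseline_conc)
    m_ref <- pmin(pmax(baseline, 0.01), 0.99)
    m_case <- pmin(pmax(baseline + delta, 0.01), 0.99)
    nr <- spec$n_ref; nc <- spec$n_case
    b <- matrix(NA_real_, ns, nr + nc)
    for (j in seq_len(nr)) b[, j] <- .rbetaMC(ns, m_ref, spec$noise_conc)
    for (j in seq_len(nc)) b[, nr + j] <- .rbetaMC(ns, m_case,
                                                   spec$noise_conc)
    samples <- c(sprintf("REF%02d", seq_len(nr)),
                 sprintf("CASE%02d", seq_len(nc)))
    dimnames(b) <- list(site_id, samples)
    groups <- setNames(rep(c("REF", "CASE"), c(nr, nc)), samples)
    bs <- BetaSet(b, groups)

    # --- enhancer-like features ------------------------------------------
    n_feat <- max(1L, min(50L, ns %/% 20L))
    feat_chrom <- sample(unique(chrom), n_feat, replace = TRUE)
    feat_start <- vapply(feat_chrom, function(ch) {
        p <- pos[chrom == ch]
        sample(p, 1L)
    }, 0L)
    feats <- GenomicRanges::GRanges(
        feat_chrom,
        IRanges::IRanges(start = feat_start, width = 500L))
    S4Vectors::mcols(feats) <- S4Vectors::DataFrame(
        feature_id = sprintf("ENH%04d", seq_len(n_feat)),
        kind = "enhancer")

    # --- truth -----------------------------------------------------------
    refcut <- deriveTierCutoffs(gse63409ShiftMixture())
    true_tier <- .tierOfDelta(delta, refcut)
    region <- vapply(anno$region_classes, paste, "", collapse = ";")
    truth <- data.frame(site_id = site_id, gene = gene_of, region = region,
                        delta = delta, planted = is_planted_site,
                        true_tier = true_tier, stringsAsFactors = FALSE)
    list(beta = bs, annotation = anno, features = feats, truth = truth,
         planted_genes = planted, spec = spec)
}

# tier of a true shift under given cutoffs (point classification, no testing)
.tierOfDelta <- function(delta, cutoffs) {
    up <- upCutoffs(cutoffs); down <- downCutoffs(cutoffs)
    lev <- tierLevels()
    lab <- c("significant", "medium", "high", "extreme")
    out <- rep("none", length(delta))
    pos <- delta > 0
    if (any(pos)) {
        depth <- rowSums(outer(delta[pos], up, ">"))
        out[pos] <- lab[depth + 1L]
    }
    neg <- delta < 0
    if (any(neg)) {
        depth <- if (length(down))
            rowSums(outer(delta[neg], down, "<")) else 0L
        out[neg] <- lab[depth + 1L]
    }
    factor(out, levels = lev, ordered = TRUE)
}

#' Tiny deterministic worked-example dataset
#'
#' 30 CpG sites, 3 genes (2 promoter + 2 body sites each), 18 intergenic
#' sites, 5 REF vs 14 CASE samples. Gene GENE00001 carries a planted up-shift
#' of 0.15; everything else is null. Small enough to check every statistic by
#' hand and used throughout the documentation and unit tests.
#'
#' @return As [simulateDataset()].
#' @export
workedExampleFixture <- function() {
    spec <- simulationSpec(
        n_sites = 30L, n_ref = 5L, n_case = 14L,
        effect_mixture = NULL,
        n_genes = 3L, sites_per_tss = 2L, sites_per_body = 2L,
        overlap_fraction = 0, planted_fraction = 1 / 3, planted_delta = 0.15,
        noise_conc = 100, seed = 20260929L)
    sim <- simulateDataset(spec)
    sim
}

#' Write a simulated dataset bundle to a directory
#'
#' Writes `beta.tsv`, `groups.tsv`, `annotation.tsv`, `features.bed` and
#' `truth.tsv` in the package's interchange formats.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeDatasetBundle <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeBetaMatrix(sim$beta, file.path(dir, "beta.tsv"),
                    file.path(dir, "groups.tsv"))
    writeSiteAnnotation(sim$annotation, file.path(dir, "annotation.tsv"))
    writeIntervals(sim$features, file.path(dir, "features.bed"))
    fwrite(as.data.table(sim$truth), file.path(dir, "truth.tsv"), sep = "\t",
           quote = FALSE)
    invisible(dir)
}
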