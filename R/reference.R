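# Published summary statistics from the GSE63409 HSC-vs-AML 450K methylation
# study, usable as reference inputs without access to the raw data.

#' Published HSC/AML methylation-status contingency tables (GSE63409)
#'
#' Counts of CpG sites cross-classified as significantly low / medium / high
#' methylated in healthy hematopoietic stem cells (rows, REF) versus AML
#' blasts (columns, CASE), as published for the GSE63409 Infinium 450K cohort
#' (5 HSC vs 14 AML samples, 485,512 sites): the whole-genome table and the
#' TSS / gene-Body / intergenic region blocks.
#'
#' @return Named list of four 3x3 integer matrices (`whole`, `tss`, `body`,
#'   `intergenic`) with low/medium/high dimnames.
#' @seealso [cramersV()] for the association coefficient these tables feed.
#' @export
gse63409StatusTables <- function() {
    dn <- list(REF = c("low", "medium", "high"),
               CASE = c("low", "medium", "high"))
    mk <- function(v) matrix(v, 3, 3, byrow = TRUE, dimnames = dn)
    list(
        whole = mk(c(191043, 14739, 2985,
                     5668, 11286, 33931,
                     2297, 10093, 213470)),
        tss = mk(c(121393, 5693, 1059,
                   2101, 3578, 8643,
                   614, 2741, 43702)),
        body = mk(c(73494, 5874, 1300,
                    2417, 4639, 16438,
                    1087, 4661, 117122)),
        intergenic = mk(c(13548, 3295, 711,
                          1154, 3065, 9893,
                          559, 2722, 58573)))
}

#' Published Gaussian-mixture model of the HSC/AML shift distribution
#'
#' The 8-component univariate Gaussian mixture fitted to the genome-wide
#' distribution of per-CpG Hodges-Lehmann shifts (AML minus HSC) in the
#' GSE63409 cohort; parameters as published (4 decimals). Components are
#' returned mean-sorted. The three positive MAP boundaries of this model are
#' the published tier cutoffs 0.0096 / 0.0372 / 0.0819.
#'
#' @return A [GaussianMixture1D] with 8 components.
#' @examples
#' deriveTierCutoffs(gse63409ShiftMixture())
#' @export
gse63409ShiftMixture <- function() {
    GaussianMixture1D(
        mu    = c(0.0128, 0.0019, 0.0348, 0.0427, 0.1792,
                  -0.1248, -0.3006, 0.3818),
        sigma = c(0.0189, 0.0051, 0.0334, 0.0748, 0.1269,
                  0.1107, 0.1940, 0.1775),
        w     = c(0.2645, 0.2148, 0.2045, 0.1942, 0.0597,
                  0.0358, 0.0158, 0.0107))
}
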