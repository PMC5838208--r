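# Reading/writing the plain-text interchange formats and deriving genomic
# context. All tabular ingest goes through data.table::fread; BED through
# rtracklayer (standard 0-based half-open -> GRanges 1-based conversion).

#' @importFrom data.table fread fwrite data.table as.data.table setnames :=
NULL

# RefGene group vocabulary. Both the unicode prime (manifest dialect) and the
# ASCII apostrophe are accepted; the ASCII form is canonical internally.
.TSS_GROUPS  <- c("TSS1500", "TSS200", "5'UTR")
.BODY_GROUPS <- c("1stExon", "Body", "3'UTR")

.canonGroup <- function(g) {
    g <- gsub("′", "'", g)
    known <- c(.TSS_GROUPS, .BODY_GROUPS)
    bad <- setdiff(unique(g[nzchar(g)]), known)
    if (length(bad))
        stop("unknown RefGene group label(s): ", paste(bad, collapse = ", "))
    g
}

.stripChr <- function(x) sub("^chr", "", as.character(x))

#' Read a beta-value matrix and its sample group map
#'
#' The matrix file is TSV with a header row of sample ids and the site id in
#' the first column; empty cells become `NA`. The groups file is a two-column
#' TSV (`sample_id`, `group`) with exactly two distinct group labels.
#'
#' @param matrix_path path to the beta TSV.
#' @param groups_path path to the sample-to-group TSV.
#' @param ref reference group label, see [BetaSet()].
#' @return A [BetaSet].
#' @seealso [writeBetaMatrix()] for the inverse operation.
#' @export
readBetaMatrix <- function(matrix_path, groups_path, ref = NULL) {
    dt <- fread(matrix_path, sep = "\t", header = TRUE, na.strings = c("", "NA"))
    sites <- as.character(dt[[1L]])
    if (anyDuplicated(sites)) stop("duplicated site ids in ", matrix_path)
    m <- as.matrix(dt[, -1L, with = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- sites
    g <- fread(groups_path, sep = "\t", header = FALSE, col.names = c("sample_id", "group"),
               colClasses = "character")
    if (tolower(g$sample_id[1L]) == "sample_id") g <- g[-1L, ]
    BetaSet(m, setNames(g$group, g$sample_id), ref = ref)
}

#' Write a BetaSet to the TSV interchange format
#'
#' @param x a [BetaSet].
#' @param matrix_path,groups_path output paths; `NA` beta values are written
#'   as empty cells and the original group labels (not the REF/CASE roles) are
#'   written to the group map.
#' @return Invisibly, the matrix path.
#' @export
writeBetaMatrix <- function(x, matrix_path, groups_path) {
    b <- betaValues(x)
    dt <- data.table(site_id = rownames(b))
    dt <- cbind(dt, as.data.table(b))
    fwrite(dt, matrix_path, sep = "\t", na = "", quote = FALSE)
    fwrite(data.table(sample_id = colnames(x),
                      group = SummarizedExperiment::colData(x)$group),
           groups_path, sep = "\t", col.names = FALSE, quote = FALSE)
    invisible(matrix_path)
}

#' Map RefGene group labels to region classes
#'
#' Promoter-side labels (TSS1500, TSS200, 5'UTR) collapse into the TSS class
#' and 1stExon, Body, 3'UTR into the gene-Body class; a site carrying no gene
#' annotation is Intergenic. A site annotated to several overlapping genes can
#' belong to both TSS and BODY, but INTERGENIC never co-occurs with either.
#'
#' @param gene_groups character vector of RefGene group labels (possibly
#'   empty); both `5'UTR` and `5′UTR` spellings are accepted.
#' @return Character vector: a non-empty subset of `c("TSS", "BODY")`, or
#'   `"INTERGENIC"`.
#' @examples
#' assignRegionClass(c("TSS200", "Body"))
#' assignRegionClass(character())
#' @export
assignRegionClass <- function(gene_groups) {
    g <- .canonGroup(gene_groups)
    g <- g[nzchar(g)]
    if (!length(g)) return("INTERGENIC")
    out <- character()
    if (any(g %in% .TSS_GROUPS)) out <- c(out, "TSS")
    if (any(g %in% .BODY_GROUPS)) out <- c(out, "BODY")
    out
}

#' Read a per-site annotation table
#'
#' Accepts a CSV/TSV in the package's canonical column naming
#' (`site_id, chrom, pos, gene_names, gene_groups, island_relation`) or the
#' Illumina 450K manifest naming (`Name, CHR, MAPINFO, UCSC_RefGene_Name,
#' UCSC_RefGene_Group, Relation_to_UCSC_CpG_Island`). Multi-valued gene fields
#' are semicolon-delimited; positions are 1-based. Chromosome labels are
#' normalized by stripping an optional `chr` prefix.
#'
#' @param path annotation file path.
#' @return A [S4Vectors::DataFrame] with one row per site: `site_id`, `chrom`,
#'   `pos`, `gene_names` / `gene_groups` (CharacterList, aligned),
#'   `island_relation`, and the derived `region_classes` CharacterList.
#' @export
readSiteAnnotation <- function(path) {
    dt <- fread(path, header = TRUE, colClasses = "character", na.strings = NULL)
    alias <- c(Name = "site_id", IlmnID = "site_id", CHR = "chrom",
               MAPINFO = "pos", UCSC_RefGene_Name = "gene_names",
               UCSC_RefGene_Group = "gene_groups",
               Relation_to_UCSC_CpG_Island = "island_relation")
    hit <- intersect(names(alias), names(dt))
    if (length(hit)) setnames(dt, hit, alias[hit])
    need <- c("site_id", "chrom", "pos", "gene_names", "gene_groups")
    miss <- setdiff(need, names(dt))
    if (length(miss))
        stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
    if (!"island_relation" %in% names(dt)) dt$island_relation <- ""
    splitfield <- function(x) strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
    gn <- splitfield(dt$gene_names)
    gg <- lapply(splitfield(dt$gene_groups), .canonGroup)
    nlen <- lengths(gn); glen <- lengths(gg)
    bad <- which(nlen != glen & nlen > 0L & glen > 0L)
    if (length(bad))
        stop("gene_names/gene_groups length mismatch for site(s): ",
             paste(head(dt$site_id[bad], 5L), collapse = ", "))
    # a lone gene name with no group (or vice versa) cannot be paired
    bad <- which(xor(nlen == 0L, glen == 0L))
    if (length(bad))
        stop("gene_names/gene_groups length mismatch for site(s): ",
             paste(head(dt$site_id[bad], 5L), collapse = ", "))
    S4Vectors::DataFrame(
        site_id = dt$site_id,
        chrom = .stripChr(dt$chrom),
        pos = as.integer(dt$pos),
        gene_names = IRanges::CharacterList(gn),
        gene_groups = IRanges::CharacterList(gg),
        island_relation = dt$island_relation,
        region_classes = IRanges::CharacterList(lapply(gg, assignRegionClass)),
        row.names = dt$site_id)
}

#' @rdname readSiteAnnotation
#' @param anno annotation DataFrame as returned by `readSiteAnnotation`.
#' @param path output path (TSV).
#' @export
writeSiteAnnotation <- function(anno, path) {
    collapse <- function(x) vapply(x, paste, "", collapse = ";")
    fwrite(data.table(site_id = anno$site_id, chrom = anno$chrom,
                      pos = anno$pos,
                      gene_names = collapse(anno$gene_names),
                      gene_groups = collapse(anno$gene_groups),
                      island_relation = anno$island_relation),
           path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read a BED3+ interval file as a feature set
#'
#' BED intervals are 0-based half-open on disk and become standard 1-based
#' closed [GenomicRanges::GRanges] on ingest (the usual Bioconductor
#' conversion), so a site at 1-based position p falls in BED interval
#' \[start, end) exactly when it overlaps the imported range. The BED name
#' column provides feature ids when present; otherwise ids are synthesized
#' from `kind`. Overlapping intervals are kept as-is (no merging).
#'
#' @param path BED file path.
#' @param kind feature kind label, e.g. `"lincRNA"`, `"enhancer"`, `"TE"`.
#' @return A `GRanges` with metadata columns `feature_id` and `kind`.
#' @export
readIntervals <- function(path, kind = "custom") {
    raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
    if (ncol(raw) < 3L) stop("BED needs at least 3 columns: ", path)
    bad <- which(!(as.numeric(raw[[2L]]) < as.numeric(raw[[3L]])))
    if (length(bad))
        stop(sprintf("BED interval with start >= end at line %d of %s",
                     bad[1L], path))
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name) && all(nzchar(gr$name))) gr$name else
        sprintf("%s_%05d", kind, seq_along(gr))
    if (anyDuplicated(ids))
        stop("duplicated feature ids within kind '", kind, "'")
    GenomeInfoDb::seqlevels(gr) <- .stripChr(GenomeInfoDb::seqlevels(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(feature_id = ids, kind = kind)
    gr
}

#' @rdname readIntervals
#' @param feats a `GRanges` from `readIntervals`.
#' @export
writeIntervals <- function(feats, path) {
    out <- feats
    names(out) <- out$feature_id
    S4Vectors::mcols(out) <- NULL
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Assign CpG sites to interval features by containment
#'
#' A site at 1-based position p belongs to a BED interval \[start, end) iff
#' start <= p-1 < end, which is plain overlap after the standard BED-to-GRanges
#' conversion. Chromosome names are compared after stripping an optional `chr`
#' prefix; strand is ignored. Features containing no site are absent from the
#' result.
#'
#' @param anno site annotation ([readSiteAnnotation()]).
#' @param feats feature `GRanges` ([readIntervals()]).
#' @return Named list, `feature_id` -> character vector of site ids, with the
#'   feature kind attached as `attr(, "kind")`.
#' @export
mapSitesToFeatures <- function(anno, feats) {
    sites <- GenomicRanges::GRanges(
        .stripChr(anno$chrom),
        IRanges::IRanges(start = anno$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(sites, feats, ignore.strand = TRUE)
    out <- split(anno$site_id[S4Vectors::queryHits(hits)],
                 feats$feature_id[S4Vectors::subjectHits(hits)])
    out <- lapply(out, unique)
    kinds <- feats$kind[match(names(out), feats$feature_id)]
    attr(out, "kind") <- as.character(kinds)
    out
}
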