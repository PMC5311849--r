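#' @import methods
#' @import SummarizedExperiment
#' @import GenomicRanges
#' @importFrom S4Vectors DataFrame metadata isEmpty
#' @importFrom IRanges IRanges
NULL

.PHENO_TYPE_CODES <- c("0", "D", "C", "P", "B")

#' PhenotypeTable: individuals by phenotypes/covariates
#'
#' Holds the content of a SNPTEST v2 sample file: an ordered set of
#' individuals (row order is authoritative and indexes the genotype
#' probability columns of the paired GEN file), the column names, the
#' SNPTEST type codes (`0` identifier/metadata, `D` discrete covariate,
#' `C` continuous covariate, `P` continuous phenotype, `B` binary
#' phenotype) and the numeric values with `NA` as the missing marker.
#'
#' @slot data a [S4Vectors::DataFrame] with one row per individual;
#'   row names are the individual identifiers.
#' @slot colTypes character vector of SNPTEST type codes, one per column.
#' @aliases PhenotypeTable
#' @exportClass PhenotypeTable
setClass("PhenotypeTable",
    slots = c(data = "DataFrame", colTypes = "character"))

setValidity("PhenotypeTable", function(object) {
    msg <- NULL
    ids <- rownames(object@data)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "individual identifiers must be present and unique")
    if (length(object@colTypes) != ncol(object@data))
        msg <- c(msg, "colTypes length must equal the number of columns")
    bad <- setdiff(unique(object@colTypes), .PHENO_TYPE_CODES)
    if (length(bad))
        msg <- c(msg, paste0("invalid type code(s): ",
                             paste(bad, collapse = ", ")))
    for (j in which(object@colTypes == "B")) {
        v <- object@data[[j]]
        if (is.numeric(v) && !all(v %in% c(0, 1) | is.na(v)))
            msg <- c(msg, paste0("binary column '", colnames(object@data)[j],
                                 "' has values outside {0, 1, NA}"))
    }
    if (is.null(msg)) TRUE else msg
})

#' GenotypeProbs: genotype probability triplets as a SummarizedExperiment
#'
#' Variants are rows, individuals are columns.  The three assays `pAA`,
#' `pAB` and `pBB` carry the SNPTEST genotype probabilities; `rowRanges`
#' carries positions (1-based), and `rowData` the variant identifiers and
#' alleles.  A triplet whose probabilities sum to less than 0.1 encodes a
#' missing genotype (the GEN convention writes `0 0 0`).
#'
#' @aliases GenotypeProbs
#' @exportClass GenotypeProbs
setClass("GenotypeProbs", contains = "RangedSummarizedExperiment")

setValidity("GenotypeProbs", function(object) {
    msg <- NULL
    need <- c("pAA", "pAB", "pBB")
    if (!all(need %in% assayNames(object)))
        msg <- c(msg, "assays must include pAA, pAB and pBB")
    needCols <- c("snpID", "rsID", "alleleA", "alleleB")
    if (!all(needCols %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must carry snpID, rsID, alleleA, alleleB")
    if (all(need %in% assayNames(object)) && nrow(object) > 0) {
        for (a in need) {
            v <- assay(object, a)
            if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
                msg <- c(msg, paste0("assay ", a,
                                     " has probabilities outside [0, 1]"))
                break
            }
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' RegionBurden: the collapsed rare-variant burden of one region
#'
#' Per individual: the (possibly fractional) minor-allele count `r`, the
#' number `n` of rare variants successfully genotyped or imputed for that
#' individual, the proportion of minor alleles `z` (undefined where
#' `n == 0`), and the regression weight `w = n`.  Individuals with no
#' typed variant in the region are flagged `excluded` and take no part in
#' the regression.
#'
#' @slot region the [GenomicRanges::GRanges] interval that was collapsed.
#' @slot minorCount numeric, minor-allele count r per individual.
#' @slot typedCount integer, count n of successfully typed rare variants.
#' @slot proportion numeric, minor-allele proportion z (NA where n = 0).
#' @slot weights numeric, regression weight per individual (equal to n).
#' @slot excluded logical, TRUE where n = 0.
#' @slot sampleIDs character, individual identifiers (defines order).
#' @slot variantInfo a [S4Vectors::DataFrame] of the variants that were
#'   collapsed: rsID, position, MAF and which allele is minor.
#' @slot denominator `"alleles"` (z = r / 2n, proportion of allele copies)
#'   or `"variants"` (z = r / n, the literal count-over-variant ratio).
#' @aliases RegionBurden
#' @exportClass RegionBurden
setClass("RegionBurden",
    slots = c(region = "GRanges",
              minorCount = "numeric",
              typedCount = "integer",
              proportion = "numeric",
              weights = "numeric",
              excluded = "logical",
              sampleIDs = "character",
              variantInfo = "DataFrame",
              denominator = "character"))

setValidity("RegionBurden", function(object) {
    msg <- NULL
    n <- length(object@sampleIDs)
    lens <- c(length(object@minorCount), length(object@typedCount),
              length(object@proportion), length(object@weights),
              length(object@excluded))
    if (!all(lens == n))
        msg <- c(msg, "per-individual slots must have one entry per sample")
    if (any(object@minorCount < -1e-9))
        msg <- c(msg, "minor-allele counts must be non-negative")
    if (any(object@minorCount > 2 * object@typedCount + 1e-9))
        msg <- c(msg, "minor-allele count exceeds 2 * typed-variant count")
    ok <- !is.na(object@proportion)
    hi <- switch(object@denominator, alleles = 1, variants = 2, 1)
    if (any(object@proportion[ok] < -1e-9 | object@proportion[ok] > hi + 1e-9))
        msg <- c(msg, "proportion outside its admissible range")
    if (!object@denominator %in% c("alleles", "variants"))
        msg <- c(msg, "denominator must be 'alleles' or 'variants'")
    if (is.null(msg)) TRUE else msg
})
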