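#' Construct a GenotypeProbs object
#'
#' @param pAA,pAB,pBB numeric matrices (variants x individuals) of
#'   genotype probabilities for the homozygous-A, heterozygous and
#'   homozygous-B genotypes.
#' @param snpID,rsID character vectors of variant identifiers (GEN fields
#'   1 and 2; extract/exclude lists match on `rsID`).
#' @param position integer vector of 1-based base-pair positions.
#' @param alleleA,alleleB character vectors of alleles.
#' @param chromosome optional character vector; `"unknown"` when the GEN
#'   dialect does not carry one.
#' @param sampleIDs optional character vector of column (individual) ids.
#' @return a [GenotypeProbs-class] object.
#' @export
GenotypeProbs <- function(pAA, pAB, pBB, snpID, rsID, position,
                          alleleA, alleleB, chromosome = NULL,
                          sampleIDs = NULL) {
    pAA <- as.matrix(pAA); pAB <- as.matrix(pAB); pBB <- as.matrix(pBB)
    if (is.null(chromosome)) chromosome <- rep("unknown", nrow(pAA))
    gr <- GRanges(seqnames = chromosome,
                  ranges = IRanges(start = as.integer(position), width = 1L))
    mcols(gr) <- DataFrame(snpID = as.character(snpID),
                           rsID = as.character(rsID),
                           alleleA = as.character(alleleA),
                           alleleB = as.character(alleleB))
    cd <- DataFrame(row.names = sampleIDs %||% paste0("sample_",
                                                      seq_len(ncol(pAA))))
    dimnames(pAA) <- dimnames(pAB) <- dimnames(pBB) <- NULL
    se <- SummarizedExperiment(
        assays = list(pAA = pAA, pAB = pAB, pBB = pBB),
        rowRanges = gr, colData = cd)
    obj <- new("GenotypeProbs", se)
    validObject(obj)
    obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname GenotypeProbs-class
#' @export
setMethod("probAA", "GenotypeProbs", function(x) assay(x, "pAA"))

#' @rdname GenotypeProbs-class
#' @export
setMethod("probAB", "GenotypeProbs", function(x) assay(x, "pAB"))

#' @rdname GenotypeProbs-class
#' @export
setMethod("probBB", "GenotypeProbs", function(x) assay(x, "pBB"))

#' @rdname GenotypeProbs-class
#' @export
setMethod("rsID", "GenotypeProbs", function(x) rowData(x)$rsID)

#' @rdname GenotypeProbs-class
#' @export
setMethod("snpID", "GenotypeProbs", function(x) rowData(x)$snpID)

#' @rdname GenotypeProbs-class
#' @export
setMethod("sampleIDs", "GenotypeProbs", function(x) colnames(x))

setMethod("show", "GenotypeProbs", function(object) {
    callNextMethod()
    miss <- tripletSum(object) < 0.1
    cat("missing genotypes:", sum(miss), "of", length(miss), "\n")
})

#' Triplet probability sums (missingness indicator)
#'
#' @param x a [GenotypeProbs-class] object.
#' @return matrix of per-triplet probability sums; a sum below 0.1 marks
#'   a missing genotype.
#' @export
tripletSum <- function(x) probAA(x) + probAB(x) + probBB(x)
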