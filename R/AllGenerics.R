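#' @rdname PhenotypeTable-class
#' @param x,object a `PhenotypeTable`, `GenotypeProbs` or `RegionBurden`.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("colTypes", function(x) standardGeneric("colTypes"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("phenoValues", function(x, columns = NULL)
    standardGeneric("phenoValues"))

#' @rdname GenotypeProbs-class
#' @export
setGeneric("probAA", function(x) standardGeneric("probAA"))

#' @rdname GenotypeProbs-class
#' @export
setGeneric("probAB", function(x) standardGeneric("probAB"))

#' @rdname GenotypeProbs-class
#' @export
setGeneric("probBB", function(x) standardGeneric("probBB"))

#' @rdname GenotypeProbs-class
#' @export
setGeneric("rsID", function(x) standardGeneric("rsID"))

#' @rdname GenotypeProbs-class
#' @export
setGeneric("snpID", function(x) standardGeneric("snpID"))

#' @rdname RegionBurden-class
#' @export
setGeneric("minorCount", function(x) standardGeneric("minorCount"))

#' @rdname RegionBurden-class
#' @export
setGeneric("typedCount", function(x) standardGeneric("typedCount"))

#' @rdname RegionBurden-class
#' @export
setGeneric("burdenProportion", function(x) standardGeneric("burdenProportion"))

#' @rdname RegionBurden-class
#' @export
setGeneric("burdenWeights", function(x) standardGeneric("burdenWeights"))

#' @rdname RegionBurden-class
#' @export
setGeneric("excludedSamples", function(x) standardGeneric("excludedSamples"))

#' @rdname RegionBurden-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' Collapse rare variants into a per-individual burden
#'
#' @param x an object carrying genotype probability triplets.
#' @param ... passed to methods; see [buildBurden,GenotypeProbs-method].
#' @export
setGeneric("buildBurden", function(x, ...) standardGeneric("buildBurden"))
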