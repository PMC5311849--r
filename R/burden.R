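# Collapsing rare variants into the per-individual minor-allele burden.
#
# Probability triplets are renormalized to sum 1 before use: a sum below
# 0.1 is a missing genotype (the GEN `0 0 0` convention), sums up to 1.02
# tolerate imputation rounding and partial probability mass, and larger
# sums are rejected upstream as corrupt.

.renormProbs <- function(pAA, pAB, pBB) {
    s <- pAA + pAB + pBB
    if (any(s > 1.02))
        stopData("genotype probabilities sum to more than 1.02 ",
                 "(corrupt triplet)")
    missing <- s < 0.1
    s[missing] <- NA_real_
    list(pAA = pAA / s, pAB = pAB / s, pBB = pBB / s, missing = missing)
}

#' Sample frequency of allele B from probability triplets
#'
#' The expected allele-B dose of a non-missing triplet is
#' `pAB + 2 pBB`; the frequency is the mean dose over non-missing
#' individuals divided by 2.  Frequencies are computed from expected
#' dosages regardless of the burden method, once per variant, after
#' individual-level exclusions.
#'
#' @param x a [GenotypeProbs-class] object.
#' @param individuals optional logical/integer/character subset of
#'   individuals to include.
#' @return numeric vector, one frequency in `[0, 1]` per variant; `NA`
#'   where every included triplet is missing (such variants are dropped
#'   and logged, never counted in any individual's typed total).
#' @examples
#' g <- GenotypeProbs(pAA = rbind(c(1, 0)), pAB = rbind(c(0, 1)),
#'                    pBB = rbind(c(0, 0)), snpID = "s1", rsID = "rs1",
#'                    position = 100L, alleleA = "A", alleleB = "G")
#' alleleBFrequency(g)  # (0 + 1) / (2 * 2) = 0.25
#' @export
alleleBFrequency <- function(x, individuals = NULL) {
    pAA <- probAA(x); pAB <- probAB(x); pBB <- probBB(x)
    if (!is.null(individuals)) {
        pAA <- pAA[, individuals, drop = FALSE]
        pAB <- pAB[, individuals, drop = FALSE]
        pBB <- pBB[, individuals, drop = FALSE]
    }
    rn <- .renormProbs(pAA, pAB, pBB)
    dose <- rn$pAB + 2 * rn$pBB
    rowMeans(dose, na.rm = TRUE) / 2
}

#' Orient a variant to its minor allele
#'
#' @param freqB numeric vector of allele-B sample frequencies in
#'   `[0, 1]`.
#' @return a [S4Vectors::DataFrame] with columns `maf`
#'   (`min(freqB, 1 - freqB)`) and `minorIsB` (`freqB <= 0.5`; a tie at
#'   exactly 0.5 designates allele B minor, a deterministic convention).
#' @export
orientMinor <- function(freqB) {
    stopifnot(all(is.na(freqB) | (freqB >= -1e-9 & freqB <= 1 + 1e-9)))
    DataFrame(maf = pmin(freqB, 1 - freqB), minorIsB = freqB <= 0.5)
}

#' Rare-variant and QC filter predicate
#'
#' A variant passes iff its position lies within the region bounds
#' (1-based, inclusive), its MAF satisfies `0 < maf < rareThresh` (the
#' "< 5%" rule is strict, and monomorphic variants fail with their own
#' reason), its rs id is not excluded, and the extract list is empty or
#' contains its rs id.
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param position integer vector of positions.
#' @param region a length-1 [GenomicRanges::GRanges], or `NULL` to skip
#'   the bounds check.
#' @param rareThresh MAF cutoff (default 0.05).
#' @param rsID character vector of rs ids.
#' @param extract,exclude character vectors of rs ids (extract empty =
#'   keep all).
#' @return a [S4Vectors::DataFrame] with logical `pass` and character
#'   `reason` (`""` when passing).
#' @export
variantPassesFilters <- function(maf, position, region = NULL,
                                 rareThresh = 0.05, rsID = NULL,
                                 extract = character(0),
                                 exclude = character(0)) {
    n <- length(maf)
    reason <- character(n)
    if (!is.null(region)) {
        out <- position < GenomicRanges::start(region)[1] |
            position > GenomicRanges::end(region)[1]
        reason[out] <- "outside-region"
    }
    if (length(exclude) && !is.null(rsID))
        reason[reason == "" & rsID %in% exclude] <- "excluded"
    if (length(extract) && !is.null(rsID))
        reason[reason == "" & !(rsID %in% extract)] <- "not-extracted"
    reason[reason == "" & is.na(maf)] <- "all-missing"
    reason[reason == "" & !is.na(maf) & maf <= 0] <- "monomorphic"
    reason[reason == "" & !is.na(maf) & maf >= rareThresh] <- "not-rare"
    DataFrame(pass = reason == "", reason = reason)
}

#' Expected minor-allele dosage of a triplet
#'
#' @param pAA,pAB,pBB probabilities (scalars, vectors or matrices after
#'   renormalization); `NA` marks a missing genotype and propagates.
#' @param minorIsB logical (scalar or per-variant) from [orientMinor()].
#' @return `pAB + 2 pBB` where the minor allele is B, else
#'   `pAB + 2 pAA`; in `[0, 2]`.
#' @examples
#' expectedDosage(0.2, 0.5, 0.3, minorIsB = TRUE)  # 1.1
#' @export
expectedDosage <- function(pAA, pAB, pBB, minorIsB = TRUE) {
    hom <- if (is.matrix(pAA)) {
        out <- pAA
        out[minorIsB, ] <- pBB[minorIsB, , drop = FALSE]
        out
    } else ifelse(minorIsB, pBB, pAA)
    pAB + 2 * hom
}

#' Threshold genotype calling
#'
#' The genotype whose (renormalized) probability reaches `callThres` is
#' called and converted to its minor-allele count; when no probability
#' reaches the cutoff the genotype is considered missing.
#'
#' @param pAA,pAB,pBB probabilities (scalars, vectors or matrices).
#' @param callThres calling cutoff in (0, 1], default 0.9.
#' @param minorIsB logical (scalar or per-variant).
#' @return minor-allele counts in `{0, 1, 2}` with `NA` for no-calls,
#'   same shape as the input.
#' @examples
#' thresholdCall(0.5, 0.4, 0.1, callThres = 0.9)       # NA (no call)
#' thresholdCall(0.02, 0.02, 0.96, callThres = 0.95,
#'               minorIsB = FALSE)                     # 0: called BB
#' @export
thresholdCall <- function(pAA, pAB, pBB, callThres = 0.9, minorIsB = TRUE) {
    dm <- dim(pAA)
    best <- pmax(pAA, pAB, pBB)
    # genotype index 0/1/2 = AA/AB/BB, ties resolved toward the first
    geno <- ifelse(pAA == best, 0L, ifelse(pAB == best, 1L, 2L))
    geno[best < callThres | is.na(best)] <- NA_integer_
    cnt <- if (length(minorIsB) > 1L && !is.null(dm)) {
        out <- geno
        flip <- !minorIsB
        out[flip, ] <- 2L - geno[flip, , drop = FALSE]
        out
    } else if (isTRUE(all(minorIsB))) geno else
        ifelse(rep(minorIsB, length.out = length(geno)), geno, 2L - geno)
    if (!is.null(dm)) dim(cnt) <- dm
    cnt
}

#' @describeIn buildBurden Collapse the rare variants of a
#'   [GenotypeProbs-class] into a [RegionBurden-class].
#'
#' For each individual, `n` counts the variants with a non-missing
#' (method `"expected"`) or callable (method `"threshold"`) genotype,
#' `r` sums the minor-allele doses or counts over those variants,
#' `z = r / (2 n)` (or `r / n` with `denominator = "variants"`), and the
#' regression weight is `n`.  Individuals with `n = 0` are flagged
#' excluded.
#'
#' @param x a [GenotypeProbs-class] object.
#' @param region optional length-1 [GenomicRanges::GRanges]; when given,
#'   only variants inside it are considered and it is recorded in the
#'   result.
#' @param method `"expected"` (imputation dosages) or `"threshold"`
#'   (hard calls at `callThres`).
#' @param callThres calling cutoff for method `"threshold"`.
#' @param rareThresh MAF cutoff; variants with `maf >= rareThresh` or
#'   `maf == 0` are dropped.
#' @param extract,exclude rs-id lists forwarded to
#'   [variantPassesFilters()].
#' @param denominator `"alleles"` (z = r/2n, keeps z in `[0, 1]`) or
#'   `"variants"` (the literal r/n ratio; rescales intercept and slopes
#'   by 2 and leaves p-values, BIC differences and model ranking
#'   unchanged).
#' @param filter set `FALSE` when the variants were already filtered.
#' @return a [RegionBurden-class]; the variants used (with MAFs) are in
#'   [variantInfo()], and dropped variants with their reasons in
#'   `metadata(variantInfo(x))$dropped`.  A region with zero qualifying
#'   variants raises a skip condition carrying the reason.
#' @export
setMethod("buildBurden", "GenotypeProbs",
    function(x, region = NULL, method = c("expected", "threshold"),
             callThres = 0.9, rareThresh = 0.05,
             extract = character(0), exclude = character(0),
             denominator = c("alleles", "variants"), filter = TRUE) {
    method <- match.arg(method)
    denominator <- match.arg(denominator)
    pos <- GenomicRanges::start(x)
    bc <- .burdenCore(probAA(x), probAB(x), probBB(x), position = pos,
                      rsID = rsID(x), region = region, method = method,
                      callThres = callThres, rareThresh = rareThresh,
                      extract = extract, exclude = exclude,
                      denominator = denominator, filter = filter)
    keep <- bc$keep
    vi <- DataFrame(rsID = rsID(x)[keep], snpID = snpID(x)[keep],
                    position = pos[keep], maf = bc$maf,
                    minorAllele = ifelse(bc$minorIsB,
                                         rowData(x)$alleleB[keep],
                                         rowData(x)$alleleA[keep]))
    S4Vectors::metadata(vi)$dropped <- bc$dropped
    reg <- if (is.null(region))
        GRanges("unknown", IRanges(min(pos[keep]), max(pos[keep])))
    else region
    new("RegionBurden", region = reg, minorCount = as.numeric(bc$r),
        typedCount = bc$n, proportion = as.numeric(bc$z),
        weights = as.numeric(bc$n), excluded = bc$n == 0L,
        sampleIDs = colnames(x), variantInfo = vi,
        denominator = denominator)
})

# Matrix-level workhorse shared by the S4 method, the streaming driver
# and the simulation experiment drivers.
.burdenCore <- function(pAA, pAB, pBB, position, rsID = NULL, region = NULL,
                        method = "expected", callThres = 0.9,
                        rareThresh = 0.05, extract = character(0),
                        exclude = character(0), denominator = "alleles",
                        filter = TRUE) {
    keep <- seq_len(nrow(pAA))
    if (!is.null(region)) {
        inb <- position >= GenomicRanges::start(region)[1] &
            position <= GenomicRanges::end(region)[1]
        keep <- keep[inb]
    }
    rn <- .renormProbs(pAA[keep, , drop = FALSE], pAB[keep, , drop = FALSE],
                       pBB[keep, , drop = FALSE])
    dose <- rn$pAB + 2 * rn$pBB
    typed <- rowSums(!is.na(dose))
    freqB <- ifelse(typed > 0L, rowMeans(dose, na.rm = TRUE) / 2, NA_real_)
    ori <- orientMinor(freqB)
    dropped <- DataFrame(rsID = character(0), reason = character(0))
    if (filter) {
        flt <- variantPassesFilters(ori$maf, position[keep], region = NULL,
                                    rareThresh = rareThresh,
                                    rsID = rsID[keep], extract = extract,
                                    exclude = exclude)
        dropped <- DataFrame(rsID = if (is.null(rsID)) character(sum(!flt$pass))
                             else rsID[keep][!flt$pass],
                             reason = flt$reason[!flt$pass])
        sel <- which(flt$pass)
        keep <- keep[sel]
        ori <- ori[sel, , drop = FALSE]
        rn <- lapply(rn, function(m) m[sel, , drop = FALSE])
    }
    if (length(keep) == 0L)
        stop(errorCondition(
            paste0("no qualifying rare variants",
                   if (nrow(dropped)) paste0(" (",
                       paste(unique(dropped$reason), collapse = ", "), ")")),
            class = c("rvburden_region_skip", "rvburden_error")))
    d <- if (method == "expected")
        expectedDosage(rn$pAA, rn$pAB, rn$pBB, ori$minorIsB)
    else
        thresholdCall(rn$pAA, rn$pAB, rn$pBB, callThres, ori$minorIsB)
    d[rn$missing] <- NA_real_
    n <- as.integer(colSums(!is.na(d)))
    r <- colSums(d, na.rm = TRUE)
    div <- if (denominator == "alleles") 2 * n else n
    z <- ifelse(n > 0L, r / div, NA_real_)
    list(keep = keep, maf = ori$maf, minorIsB = ori$minorIsB,
         dropped = dropped, r = r, n = n, z = z)
}

#' @rdname RegionBurden-class
#' @export
setMethod("minorCount", "RegionBurden", function(x)
    structure(x@minorCount, names = x@sampleIDs))

#' @rdname RegionBurden-class
#' @export
setMethod("typedCount", "RegionBurden", function(x)
    structure(x@typedCount, names = x@sampleIDs))

#' @rdname RegionBurden-class
#' @export
setMethod("burdenProportion", "RegionBurden", function(x)
    structure(x@proportion, names = x@sampleIDs))

#' @rdname RegionBurden-class
#' @export
setMethod("burdenWeights", "RegionBurden", function(x)
    structure(x@weights, names = x@sampleIDs))

#' @rdname RegionBurden-class
#' @export
setMethod("excludedSamples", "RegionBurden", function(x)
    structure(x@excluded, names = x@sampleIDs))

#' @rdname RegionBurden-class
#' @export
setMethod("variantInfo", "RegionBurden", function(x) x@variantInfo)

#' @rdname RegionBurden-class
#' @export
setMethod("sampleIDs", "RegionBurden", function(x) x@sampleIDs)

#' @rdname RegionBurden-class
#' @export
setMethod("length", "RegionBurden", function(x) length(x@sampleIDs))

setMethod("show", "RegionBurden", function(object) {
    cat("RegionBurden over", nrow(object@variantInfo), "rare variants,",
        length(object@sampleIDs), "individuals\n")
    cat("  region:", names(object@region) %||% "", sprintf("[%d, %d]\n",
        GenomicRanges::start(object@region), GenomicRanges::end(object@region)))
    cat("  excluded (no typed variant):", sum(object@excluded), "\n")
    ok <- !is.na(object@proportion)
    if (any(ok))
        cat(sprintf("  proportion z: mean %.4g, range [%.4g, %.4g] (%s)\n",
                    mean(object@proportion[ok]), min(object@proportion[ok]),
                    max(object@proportion[ok]), object@denominator))
})
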