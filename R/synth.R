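# Seeded generator of GEN/sample/region study fixtures with known MAFs,
# missingness, call certainty, phenotype correlation and known
# phenotype -> burden effects.  The defaults describe the simulated
# study the test-suite analyses: 500 individuals, 20 rare variants with
# MAFs spread over 0.5-4%, 2% missing genotypes, 0.98 probability mass
# on the true genotype, and three phenotypes correlated like the
# metabolic-trait triple of a population cohort (pairwise 0.37, 0.18,
# 0.19).

.defaultCor <- function(K) {
    if (K == 3) {
        m <- diag(3)
        m[1, 2] <- m[2, 1] <- 0.37
        m[1, 3] <- m[3, 1] <- 0.18
        m[2, 3] <- m[3, 2] <- 0.19
        m
    } else {
        m <- matrix(0.2, K, K)
        diag(m) <- 1
        m
    }
}

#' Specify a synthetic study
#'
#' @param seed integer seed; the whole study triple is deterministic
#'   given it.  Phenotype draws use a fixed offset of the seed so that
#'   genotypes and phenotypes come from distinct streams.
#' @param nIndividuals number of individuals.
#' @param variantMAFs minor (allele B) frequencies in (0, 0.5], one per
#'   variant.
#' @param positions 1-based positions, one per variant.
#' @param missingRate fraction of triplets replaced by `0 0 0`.
#' @param certainty probability mass placed on the true genotype, in
#'   (1/3, 1]; the remainder is split evenly over the other two.
#' @param phenotypeCount K.
#' @param phenotypeCor K x K correlation matrix (symmetric positive
#'   definite).
#' @param effects length-K vector linking phenotypes to the burden
#'   proportion; all zero is the null (phenotypes independent of
#'   genotypes).
#' @param alpha burden-proportion intercept used in effect mode, in
#'   `[0, 0.45]` so allele B stays the minor allele.
#' @param residualSd residual scale of the burden model; individual i's
#'   noise is `residualSd / sqrt(n_i)`.
#' @return a validated `simSpec` list.
#' @export
simSpec <- function(seed = 1L, nIndividuals = 500L,
                    variantMAFs = seq(0.005, 0.04, length.out = 20),
                    positions = NULL, missingRate = 0.02,
                    certainty = 0.98, phenotypeCount = 3L,
                    phenotypeCor = NULL, effects = NULL,
                    alpha = mean(variantMAFs), residualSd = 0.05) {
    K <- as.integer(phenotypeCount)
    if (is.null(phenotypeCor)) phenotypeCor <- .defaultCor(K)
    if (is.null(effects)) effects <- rep(0, K)
    if (is.null(positions))
        positions <- as.integer(seq(1000L, by = 1000L,
                                    length.out = length(variantMAFs)))
    stopifnot(length(positions) == length(variantMAFs),
              all(variantMAFs > 0 & variantMAFs <= 0.5),
              missingRate >= 0, missingRate < 1,
              certainty > 1 / 3, certainty <= 1,
              K >= 1, length(effects) == K,
              nrow(phenotypeCor) == K, ncol(phenotypeCor) == K,
              isSymmetric(unname(phenotypeCor)),
              all(eigen(phenotypeCor, symmetric = TRUE,
                        only.values = TRUE)$values > 1e-10),
              alpha >= 0, alpha <= 0.45, residualSd > 0)
    structure(list(seed = as.integer(seed),
                   nIndividuals = as.integer(nIndividuals),
                   variantMAFs = variantMAFs, positions = positions,
                   missingRate = missingRate, certainty = certainty,
                   phenotypeCount = K, phenotypeCor = phenotypeCor,
                   effects = effects, alpha = alpha,
                   residualSd = residualSd),
              class = "simSpec")
}

.simCountMatrices <- function(spec) {
    stopifnot(inherits(spec, "simSpec"))
    set.seed(spec$seed)
    V <- length(spec$variantMAFs)
    N <- spec$nIndividuals
    counts <- matrix(stats::rbinom(V * N, 2L, rep(spec$variantMAFs, N)),
                     nrow = V, ncol = N)
    missing <- matrix(stats::runif(V * N) < spec$missingRate, V, N)
    list(counts = counts, missing = missing)
}

.phenoMatrix <- function(spec) {
    set.seed(spec$seed + .PHENO_SEED_OFFSET)
    N <- spec$nIndividuals
    K <- spec$phenotypeCount
    Y <- matrix(MASS::mvrnorm(N, mu = rep(0, K),
                              Sigma = spec$phenotypeCor), N, K)
    colnames(Y) <- paste0("pheno_", seq_len(K))
    rownames(Y) <- paste0("ind", seq_len(N))
    Y
}

.tripletsFromCounts <- function(counts, certainty, missing) {
    off <- (1 - certainty) / 2
    pAA <- matrix(off, nrow(counts), ncol(counts))
    pAB <- pAA; pBB <- pAA
    pAA[counts == 0L] <- certainty
    pAB[counts == 1L] <- certainty
    pBB[counts == 2L] <- certainty
    pAA[missing] <- 0; pAB[missing] <- 0; pBB[missing] <- 0
    list(pAA = pAA, pAB = pAB, pBB = pBB)
}

#' Simulate genotype probability triplets
#'
#' True genotypes are drawn binomially (2 trials at the variant's allele-B
#' frequency); each is emitted as a probability triplet with `certainty`
#' mass on the truth, and a `missingRate` fraction is replaced by the
#' missing triplet `0 0 0`.
#'
#' @param spec a [simSpec()].
#' @return a list with `geno` (a [GenotypeProbs-class]), `trueCounts`
#'   (variants x individuals matrix of true allele-B counts, `NA` where
#'   masked missing) and `spec`.
#' @export
simulateGenotypes <- function(spec) {
    cm <- .simCountMatrices(spec)
    counts <- cm$counts; missing <- cm$missing
    V <- length(spec$variantMAFs)
    N <- spec$nIndividuals
    tr <- .tripletsFromCounts(counts, spec$certainty, missing)
    geno <- GenotypeProbs(tr$pAA, tr$pAB, tr$pBB,
                          snpID = paste0("snp", seq_len(V)),
                          rsID = paste0("rs", seq_len(V)),
                          position = spec$positions,
                          alleleA = rep("A", V), alleleB = rep("G", V),
                          sampleIDs = paste0("ind", seq_len(N)))
    trueCounts <- counts
    trueCounts[missing] <- NA_integer_
    list(geno = geno, trueCounts = trueCounts, spec = spec)
}

.PHENO_SEED_OFFSET <- 1000003L

#' Simulate phenotypes (null or effect mode)
#'
#' Phenotypes are drawn multivariate normal with the spec's correlation.
#' In null mode (all effects zero, or no genotypes supplied) they are
#' independent of the genotypes.  In effect mode the burden is
#' regenerated from the phenotypes — the generative direction of the
#' reverse-regression model itself: `z_i = alpha + sum_k beta_k y_ik +
#' eps_i` with `eps_i ~ N(0, residualSd^2 / n_i)`, `z` projected back to
#' integer minor-allele counts `r_i = round(2 n_i z_i)` and those counts
#' re-distributed over the individual's typed variants (at most 2 copies
#' per variant).
#'
#' @param spec a [simSpec()].
#' @param genotypes result of [simulateGenotypes()] (required for effect
#'   mode).
#' @return a list with `pheno` (a [PhenotypeTable-class]), `Y` (the raw
#'   matrix), and in effect mode `genotypes` (the regenerated
#'   [GenotypeProbs-class]) and `truth` (alpha, effects, the latent and
#'   realized z, and the typed counts n).
#' @export
simulatePhenotypes <- function(spec, genotypes = NULL) {
    stopifnot(inherits(spec, "simSpec"))
    N <- spec$nIndividuals
    K <- spec$phenotypeCount
    Y <- .phenoMatrix(spec)
    df <- data.frame(ID_2 = rownames(Y), missing = rep(0, N), Y,
                     row.names = rownames(Y), check.names = FALSE)
    pt <- PhenotypeTable(df, colTypes = c("0", "0", rep("P", K)))
    if (is.null(genotypes) || all(spec$effects == 0))
        return(list(pheno = pt, Y = Y, genotypes = genotypes, truth = NULL))

    missing <- is.na(genotypes$trueCounts)
    n <- colSums(!missing)
    eps <- stats::rnorm(N, 0, spec$residualSd / sqrt(pmax(n, 1)))
    zLatent <- spec$alpha + as.vector(Y %*% spec$effects) + eps
    outside <- mean(zLatent < 0 | zLatent > 1)
    if (outside > 0.01)
        stop("effect sizes push the burden proportion outside [0, 1] for ",
             sprintf("%.1f%%", 100 * outside),
             " of individuals; use smaller effects, alpha or residualSd")
    zc <- pmin(pmax(zLatent, 0), 1)
    r <- round(zc * 2 * n)
    V <- nrow(genotypes$trueCounts)
    counts <- matrix(0L, V, N)
    for (i in seq_len(N)) {
        typed <- which(!missing[, i])
        if (!length(typed) || r[i] == 0) next
        slots <- rep(typed, each = 2L)
        hit <- sample(slots, r[i])
        counts[, i] <- tabulate(hit, nbins = V)
    }
    tr <- .tripletsFromCounts(counts, spec$certainty, missing)
    geno <- GenotypeProbs(tr$pAA, tr$pAB, tr$pBB,
                          snpID = snpID(genotypes$geno),
                          rsID = rsID(genotypes$geno),
                          position = spec$positions,
                          alleleA = rep("A", V), alleleB = rep("G", V),
                          sampleIDs = rownames(Y))
    trueCounts <- counts
    trueCounts[missing] <- NA_integer_
    list(pheno = pt, Y = Y,
         genotypes = list(geno = geno, trueCounts = trueCounts, spec = spec),
         truth = list(alpha = spec$alpha, effects = spec$effects,
                      zLatent = zLatent, zRealized = ifelse(n > 0,
                          r / (2 * n), NA_real_), n = n))
}

#' Null-calibration experiment for the full-model LRT
#'
#' Simulates independent single-region replicates under the null
#' (phenotypes independent of genotypes), runs the full pipeline on each
#' (collapse, weighted fit of the full phenotype model, LRT against the
#' intercept-only null) and returns the statistics, whose distribution
#' should approximate a chi-squared with K degrees of freedom.
#'
#' @param nReplicates number of replicate regions.
#' @param spec a [simSpec()] template; its seed is replaced per
#'   replicate by `baseSeed + replicate`.
#' @param baseSeed offset for the per-replicate seeds.
#' @return a data.frame with one row per replicate: `stat` (the LRT
#'   statistic) and `pValue`.
#' @export
nullCalibration <- function(nReplicates, spec = simSpec(),
                            baseSeed = 1L) {
    K <- spec$phenotypeCount
    phenos <- paste0("pheno_", seq_len(K))
    out <- matrix(NA_real_, nReplicates, 2L)
    for (i in seq_len(nReplicates)) {
        sp <- spec
        sp$seed <- as.integer(baseSeed + i)
        cm <- .simCountMatrices(sp)
        tr <- .tripletsFromCounts(cm$counts, sp$certainty, cm$missing)
        Y <- .phenoMatrix(sp)
        bc <- tryCatch(
            .burdenCore(tr$pAA, tr$pAB, tr$pBB, position = sp$positions),
            rvburden_region_skip = function(e) NULL)
        if (is.null(bc)) next
        mask <- bc$n > 0L
        z <- bc$z[mask]
        w <- bc$n[mask]
        alt <- fitWeightedLM(z, Y[mask, , drop = FALSE], w)
        null <- fitNullModel(z, w)
        if (alt$status != "ok" || null$status != "ok") next
        out[i, 1] <- max(2 * (alt$loglik - null$loglik), 0)
        out[i, 2] <- lrtPvalue(alt$loglik, null$loglik, df = K)
    }
    data.frame(stat = out[, 1], pValue = out[, 2])
}

#' Parameter-recovery experiment in effect mode
#'
#' Repeatedly generates studies whose burden proportion follows
#' `z = alpha + beta y + eps` exactly (effect mode, full certainty),
#' refits the model on the regenerated data and collects the estimates;
#' over replicates they should be unbiased for the spec's `alpha` and
#' `effects`.
#'
#' @inheritParams nullCalibration
#' @param spec a [simSpec()] template with non-zero `effects`.
#' @return a matrix of estimates, one row per replicate, columns
#'   `alpha` then one per phenotype effect.
#' @export
recoverySimulation <- function(nReplicates, spec, baseSeed = 1L) {
    stopifnot(any(spec$effects != 0))
    K <- spec$phenotypeCount
    phenos <- paste0("pheno_", seq_len(K))
    est <- matrix(NA_real_, nReplicates, K + 1L,
                  dimnames = list(NULL, c("alpha", phenos)))
    for (i in seq_len(nReplicates)) {
        sp <- spec
        sp$seed <- as.integer(baseSeed + i)
        sim <- simulateGenotypes(sp)
        ph <- simulatePhenotypes(sp, sim)
        b <- buildBurden(ph$genotypes$geno, rareThresh = 0.5)
        mask <- completeCases(ph$pheno, phenos, b)
        f <- fitWeightedLM(burdenProportion(b)[mask],
                           ph$Y[mask, , drop = FALSE],
                           burdenWeights(b)[mask])
        if (f$status != "ok") next
        est[i, ] <- c(f$alpha, f$betas)
    }
    est
}

#' Write a GenotypeProbs object as a SNPTEST v2 GEN file
#'
#' @param x a [GenotypeProbs-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGenFile <- function(x, path) {
    pAA <- probAA(x); pAB <- probAB(x); pBB <- probBB(x)
    V <- nrow(pAA); N <- ncol(pAA)
    probs <- matrix("", V, 3L * N)
    idx <- 3L * (seq_len(N) - 1L)
    fmt <- function(m) matrix(fmtNum(m), nrow = V)
    probs[, idx + 1L] <- fmt(pAA)
    probs[, idx + 2L] <- fmt(pAB)
    probs[, idx + 3L] <- fmt(pBB)
    lines <- paste(snpID(x), rsID(x), GenomicRanges::start(x),
                   rowData(x)$alleleA, rowData(x)$alleleB,
                   apply(probs, 1L, paste, collapse = " "))
    writeLines(lines, path)
    invisible(path)
}

#' Write a PhenotypeTable as a SNPTEST v2 sample file
#'
#' @param x a [PhenotypeTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSampleFile <- function(x, path) {
    tps <- colTypes(x)
    header <- c("ID_1", names(tps))
    lines <- c(paste(header, collapse = " "),
               paste(c("0", unname(tps)), collapse = " "))
    vals <- vapply(seq_along(tps), function(j) {
        v <- x@data[[j]]
        if (is.character(v)) ifelse(is.na(v), "NA", v) else fmtNum(v)
    }, character(length(x)))
    vals <- matrix(vals, nrow = length(x))
    lines <- c(lines, paste(sampleIDs(x), apply(vals, 1L, paste,
                                                collapse = " ")))
    writeLines(lines, path)
    invisible(path)
}

#' Generate a coherent GEN + sample + region study on disk
#'
#' @param spec a [simSpec()].
#' @param dir output directory (created if needed).
#' @param regionName name of the single region, which spans all
#'   simulated variants.
#' @return a list with the three `paths`, the in-memory `genotypes` and
#'   `phenotypes`, and `truth` (non-`NULL` in effect mode).
#' @export
makeStudy <- function(spec, dir = tempfile("rvstudy"), regionName = "GENE1") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sim <- simulateGenotypes(spec)
    ph <- simulatePhenotypes(spec, sim)
    if (!is.null(ph$truth)) sim <- ph$genotypes
    paths <- list(gen = file.path(dir, "study.gen"),
                  sample = file.path(dir, "study.sample"),
                  regions = file.path(dir, "study.regions"))
    writeGenFile(sim$geno, paths$gen)
    writeSampleFile(ph$pheno, paths$sample)
    writeLines(paste(regionName, min(spec$positions), max(spec$positions)),
               paths$regions)
    list(paths = paths, genotypes = sim, phenotypes = ph, truth = ph$truth)
}
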