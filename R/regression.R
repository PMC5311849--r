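# Weighted "reverse regression" of the burden proportion on phenotype
# combinations.  The model is z_i = alpha + beta y_i + eps_i with
# eps_i ~ N(0, sigma^2 / w_i), w_i the number of successfully typed rare
# variants, so the likelihood contribution of each individual is
# precision-weighted.  Significance is a likelihood ratio test of the
# fitted combination against the intercept-only null, approximately
# chi-squared with K degrees of freedom.

#' Enumerate all non-empty phenotype combinations
#'
#' @param phenotypeNames ordered character vector of the K analysed
#'   phenotypes.
#' @param cap largest K for which enumeration is permitted (2^K - 1
#'   models must stay tractable).
#' @return a list of exactly `2^K - 1` model specs, each a list with
#'   `phenotypes` (character subset, in user order) and `label`
#'   (`"+"`-joined names).  The full model comes first, then subsets by
#'   decreasing size, ties broken lexicographically by member indices.
#' @examples
#' vapply(enumerateModels(c("a", "b")), `[[`, "", "label")  # a+b, a, b
#' @export
enumerateModels <- function(phenotypeNames, cap = 16L) {
    K <- length(phenotypeNames)
    if (K == 0L)
        stopUsage("at least one phenotype must be specified")
    if (anyDuplicated(phenotypeNames))
        stopUsage("duplicated phenotype name: ",
                  phenotypeNames[duplicated(phenotypeNames)][1])
    if (K > cap)
        stopUsage(K, " phenotypes would require ", 2^K - 1, " models; ",
                  "raise the model cap (--model_cap) to allow more than ",
                  cap)
    specs <- list()
    for (size in seq(K, 1L)) {
        idx <- utils::combn(K, size, simplify = FALSE)
        for (ii in idx) {
            nm <- phenotypeNames[ii]
            specs[[length(specs) + 1L]] <-
                list(phenotypes = nm, label = paste(nm, collapse = "+"))
        }
    }
    specs
}

#' Shared complete-case mask for a region
#'
#' One shared sample across all sub-models: an individual is analysed
#' iff it has at least one typed rare variant (`n > 0`) and no missing
#' value in any analysed phenotype.  BIC comparisons between sub-models
#' are only meaningful on identical data, so the mask never varies with
#' the sub-model.
#'
#' @param phenotable a [PhenotypeTable-class].
#' @param phenotypeNames phenotypes to be analysed.
#' @param burden a [RegionBurden-class] over the same individuals, or
#'   `NULL` to apply the phenotype criterion alone.
#' @return logical mask over individuals.
#' @export
completeCases <- function(phenotable, phenotypeNames, burden = NULL) {
    Y <- phenoValues(phenotable, phenotypeNames)
    mask <- rowSums(is.na(Y)) == 0L
    if (!is.null(burden)) {
        stopifnot(length(burden) == nrow(Y))
        mask <- mask & !excludedSamples(burden)
    }
    unname(mask)
}

.wloglik <- function(w, sigma2, N) {
    0.5 * sum(log(w)) - (N / 2) * (log(2 * pi * sigma2) + 1)
}

.degenerate <- function(sigma2, z, w) {
    base <- sum(w * (z - stats::weighted.mean(z, w))^2) / length(z)
    sigma2 <= 1e-10 * max(base, .Machine$double.eps)
}

#' Weighted linear least-squares fit of the burden proportion
#'
#' Coefficients solve the weighted normal equations for a design with an
#' intercept column; the maximized weighted Gaussian log-likelihood uses
#' the MLE residual variance `sigma2 = sum(w e^2) / N` (so that
#' log-likelihood and BIC are coherent), while standard errors use the
#' unbiased variance `sum(w e^2) / (N - K - 1)`.
#'
#' @param z numeric outcome (burden proportion), length N.
#' @param Y numeric N x K phenotype matrix without missing entries (use
#'   `NULL` or zero columns for the intercept-only null).
#' @param w positive weights, length N.
#' @return a list with `status` (`"ok"`, `"singular"` for collinear
#'   phenotypes, `"degenerate"` for zero residual variance), `alpha`,
#'   `betas`, `ses` (per-phenotype), `seAlpha`, `sigma2`, `loglik`,
#'   `nUsed`.  Log-likelihood is `NA` for non-`"ok"` statuses except
#'   `"degenerate"`, where coefficients are still reported.
#' @examples
#' # perfect fit: alpha = 0, beta = 0.25, flagged degenerate variance
#' fitWeightedLM(c(0, 0.25, 0.25, 0.5), cbind(y = c(0, 1, 1, 2)),
#'               w = rep(1, 4))
#' @export
fitWeightedLM <- function(z, Y, w) {
    N <- length(z)
    stopifnot(length(w) == N, all(w > 0), !anyNA(z), !anyNA(w))
    if (is.null(Y)) Y <- matrix(numeric(0), nrow = N, ncol = 0)
    Y <- as.matrix(Y)
    stopifnot(nrow(Y) == N, !anyNA(Y))
    K <- ncol(Y)
    X <- cbind(`(Intercept)` = rep(1, N), Y)
    fit <- stats::lm.wfit(X, z, w)
    coefs <- fit$coefficients
    if (anyNA(coefs))
        return(list(status = "singular", alpha = NA_real_,
                    betas = rep(NA_real_, K), ses = rep(NA_real_, K),
                    seAlpha = NA_real_, sigma2 = NA_real_,
                    loglik = NA_real_, nUsed = N))
    e <- fit$residuals
    sigma2 <- sum(w * e^2) / N
    if (.degenerate(sigma2, z, w)) {
        return(list(status = "degenerate", alpha = unname(coefs[1]),
                    betas = unname(coefs[-1]), ses = rep(NA_real_, K),
                    seAlpha = NA_real_, sigma2 = sigma2,
                    loglik = NA_real_, nUsed = N))
    }
    s2 <- sum(w * e^2) / (N - K - 1L)
    XtWXinv <- chol2inv(chol(crossprod(X * sqrt(w))))
    ses <- sqrt(diag(XtWXinv) * s2)
    list(status = "ok", alpha = unname(coefs[1]), betas = unname(coefs[-1]),
         ses = unname(ses[-1]), seAlpha = unname(ses[1]), sigma2 = sigma2,
         loglik = .wloglik(w, sigma2, N), nUsed = N)
}

#' Intercept-only weighted null fit
#'
#' The null (`beta = 0`) companion of [fitWeightedLM()], fitted on the
#' same individuals and weights as the alternative; the intercept is the
#' weighted mean of `z`.
#'
#' @inheritParams fitWeightedLM
#' @return as [fitWeightedLM()] with zero-length `betas`.
#' @export
fitNullModel <- function(z, w) fitWeightedLM(z, NULL, w)

#' Likelihood ratio test p-value
#'
#' @param loglikAlt,loglikNull maximized log-likelihoods of the nested
#'   pair (same individuals and weights).
#' @param df degrees of freedom K (number of phenotypes tested).
#' @param tol negativity tolerance for the statistic; a statistic in
#'   `[-tol, 0)` is clamped to 0, anything lower is a nested-model
#'   violation and an error.
#' @return the upper-tail chi-squared probability, in `(0, 1]`.
#' @examples
#' lrtPvalue(0, 0, df = 1)                 # 1
#' lrtPvalue(3.841 / 2, 0, df = 1)         # ~0.05
#' @export
lrtPvalue <- function(loglikAlt, loglikNull, df, tol = 1e-8) {
    stopifnot(df >= 1)
    stat <- 2 * (loglikAlt - loglikNull)
    if (is.na(stat)) return(NA_real_)
    if (stat < -tol)
        stop("internal consistency error: alternative log-likelihood below ",
             "the null by ", format(-stat), " (nested-model violation)")
    stat <- max(stat, 0)
    stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Bayesian Information Criterion
#'
#' @param loglik maximized log-likelihood.
#' @param kParams number of free parameters; for a K-phenotype model this
#'   is `K + 2` (intercept, K slopes, residual variance).
#' @param nUsed number of individuals in the regression.
#' @return `kParams * log(nUsed) - 2 * loglik`.
#' @export
modelBIC <- function(loglik, kParams, nUsed) {
    stopifnot(nUsed >= 1)
    kParams * log(nUsed) - 2 * loglik
}

#' Bonferroni-corrected significance threshold
#'
#' A documentation helper: output p-values themselves are never adjusted
#' for multiple testing.
#'
#' @param alpha family-wise level in (0, 1).
#' @param nTests number of tests (e.g. 30,000 genes, or genes times
#'   phenotypes for univariate scans).
#' @return `alpha / nTests`.
#' @export
bonferroniThreshold <- function(alpha, nTests) {
    stopifnot(alpha > 0, alpha < 1, nTests >= 1)
    alpha / nTests
}

#' Fit every phenotype combination for one region
#'
#' Fits all `2^K - 1` models of [enumerateModels()] on the shared
#' complete-case sample, pairs each with the intercept-only null on the
#' same individuals and weights for the LRT, and computes BIC with
#' `K_model + 2` parameters.  The minimum-BIC model is flagged.
#'
#' @param burden a [RegionBurden-class].
#' @param phenotable a [PhenotypeTable-class] over the same individuals
#'   (same order).
#' @param phenotypeNames the K analysed phenotypes.
#' @param modelCap forwarded to [enumerateModels()].
#' @param denominatorNote unused hook for callers; ignored.
#' @return a list with `fits` (data.frame: one row per model with label,
#'   df, nUsed, loglik, bic, lrtStat, pValue, status), `betas`
#'   (data.frame: model, phenotype, beta, se for `"ok"`/`"degenerate"`
#'   fits), `bestModel` (minimum-BIC label or `NA`), `nUsed`, and
#'   `skipped` (`NULL`, or the reason when the region cannot be
#'   analysed, e.g. fewer than K + 3 complete cases).
#' @export
analyseRegion <- function(burden, phenotable, phenotypeNames,
                          modelCap = 16L, denominatorNote = NULL) {
    K <- length(phenotypeNames)
    specs <- enumerateModels(phenotypeNames, cap = modelCap)
    mask <- completeCases(phenotable, phenotypeNames, burden)
    nUsed <- sum(mask)
    if (nUsed < K + 3L)
        return(list(fits = NULL, betas = NULL, bestModel = NA_character_,
                    nUsed = nUsed,
                    skipped = paste0("insufficient sample (", nUsed,
                                     " complete cases, need at least ",
                                     K + 3L, ")")))
    z <- burdenProportion(burden)[mask]
    w <- burdenWeights(burden)[mask]
    Yall <- phenoValues(phenotable, phenotypeNames)[mask, , drop = FALSE]
    null <- fitNullModel(z, w)
    fits <- vector("list", length(specs))
    betas <- list()
    for (m in seq_along(specs)) {
        sp <- specs[[m]]
        Km <- length(sp$phenotypes)
        fit <- fitWeightedLM(z, Yall[, sp$phenotypes, drop = FALSE], w)
        status <- fit$status
        if (status == "ok" && null$status != "ok")
            status <- null$status  # constant z: no LRT is defined
        p <- if (status == "ok")
            lrtPvalue(fit$loglik, null$loglik, df = Km) else NA_real_
        lrt <- if (status == "ok") max(2 * (fit$loglik - null$loglik), 0)
        else NA_real_
        fits[[m]] <- data.frame(
            model = sp$label, df = Km, nUsed = nUsed,
            loglik = if (status == "ok") fit$loglik else NA_real_,
            bic = if (status == "ok")
                modelBIC(fit$loglik, Km + 2L, nUsed) else NA_real_,
            lrtStat = lrt, pValue = p, status = status,
            stringsAsFactors = FALSE)
        if (status %in% c("ok", "degenerate"))
            betas[[length(betas) + 1L]] <- data.frame(
                model = sp$label, phenotype = sp$phenotypes,
                beta = fit$betas, se = fit$ses, stringsAsFactors = FALSE)
    }
    fits <- do.call(rbind, fits)
    best <- if (any(!is.na(fits$bic)))
        fits$model[which.min(fits$bic)] else NA_character_
    list(fits = fits,
         betas = if (length(betas)) do.call(rbind, betas) else NULL,
         bestModel = best, nUsed = nUsed, skipped = NULL)
}
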