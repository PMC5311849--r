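test_that("model enumeration covers every non-empty combination in order", {
    labs <- vapply(enumerateModels(c("a", "b")), `[[`, "", "label")
    expect_identical(labs, c("a+b", "a", "b"))
    labs3 <- vapply(enumerateModels(c("a", "b", "c")), `[[`, "", "label")
    expect_identical(labs3, c("a+b+c", "a+b", "a+c", "b+c", "a", "b", "c"))
    for (K in 1:10)
        expect_length(enumerateModels(paste0("p", seq_len(K))), 2^K - 1)
    expect_error(enumerateModels(character(0)), class =
                 "rvburden_usage_error")
    expect_error(enumerateModels(paste0("p", 1:17)), "model cap")
})

test_that("the complete-case mask is shared across sub-models", {
    pt <- PhenotypeTable(
        data.frame(missing = c(0, 0, 0), a = c(1, 2, 3), b = c(1, NA, 2),
                   row.names = paste0("i", 1:3)),
        colTypes = c("0", "P", "P"))
    expect_identical(completeCases(pt, c("a", "b")), c(TRUE, FALSE, TRUE))
    # missing pheno_b excludes the individual from the a-only model too
    expect_identical(completeCases(pt, c("a", "b")),
                     completeCases(pt, c("b", "a")))
    g <- genoFromTriplets(list(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
                               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))))
    b <- buildBurden(g, filter = FALSE)
    expect_identical(completeCases(pt, "a", b), c(TRUE, TRUE, FALSE))
})

test_that("the weighted fit solves the normal equations", {
    # perfect fit: coefficients recovered, variance flagged degenerate
    f <- fitWeightedLM(c(0, 0.25, 0.25, 0.5), cbind(c(0, 1, 1, 2)),
                       rep(1, 4))
    expect_equal(f$status, "degenerate")
    expect_equal(f$alpha, 0)
    expect_equal(f$betas, 0.25)

    # frozen instance, computed with an explicit normal-equations oracle
    z <- c(0.1, 0.3, 0.2, 0.4, 0.25)
    y <- c(-1, 0.5, 0, 2, 1)
    w <- c(3, 1, 2, 5, 4)
    f2 <- fitWeightedLM(z, cbind(y), w)
    expect_equal(f2$alpha, 0.192495479204, tolerance = 1e-10)
    expect_equal(f2$betas, 0.0967450271248, tolerance = 1e-10)
    expect_equal(c(f2$seAlpha, f2$ses), c(0.0188400238085, 0.0139779609708),
                 tolerance = 1e-9)
    expect_equal(f2$loglik, 10.6420827457, tolerance = 1e-9)

    # constant weights reduce to ordinary least squares
    set.seed(1)
    zz <- runif(30); yy <- matrix(rnorm(60), 30, 2)
    fc <- fitWeightedLM(zz, yy, rep(2, 30))
    ols <- stats::lm(zz ~ yy)
    expect_equal(c(fc$alpha, fc$betas), unname(coef(ols)), tolerance = 1e-10)
    expect_equal(c(fc$seAlpha, fc$ses),
                 unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)

    # constant outcome: zero variance
    expect_equal(fitWeightedLM(rep(0.2, 10), cbind(rnorm(10)),
                               rep(1, 10))$status, "degenerate")
    # perfectly collinear phenotypes: singular
    x <- rnorm(10)
    expect_equal(fitWeightedLM(runif(10), cbind(x, 2 * x),
                               rep(1, 10))$status, "singular")
})

test_that("the fit matches the brute-force oracle on random instances", {
    set.seed(2024)
    for (rep in 1:40) {
        inst <- randomWLSInstance()
        f <- fitWeightedLM(inst$z, inst$Y, inst$w)
        o <- bruteWLS(inst$z, inst$Y, inst$w)
        expect_equal(c(f$alpha, f$betas), o$coef, tolerance = 1e-8)
        expect_equal(c(f$seAlpha, f$ses), o$ses, tolerance = 1e-8)
        expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
    }
})

test_that("the null fit is the weighted mean on the same sample", {
    expect_equal(fitNullModel(c(0, 1), c(1, 1))$alpha, 0.5)
    expect_equal(fitNullModel(c(0, 1), c(3, 1))$alpha, 0.25)
    expect_equal(fitNullModel(rep(0.3, 5), rep(2, 5))$status, "degenerate")
})

test_that("LRT p-values follow the chi-squared upper tail", {
    expect_equal(lrtPvalue(0, 0, df = 1), 1)
    expect_equal(lrtPvalue(3.841 / 2, 0, df = 1), 0.050013683764,
                 tolerance = 1e-9)
    # for a fixed statistic the tail grows with df
    expect_gt(lrtPvalue(2.5, 0, df = 4), lrtPvalue(2.5, 0, df = 1))
    # tiny negative statistics are clamped, real violations are errors
    expect_equal(lrtPvalue(-1e-10, 0, df = 1), 1)
    expect_error(lrtPvalue(-1, 0, df = 1), "nested-model violation")
})

test_that("BIC penalizes parameters by log sample size", {
    expect_equal(modelBIC(0, 3, 1), 0)
    expect_equal(modelBIC(-100, 3, 100), 213.815510558, tolerance = 1e-9)
    expect_equal(modelBIC(-5, 4, 50) - modelBIC(-5, 3, 50), log(50))
})

test_that("Bonferroni thresholds match genome-wide conventions", {
    expect_equal(signif(bonferroniThreshold(0.05, 30000), 3), 1.67e-6)
    expect_equal(signif(bonferroniThreshold(0.05, 90000), 3), 5.56e-7)
    expect_equal(bonferroniThreshold(0.05, 1), 0.05)
})

test_that("region analysis fits every combination on one shared sample", {
    spec <- simSpec(seed = 3, nIndividuals = 150, phenotypeCount = 2)
    sim <- simulateGenotypes(spec)
    ph <- simulatePhenotypes(spec)
    b <- buildBurden(sim$geno, rareThresh = 0.5)
    res <- analyseRegion(b, ph$pheno, c("pheno_1", "pheno_2"))
    expect_equal(nrow(res$fits), 3L)
    expect_identical(res$fits$model, c("pheno_1+pheno_2", "pheno_1",
                                       "pheno_2"))
    expect_true(all(res$fits$status == "ok"))
    expect_true(all(res$fits$nUsed == res$nUsed))
    expect_true(res$bestModel %in% res$fits$model)
    # nesting: the full model's loglik dominates its sub-models
    expect_true(all(res$fits$loglik[1] >= res$fits$loglik[-1] - 1e-8))
    # betas cover each model's members exactly
    expect_equal(nrow(res$betas), 2 + 1 + 1)

    # a duplicated phenotype makes the full model singular only
    pt2 <- PhenotypeTable(
        data.frame(a = ph$Y[, 1], b = ph$Y[, 1],
                   row.names = sampleIDs(ph$pheno)),
        colTypes = c("P", "P"))
    res2 <- analyseRegion(b, pt2, c("a", "b"))
    expect_identical(res2$fits$status, c("singular", "ok", "ok"))

    # too few complete cases: region is skipped with a reason
    tiny <- simSpec(seed = 4, nIndividuals = 4, phenotypeCount = 2)
    simT <- simulateGenotypes(tiny)
    phT <- simulatePhenotypes(tiny)
    bT <- buildBurden(simT$geno, rareThresh = 0.5)
    resT <- analyseRegion(bT, phT$pheno, c("pheno_1", "pheno_2"))
    expect_match(resT$skipped, "insufficient sample")
})

test_that("p-values are invariant to rescaling constant weights", {
    set.seed(12)
    z <- runif(40); Y <- matrix(rnorm(80), 40, 2)
    ps <- vapply(c(0.5, 1, 7), function(cst) {
        f <- fitWeightedLM(z, Y, rep(cst, 40))
        n <- fitNullModel(z, rep(cst, 40))
        lrtPvalue(f$loglik, n$loglik, df = 2)
    }, 0)
    expect_equal(ps[1], ps[2], tolerance = 1e-12)
    expect_equal(ps[2], ps[3], tolerance = 1e-12)
})

test_that("estimates are unbiased under the generative weighted model", {
    set.seed(77)
    alpha <- 0.2; beta <- 0.05
    R <- 400; N <- 120
    est <- matrix(NA_real_, R, 2)
    for (r in seq_len(R)) {
        w <- sample(10:30, N, replace = TRUE)
        y <- rnorm(N)
        z <- alpha + beta * y + rnorm(N, 0, 0.08 / sqrt(w))
        f <- fitWeightedLM(z, cbind(y), w)
        est[r, ] <- c(f$alpha, f$betas)
    }
    mc <- apply(est, 2, sd) / sqrt(R)
    expect_lt(abs(mean(est[, 1]) - alpha), 3 * mc[1])
    expect_lt(abs(mean(est[, 2]) - beta), 3 * mc[2])
})
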