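test_that("allele-B frequency is the mean expected dose over 2", {
    gAA <- genoFromTriplets(list(rbind(c(1, 0, 0), c(1, 0, 0))))
    expect_equal(alleleBFrequency(gAA), 0)
    gBB <- genoFromTriplets(list(rbind(c(0, 0, 1), c(0, 0, 1))))
    expect_equal(alleleBFrequency(gBB), 1)
    # one AA and one AB: (0 + 1) / (2 * 2)
    gMix <- genoFromTriplets(list(rbind(c(1, 0, 0), c(0, 1, 0))))
    expect_equal(alleleBFrequency(gMix), 0.25)
    # all triplets missing: undefined frequency
    gMiss <- genoFromTriplets(list(rbind(c(0, 0, 0), c(0, 0, 0))))
    expect_true(is.na(alleleBFrequency(gMiss)))
})

test_that("minor-allele orientation folds the frequency and breaks ties", {
    o <- orientMinor(c(0.02, 0.98, 0.5))
    expect_equal(o$maf, c(0.02, 0.02, 0.5))
    expect_identical(o$minorIsB, c(TRUE, FALSE, TRUE))
    # invariance under swapping allele labels (freq -> 1 - freq)
    f <- runif(100)
    expect_equal(orientMinor(f)$maf, orientMinor(1 - f)$maf)
})

test_that("rare-variant filters are strict and give reasons", {
    ok <- variantPassesFilters(0.03, 150L,
                               region = GenomicRanges::GRanges(
                                   "unknown", IRanges::IRanges(100, 200)))
    expect_true(ok$pass)
    # "< 5%" is strict at the default threshold
    expect_false(variantPassesFilters(0.05, 150L)$pass)
    expect_equal(variantPassesFilters(0.05, 150L)$reason, "not-rare")
    mono <- variantPassesFilters(0, 150L)
    expect_false(mono$pass)
    expect_equal(mono$reason, "monomorphic")
    out <- variantPassesFilters(0.03, 999L,
                                region = GenomicRanges::GRanges(
                                    "unknown", IRanges::IRanges(100, 200)))
    expect_equal(out$reason, "outside-region")
    expect_equal(variantPassesFilters(0.03, 150L, rsID = "rs9",
                                      exclude = "rs9")$reason, "excluded")
    expect_equal(variantPassesFilters(0.03, 150L, rsID = "rs9",
                                      extract = "rs1")$reason,
                 "not-extracted")
    expect_true(variantPassesFilters(0.03, 150L, rsID = "rs9",
                                     extract = c("rs9", "rs1"))$pass)
})

test_that("expected dosage and threshold calling match hand values", {
    expect_equal(expectedDosage(1, 0, 0, minorIsB = TRUE), 0)
    expect_equal(expectedDosage(0, 0, 1, minorIsB = TRUE), 2)
    expect_equal(expectedDosage(0.2, 0.5, 0.3, minorIsB = TRUE), 1.1)
    expect_equal(expectedDosage(0.2, 0.5, 0.3, minorIsB = FALSE), 0.9)

    expect_equal(thresholdCall(0.96, 0.02, 0.02, 0.9, minorIsB = TRUE), 0L)
    expect_true(is.na(thresholdCall(0.5, 0.4, 0.1, 0.9)))
    # called BB, zero copies of the minor allele A
    expect_equal(thresholdCall(0.02, 0.02, 0.96, 0.95, minorIsB = FALSE), 0L)
    expect_equal(thresholdCall(0.02, 0.96, 0.02, 0.9, minorIsB = FALSE), 1L)
})

test_that("burden collapse counts minor alleles over typed variants", {
    # 1 individual, 2 variants: hard calls 1 and 0 minor alleles
    g <- genoFromTriplets(list(rbind(c(0, 1, 0)), rbind(c(1, 0, 0))))
    b <- buildBurden(g, filter = FALSE)
    expect_equal(unname(minorCount(b)), 1)
    expect_equal(unname(typedCount(b)), 2L)
    expect_equal(unname(burdenProportion(b)), 1 / (2 * 2))
    expect_equal(unname(burdenWeights(b)), 2)
    # the literal count-over-variant convention doubles the proportion
    b2 <- buildBurden(g, filter = FALSE, denominator = "variants")
    expect_equal(unname(burdenProportion(b2)), 0.5)

    # an individual missing at every variant is excluded with n = 0
    gm <- genoFromTriplets(list(rbind(c(0, 1, 0), c(0, 0, 0)),
                                rbind(c(1, 0, 0), c(0, 0, 0))))
    bm <- buildBurden(gm, filter = FALSE)
    expect_equal(unname(typedCount(bm)), c(2L, 0L))
    expect_identical(unname(excludedSamples(bm)), c(FALSE, TRUE))
    expect_true(is.na(burdenProportion(bm)[2]))

    # everyone homozygous non-minor everywhere: z is identically zero
    gz <- genoFromTriplets(list(rbind(c(1, 0, 0), c(1, 0, 0))))
    expect_equal(unname(burdenProportion(buildBurden(gz, filter = FALSE))),
                 c(0, 0))

    # zero qualifying variants raises a skip condition
    expect_error(buildBurden(gz), class = "rvburden_region_skip")
})

test_that("burden respects the region bounds and MAF filter", {
    set.seed(5)
    spec <- simSpec(seed = 5, nIndividuals = 120, phenotypeCount = 1,
                    variantMAFs = c(0.01, 0.02, 0.3), missingRate = 0)
    g <- simulateGenotypes(spec)$geno
    b <- buildBurden(g)  # default rareThresh 0.05 drops the common variant
    expect_equal(nrow(variantInfo(b)), 2L)
    expect_true(all(variantInfo(b)$maf < 0.05))
    dropped <- S4Vectors::metadata(variantInfo(b))$dropped
    expect_true("rs3" %in% dropped$rsID)
    reg <- GenomicRanges::GRanges("unknown", IRanges::IRanges(1000, 1000))
    b1 <- buildBurden(g, region = reg)
    expect_equal(variantInfo(b1)$rsID, "rs1")
})

test_that("burden invariants hold on random probability data", {
    set.seed(99)
    for (rep in 1:5) {
        spec <- simSpec(seed = 100 + rep, nIndividuals = 40,
                        phenotypeCount = 1,
                        variantMAFs = runif(8, 0.01, 0.04),
                        missingRate = 0.15, certainty = 0.9)
        g <- simulateGenotypes(spec)$geno
        for (m in c("expected", "threshold")) {
            b <- buildBurden(g, method = m, rareThresh = 0.5, callThres = 0.8)
            r <- minorCount(b); n <- typedCount(b); z <- burdenProportion(b)
            expect_true(all(r >= -1e-9))
            expect_true(all(r <= 2 * n + 1e-9))
            ok <- !is.na(z)
            expect_true(all(z[ok] >= -1e-9 & z[ok] <= 1 + 1e-9))
        }
    }
})

test_that("expected and threshold methods agree on degenerate triplets", {
    spec <- simSpec(seed = 21, nIndividuals = 50, phenotypeCount = 1,
                    variantMAFs = c(0.02, 0.03, 0.04), missingRate = 0.1,
                    certainty = 1)
    g <- simulateGenotypes(spec)$geno
    be <- buildBurden(g, method = "expected", rareThresh = 0.5)
    bt <- buildBurden(g, method = "threshold", callThres = 1, rareThresh = 0.5)
    expect_equal(minorCount(be), minorCount(bt))
    expect_equal(typedCount(be), typedCount(bt))
    expect_equal(burdenProportion(be), burdenProportion(bt))
})

test_that("adding a carried variant never decreases the minor count", {
    set.seed(31)
    base <- list(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rbind(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0)))
    extra <- rbind(c(0, 1, 0), c(0, 0, 1), c(0, 1, 0))  # all carry >= 1
    b0 <- buildBurden(genoFromTriplets(base), filter = FALSE)
    b1 <- buildBurden(genoFromTriplets(c(base, list(extra))), filter = FALSE)
    expect_true(all(minorCount(b1) >= minorCount(b0) - 1e-12))
})
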