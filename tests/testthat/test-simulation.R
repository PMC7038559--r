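test_that("simulated site labels follow the requested fraction", {
    ds <- simulateHmrDataset(nPeaks = 1000, fracNonclassical = 0.5,
                             seed = 3)
    k <- sum(siteLabels(ds) == "non_classical")
    # binomial 99% CI around 500
    expect_gt(k, 500 - 2.58 * sqrt(250))
    expect_lt(k, 500 + 2.58 * sqrt(250))
    expect_equal(nPeaks(ds), 1000L)
    # peaks laid out non-overlapping on one synthetic chromosome
    gr <- peakRanges(ds)
    expect_true(GenomicRanges::isDisjoint(gr))
    expect_error(simulateHmrDataset(fracNonclassical = 1.2),
                 "fracNonclassical")
    expect_error(simulateHmrDataset(muLow = 9, muHigh = 8), "muLow")
})

test_that("vanishing spread collapses the response onto the two means", {
    ds <- simulateHmrDataset(nPeaks = 300, sdLow = 1e-9, sdHigh = 1e-9,
                             muLow = 1, muHigh = 8, seed = 5)
    y <- responseValues(ds)
    expect_true(all(abs(y - 1) < 1e-6 | abs(y - 8) < 1e-6))
})

test_that("generated cobinding columns land in their strata", {
    ds <- simulateHmrDataset(nPeaks = 800, seed = 21)
    ds <- simulateCobinding(ds, seed = 22)
    X <- cobindingMatrix(ds)
    expect_equal(ncol(X), 100L)
    expect_equal(unname(table(ds@groupOf)[c("strong_negative",
        "weak_negative", "weak_positive", "strong_positive")]),
        c(15L, 35L, 35L, 15L), ignore_attr = TRUE)
    y <- responseValues(ds)
    # independent re-scoring of every column via lm
    for (j in seq_len(ncol(X))) {
        fit <- summary(lm(y ~ X[, j]))
        slope <- coef(fit)[2, 1]
        adj <- fit$adj.r.squared
        g <- ds@groupOf[colnames(X)[j]]
        if (grepl("negative$", g)) expect_lt(slope, 0)
        else expect_gt(slope, 0)
        if (grepl("^strong", g)) expect_gt(adj, 0.1)
        else {
            expect_gt(adj, 0.005)
            expect_lt(adj, 0.1)
        }
    }
})

test_that("simulateFactorGroup agrees with univariateRefit scoring", {
    ds <- simulateHmrDataset(nPeaks = 600, seed = 31)
    col <- simulateFactorGroup(ds, "strong_negative", seed = 7)
    st <- univariateRefit(col$column, responseValues(ds))
    expect_equal(st$slope, col$slope)
    expect_equal(st$adjR2, col$adjR2)
    expect_lt(st$slope, 0)
    expect_gt(st$adjR2, 0.1)
    colW <- simulateFactorGroup(ds, "weak_positive", seed = 8)
    stW <- univariateRefit(colW$column, responseValues(ds))
    expect_gt(stW$slope, 0)
    expect_lt(stW$adjR2, 0.1)
    expect_gt(stW$adjR2, 0.005)
})

test_that("simulation is bit-reproducible given the seed", {
    a <- simulateCobinding(simulateHmrDataset(nPeaks = 400, seed = 9),
                           seed = 10)
    b <- simulateCobinding(simulateHmrDataset(nPeaks = 400, seed = 9),
                           seed = 10)
    expect_identical(responseValues(a), responseValues(b))
    expect_identical(cobindingMatrix(a), cobindingMatrix(b))
    expect_identical(siteLabels(a), siteLabels(b))
})

test_that("histone-mark noise shifts the response as specified", {
    ds <- simulateHmrDataset(nPeaks = 2000, seed = 12)
    expect_identical(responseValues(addHmNoise(ds, 0)),
                     responseValues(ds))
    m <- ds@params$genomeMeanSignal
    noisy <- addHmNoise(ds, 1, seed = 99)
    shift <- mean(responseValues(noisy)) - mean(responseValues(ds))
    # mean shift ~ m before truncation at 0; truncation bites mildly
    expect_gt(shift, 0.7 * m)
    expect_lt(shift, 1.2 * m)
    expect_identical(siteLabels(noisy), siteLabels(ds))
    expect_true(all(responseValues(noisy) >= 0))
})

test_that("site loss removes only non-classical rows, alignment intact", {
    ds <- simulateCobinding(simulateHmrDataset(nPeaks = 500, seed = 14),
                            seed = 15)
    expect_identical(dropNonclassicalSites(ds, 0), ds)
    nc0 <- sum(siteLabels(ds) == "non_classical")
    cl0 <- sum(siteLabels(ds) == "classical")
    red <- dropNonclassicalSites(ds, 0.8, seed = 16)
    expect_equal(sum(siteLabels(red) == "non_classical"),
                 nc0 - round(0.8 * nc0))
    expect_equal(sum(siteLabels(red) == "classical"), cl0)
    # rows of X, Y and labels were removed together
    key0 <- paste(responseValues(ds),
                  apply(cobindingMatrix(ds)[, 1:5], 1, paste,
                        collapse = ""), siteLabels(ds))
    keyR <- paste(responseValues(red),
                  apply(cobindingMatrix(red)[, 1:5], 1, paste,
                        collapse = ""), siteLabels(red))
    expect_true(all(keyR %in% key0))
    expect_equal(nPeaks(red), length(siteLabels(red)))
    expect_true(validObject(red))
})

test_that("cobinding flips have exact Hamming weight and are involutive", {
    ds <- simulateCobinding(simulateHmrDataset(nPeaks = 1000, seed = 17),
                            seed = 18)
    expect_identical(flipCobinding(ds, 0), ds)
    f <- flipCobinding(ds, 0.1, seed = 19)
    d <- abs(cobindingMatrix(f) - cobindingMatrix(ds))
    expect_true(all(colSums(d) == 100))
    back <- flipCobinding(f, 0.1, seed = 19)
    expect_identical(cobindingMatrix(back), cobindingMatrix(ds))
})

test_that("prediction scoring implements the confusion formulas", {
    ds <- simulateCobinding(simulateHmrDataset(nPeaks = 300, seed = 25),
                            seed = 26)
    g <- ds@groupOf
    pos <- names(g)[g == "strong_negative"]
    neg <- names(g)[g != "strong_negative"]
    # 2 false positives: tn = 83, fp = 2 -> specificity 83/85
    m <- scorePrediction(c(pos, neg[1:2]), ds)
    expect_equal(m$tp, 15); expect_equal(m$fp, 2)
    expect_equal(m$tn, 83); expect_equal(m$fn, 0)
    expect_equal(m$specificity, 83 / 85)
    # perfect prediction: f_beta = 1
    perf <- scorePrediction(pos, ds)
    expect_equal(perf$precision, 1)
    expect_equal(perf$recall, 1)
    expect_equal(perf$fBeta, 1)
    # precision 0.5, recall 1, beta 0.75 -> 1.5625*0.5/(0.5625*0.5+1)
    half <- scorePrediction(c(pos, neg[1:15]), ds)
    expect_equal(half$precision, 0.5)
    expect_equal(half$fBeta, 1.5625 * 0.5 / (0.5625 * 0.5 + 1))
    expect_equal(half$fBeta, 0.6097561, tolerance = 1e-6)
    # empty prediction: recall 0, fBeta 0, specificity still defined
    none <- scorePrediction(character(0), ds)
    expect_equal(none$recall, 0)
    expect_equal(none$fBeta, 0)
    expect_equal(none$specificity, 1)
    expect_error(scorePrediction("nosuch", ds), "unknown")
})

test_that("confusion counts always partition the factor set", {
    ds <- simulateCobinding(simulateHmrDataset(nPeaks = 300, seed = 27),
                            seed = 28)
    set.seed(29)
    for (i in 1:10) {
        pred <- sample(names(ds@groupOf), sample(0:40, 1))
        m <- scorePrediction(pred, ds)
        expect_equal(m$tp + m$fn, 15)
        expect_equal(m$tn + m$fp, 85)
        expect_true(all(c(m$specificity, m$precision, m$recall,
                          m$fBeta) >= 0))
        expect_true(all(c(m$specificity, m$precision, m$recall,
                          m$fBeta) <= 1))
    }
})
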