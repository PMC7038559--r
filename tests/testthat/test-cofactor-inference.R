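# A small bimodal regression problem with planted signal columns.
mkDesign <- function(seed, n = 300, pSignal = 5, noiseCol = FALSE) {
    set.seed(seed)
    lab <- rbinom(n, 1, 0.5)
    y <- pmax(ifelse(lab == 1, rnorm(n, 1, 0.5), rnorm(n, 8, 2)), 0)
    X <- vapply(seq_len(pSignal), function(j)
        rbinom(n, 1, ifelse(lab == 1, 0.75, 0.25)), numeric(n))
    colnames(X) <- paste0("s", seq_len(pSignal))
    if (noiseCol) {
        X <- cbind(X, noise = sample(X[, 1]))
    }
    list(X = X, y = y, lab = lab)
}

test_that("univariate refit matches the closed-form OLS oracle", {
    st <- univariateRefit(c(1, 1, 0, 0), c(1, 2, 3, 4))
    expect_equal(st$slope, -2)
    expect_equal(st$r2, 0.8)
    expect_equal(st$adjR2, 0.7)
    # an exact linear relation gives r2 = adjR2 = 1 at any n >= 3
    x <- c(0, 1, 0, 1, 1, 0, 1)
    st2 <- univariateRefit(x, 5 - 3 * x)
    expect_equal(st2$r2, 1)
    expect_equal(st2$adjR2, 1)
    expect_equal(st2$slope, -3)
    expect_error(univariateRefit(rep(1, 5), rnorm(5)), "degenerate")
    expect_error(univariateRefit(c(0, 1), c(1, 2)), "at least 3")
})

test_that("Wherry adjustment behaves as required", {
    # against lm on random cases: adjR2 <= r2, equality only at r2 = 1
    set.seed(4)
    for (i in 1:10) {
        n <- sample(10:60, 1)
        x <- rbinom(n, 1, 0.5)
        if (sd(x) == 0) next
        y <- rnorm(n, 2 - x, 1)
        st <- univariateRefit(x, pmax(y, 0))
        fit <- summary(lm(pmax(y, 0) ~ x))
        expect_equal(st$r2, fit$r.squared, tolerance = 1e-10)
        expect_equal(st$adjR2, fit$adj.r.squared, tolerance = 1e-10)
        expect_lte(st$adjR2, st$r2)
    }
})

test_that("a perfectly anti-correlated column is selected negative", {
    set.seed(2)
    x <- rbinom(60, 1, 0.5)
    y <- 10 - 8 * x
    sel <- elasticNetSelect(cbind(tf = x), y,
                            regressionConfig(seed = 1, cvFolds = 5))
    expect_true("tf" %in% sel$factor)
    expect_lt(sel$coefficient[sel$factor == "tf"], 0)
    selL <- lassoSelect(cbind(tf = x), y,
                        regressionConfig(seed = 1, cvFolds = 5))
    expect_lt(selL$coefficient[selL$factor == "tf"], 0)
})

test_that("with no penalty the fit reduces to ordinary least squares", {
    set.seed(3)
    x <- rbinom(80, 1, 0.4)
    y <- pmax(rnorm(80, 6 - 4 * x, 1), 0)
    sel <- elasticNetSelect(cbind(tf = x), y, regressionConfig(),
                            lambda = 0)
    expect_equal(sel$coefficient, unname(coef(lm(y ~ x))[2]),
                 tolerance = 1e-6)
    # multi-predictor: lambda -> 0 converges to OLS
    d <- mkDesign(31)
    sel2 <- elasticNetSelect(d$X, d$y, regressionConfig(), lambda = 1e-8)
    ols <- coef(lm(d$y ~ d$X))[-1]
    got <- setNames(rep(0, ncol(d$X)), colnames(d$X))
    got[sel2$factor] <- sel2$coefficient
    expect_equal(unname(got), unname(ols), tolerance = 1e-3)
})

test_that("lasso is the alpha = 0 special case of the elastic net", {
    d <- mkDesign(12)
    cfg <- regressionConfig(alpha = 0, seed = 42)
    a <- elasticNetSelect(d$X, d$y, cfg)
    b <- lassoSelect(d$X, d$y, regressionConfig(alpha = 0.5, seed = 42))
    expect_identical(a, b)
})

test_that("lasso on an orthonormal design matches soft-thresholding", {
    set.seed(8)
    n <- 64; p <- 5
    M <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
    X <- qr.Q(qr(M)) * sqrt(n)
    colnames(X) <- paste0("f", seq_len(p))
    y <- rnorm(n, 0, 2)
    bOls <- as.numeric(crossprod(X, y - mean(y))) / n
    lamP <- 0.5 * n * median(abs(bOls))
    sel <- lassoSelect(X, y, regressionConfig(), lambda = lamP,
                       standardize = FALSE)
    got <- setNames(rep(0, p), colnames(X))
    got[sel$factor] <- sel$coefficient
    expect_equal(unname(got), softThreshold(bOls, lamP / n),
                 tolerance = 1e-6)
})

test_that("penalized objective at the fit beats zero and OLS solutions", {
    # objective in the package convention:
    # 0.5*RSS + lambda*sum(alpha*b^2 + (1-alpha)*|b|)
    obj <- function(b0, b, X, y, lam, alpha)
        0.5 * sum((y - b0 - X %*% b)^2) +
            lam * sum(alpha * b^2 + (1 - alpha) * abs(b))
    d <- mkDesign(19, n = 200)
    for (alpha in c(0, 0.5)) {
        lamP <- 20
        sel <- elasticNetSelect(d$X, d$y,
                                regressionConfig(alpha = alpha),
                                lambda = lamP, standardize = FALSE)
        b <- setNames(rep(0, ncol(d$X)), colnames(d$X))
        b[sel$factor] <- sel$coefficient
        # refit the intercept at the returned slopes
        b0 <- mean(d$y - d$X %*% b)
        fHat <- obj(b0, b, d$X, d$y, lamP, alpha)
        fZero <- obj(mean(d$y), rep(0, ncol(d$X)), d$X, d$y, lamP, alpha)
        ols <- lm(d$y ~ d$X)
        fOls <- obj(coef(ols)[1], coef(ols)[-1], d$X, d$y, lamP, alpha)
        tol <- 1e-4 * fZero
        expect_lte(fHat, fZero + tol)
        expect_lte(fHat, fOls + tol)
    }
})

test_that("an independent column is dropped at lambda.1se", {
    zeros <- 0L
    for (s in 1:20) {
        d <- mkDesign(s, noiseCol = TRUE)
        sel <- elasticNetSelect(d$X, d$y,
                                regressionConfig(seed = 100 + s))
        if (!"noise" %in% sel$factor) zeros <- zeros + 1L
    }
    expect_gte(zeros, 19L)
})

test_that("degenerate inputs are rejected", {
    expect_error(elasticNetSelect(cbind(a = rbinom(30, 1, 0.5)),
                                  rep(2, 30), regressionConfig()),
                 "degenerate response")
    # an all-zero column is permissible and never selected
    d <- mkDesign(5)
    X <- cbind(d$X, dead = 0)
    sel <- elasticNetSelect(X, d$y, regressionConfig(seed = 3))
    expect_false("dead" %in% sel$factor)
})

test_that("forward selection is greedy on RSS and stops correctly", {
    set.seed(2)
    n <- 40
    X <- matrix(rnorm(n * 5), n, 5)
    colnames(X) <- paste0("c", 1:5)
    y <- 10 - 8 * X[, 3]
    # exhaustive best first step
    rss <- apply(X, 2, function(x) sum(resid(lm(y ~ x))^2))
    fs <- forwardSelect(X, y)
    expect_equal(fs$factor[1], names(which.min(rss)))
    # y is an exact function of one column: stops after one step
    expect_equal(nrow(fs), 1L)
    expect_equal(fs$coefficient, -8, tolerance = 1e-10)
    # anti-correlated signal among noise columns is picked first
    d <- mkDesign(44, pSignal = 1, noiseCol = FALSE)
    Xn <- cbind(d$X, matrix(rbinom(300 * 4, 1, 0.5), 300, 4,
                            dimnames = list(NULL, paste0("n", 1:4))))
    fs2 <- forwardSelect(Xn, d$y)
    expect_equal(fs2$factor[1], "s1")
    expect_lt(fs2$coefficient[1], 0)
})

test_that("permutation p values behave at the extremes", {
    d <- mkDesign(6, pSignal = 1)
    # strong association: no permutation reaches the original adjR2
    expect_equal(permutationTest(d$X[, 1], d$y, nPerm = 300, seed = 2), 0)
    # a single cobinding event carries no stable association
    set.seed(5)
    x1 <- c(1, rep(0, 49)); yy <- rnorm(50)
    p <- permutationTest(x1, yy, nPerm = 200, seed = 3)
    expect_gt(p, 0.2)
    # deterministic given the seed
    expect_identical(permutationTest(x1, yy, nPerm = 200, seed = 3), p)
    expect_error(permutationTest(rep(0, 20), rnorm(20)), "degenerate")
})

test_that("predictCofactors gates, ranks and calls the verdict", {
    d <- mkDesign(13, pSignal = 2)
    # add positively associated and irrelevant columns
    set.seed(14)
    pos <- rbinom(300, 1, ifelse(d$lab == 1, 0.2, 0.8))
    rnd <- rbinom(300, 1, 0.5)
    X <- cbind(d$X, posA = pos, rndB = rnd)
    rep <- predictCofactors(X, d$y, regressionConfig(seed = 2,
                                                     nPerm = 300))
    tab <- cofactorTable(rep)
    expect_true(verdict(rep))
    expect_setequal(tab$factor, c("s1", "s2"))
    expect_true(all(tab$slope < 0))
    expect_true(all(tab$adjR2 > 0.1))
    expect_true(all(tab$permP < 0.001))
    expect_equal(tab$rank, seq_len(nrow(tab)))
    expect_equal(order(-tab$adjR2), seq_len(nrow(tab)))

    # only positive factors: sign filter empties the report
    Xp <- cbind(posA = pos)
    repP <- predictCofactors(Xp, d$y, regressionConfig(seed = 2))
    expect_false(verdict(repP))
    expect_equal(nrow(cofactorTable(repP)), 0L)
})

test_that("ranking ties break lexicographically by factor name", {
    set.seed(9)
    lab <- rbinom(400, 1, 0.5)
    y <- pmax(ifelse(lab == 1, rnorm(400, 1, 0.5), rnorm(400, 8, 2)), 0)
    colb <- rbinom(400, 1, ifelse(lab == 1, 0.8, 0.2))
    X <- cbind(b = colb, a = colb)
    rep <- predictCofactors(X, y, regressionConfig(seed = 4, nPerm = 200))
    expect_equal(cofactorTable(rep)$factor, c("a", "b"))
})

test_that("raising the adjusted-R2 cutoff never adds candidates", {
    d <- mkDesign(23, pSignal = 4)
    lo <- predictCofactors(d$X, d$y,
                           regressionConfig(seed = 5, nPerm = 200,
                                            r2Cutoff = 0.1))
    hi <- predictCofactors(d$X, d$y,
                           regressionConfig(seed = 5, nPerm = 200,
                                            r2Cutoff = 0.2))
    expect_true(all(cofactorTable(hi)$factor %in%
                    cofactorTable(lo)$factor))
})
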