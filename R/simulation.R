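#' @include AllClasses.R cofactor-inference.R
#' @importFrom stats rbinom
NULL

.defaultGroupSizes <- c(strong_negative = 15L, weak_negative = 35L,
                        weak_positive = 35L, strong_positive = 15L)

#' Simulate a synthetic HMR dataset (response and site labels)
#'
#' Emulates the bimodal per-peak histone-mark signal of an HMR with a
#' non-classical function: each peak is non-classical with probability
#' `fracNonclassical`; the response is drawn from
#' `Normal(muLow, sdLow)` at non-classical and `Normal(muHigh, sdHigh)`
#' at classical peaks, truncated at 0 (signal densities are
#' non-negative). Synthetic peak coordinates are laid out non-overlapping
#' on one synthetic chromosome. Default mixture parameters place the two
#' components roughly five pooled standard deviations apart, the clearly
#' bimodal regime of a broad repressive mark over its bound peaks;
#' `genomeMeanSignal` (default 2) is the genome-wide average signal used
#' to scale the additive noise model, set to about half the overall
#' peak-level mean as befits a broad mark covering much of the genome.
#'
#' @param nPeaks number of synthetic HMR peaks (default 5000).
#' @param fracNonclassical probability a peak is non-classical, in (0, 1)
#'   (default 0.5).
#' @param muLow,sdLow mean and SD of the non-classical (mark-depleted)
#'   component (defaults 1 and 0.5).
#' @param muHigh,sdHigh mean and SD of the classical component (defaults
#'   8 and 2); `muLow < muHigh` is required.
#' @param genomeMeanSignal genome-wide average mark signal `m`, the unit
#'   of the additive noise model in [addHmNoise()].
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return a [SimulatedDataset] with an empty cobinding matrix; see
#'   [simulateCobinding()].
#' @export
simulateHmrDataset <- function(nPeaks = 5000L, fracNonclassical = 0.5,
                               muLow = 1, sdLow = 0.5, muHigh = 8,
                               sdHigh = 2, genomeMeanSignal = 2,
                               seed = 1L) {
    if (fracNonclassical <= 0 || fracNonclassical >= 1)
        stop("'fracNonclassical' must lie strictly in (0, 1)")
    if (muLow >= muHigh)
        stop("'muLow' must be smaller than 'muHigh'")
    if (sdLow <= 0 || sdHigh <= 0)
        stop("standard deviations must be positive")
    set.seed(seed)
    n <- as.integer(nPeaks)
    labels <- ifelse(runif(n) < fracNonclassical,
                     "non_classical", "classical")
    nc <- labels == "non_classical"
    y <- numeric(n)
    y[nc] <- rnorm(sum(nc), muLow, sdLow)
    y[!nc] <- rnorm(sum(!nc), muHigh, sdHigh)
    y <- pmax(y, 0)
    starts0 <- (seq_len(n) - 1L) * 2000L
    gr <- GRanges("chrSim", IRanges(starts0 + 1L, starts0 + 500L))
    peaks <- new("PeakSet", factorName = "simHMR", ranges = gr)
    resp <- new("ResponseVector", values = y, hmName = "simHM",
                halfwidth = 5000)
    emptyX <- new("CobindingMatrix",
                  matrix = matrix(numeric(0), nrow = n, ncol = 0L),
                  mode = "binary")
    params <- list(nPeaks = n, fracNonclassical = fracNonclassical,
                   muLow = muLow, sdLow = sdLow, muHigh = muHigh,
                   sdHigh = sdHigh, genomeMeanSignal = genomeMeanSignal)
    new("SimulatedDataset", peaks = peaks, response = resp,
        labels = labels, cobinding = emptyX,
        groupOf = stats::setNames(character(0), character(0)),
        params = params, noise = character(0), seed = as.integer(seed))
}

#' Simulate one planted cobinding column of a given group
#'
#' Generates a binary cobinding column by Bernoulli sampling with
#' probability `p1` at non-classical and `p0` at classical peaks
#' (`p1 > p0` for the negative groups, `p1 < p0` for the positive ones).
#' `(p0, p1)` are solved from a target adjusted R-squared drawn inside
#' the group's stratum, and the realized column is re-scored against the
#' clean response: strong groups must land at adjusted R2 > 0.1 with the
#' required slope sign, weak groups strictly between 0.005 and 0.1 (the
#' 0.005 floor keeps "weak" distinguishable from pure noise). Columns
#' failing their stratum are regenerated with a new sub-seed, up to 100
#' attempts.
#'
#' @param dataset a [SimulatedDataset] (labels and clean response).
#' @param group one of `strong_negative`, `weak_negative`,
#'   `weak_positive`, `strong_positive`.
#' @param seed integer seed for this column.
#' @return list with `column` (binary vector), `p0`, `p1`, and the
#'   realized `slope`/`adjR2` of the univariate refit.
#' @export
simulateFactorGroup <- function(dataset, group, seed = 1L) {
    group <- match.arg(group, names(.defaultGroupSizes))
    y <- dataset@response@values
    lab <- dataset@labels
    nc <- lab == "non_classical"
    n <- length(y)
    f <- mean(nc)
    m1 <- mean(y[nc])
    m0 <- mean(y[!nc])
    vy <- var(y)
    strong <- grepl("^strong", group)
    negative <- grepl("negative$", group)
    for (attempt in seq_len(100L)) {
        set.seed(seed + attempt - 1L)
        target <- if (strong) runif(1, 0.14, 0.32)
                  else runif(1, 0.015, 0.085)
        q <- runif(1, 0.35, 0.65)
        delta <- sqrt(target * q * (1 - q) * vy) /
            (f * (1 - f) * abs(m1 - m0))
        if (!negative) delta <- -delta
        p1 <- q + (1 - f) * delta
        p0 <- q - f * delta
        if (p0 < 0.01 || p0 > 0.99 || p1 < 0.01 || p1 > 0.99) next
        col <- numeric(n)
        col[nc] <- rbinom(sum(nc), 1L, p1)
        col[!nc] <- rbinom(sum(!nc), 1L, p0)
        if (sd(col) == 0) next
        st <- .refitStats(col, y)
        signOK <- if (negative) st$slope < 0 else st$slope > 0
        stratumOK <- if (strong) st$adjR2 > 0.1
                     else st$adjR2 > 0.005 && st$adjR2 < 0.1
        if (signOK && stratumOK)
            return(list(column = col, p0 = p0, p1 = p1,
                        slope = st$slope, adjR2 = st$adjR2,
                        group = group))
    }
    stop("could not generate a '", group, "' column in its adjusted-R2 ",
         "stratum; mixture separation may be too small")
}

#' Plant the grouped cobinding matrix into a simulated dataset
#'
#' Generates all cobinding columns, by default 15 strong-negative, 35
#' weak-negative, 35 weak-positive and 15 strong-positive factors, each
#' verified to land in its group's adjusted-R-squared stratum with the
#' prescribed sign (see [simulateFactorGroup()]).
#'
#' @param dataset a [SimulatedDataset] with a clean response.
#' @param groupSizes named integer vector over the four groups.
#' @param seed integer seed; columns get deterministic sub-seeds.
#' @return the dataset with `cobinding` and `groupOf` filled.
#' @export
simulateCobinding <- function(dataset, groupSizes = .defaultGroupSizes,
                              seed = dataset@seed) {
    stopifnot(all(names(groupSizes) %in% names(.defaultGroupSizes)))
    groups <- rep(names(groupSizes), times = groupSizes)
    p <- length(groups)
    n <- length(dataset@labels)
    X <- matrix(0, nrow = n, ncol = p,
                dimnames = list(NULL, sprintf("factor%03d", seq_len(p))))
    for (j in seq_len(p)) {
        col <- simulateFactorGroup(dataset, groups[j],
                                   seed = seed + 7919L * j)
        X[, j] <- col$column
    }
    groupOf <- stats::setNames(groups, colnames(X))
    initialize(dataset,
               cobinding = new("CobindingMatrix", matrix = X,
                               mode = "binary"),
               groupOf = groupOf)
}

#' Add Gaussian histone-mark noise to the response
#'
#' Emulates experimental variation in the mark's ChIP-seq signal: adds
#' `Normal(f * m, (f * m)^2)` noise to every response value, where `m` is
#' the dataset's genome-wide mean signal and `f` the given fraction, then
#' truncates at 0. Ground-truth labels are unchanged.
#'
#' @param dataset a [SimulatedDataset].
#' @param fraction noise scale `f` in `[0, 1]`.
#' @param seed integer seed.
#' @return the perturbed dataset.
#' @export
addHmNoise <- function(dataset, fraction, seed = dataset@seed + 1L) {
    stopifnot(fraction >= 0, fraction <= 1)
    if (fraction == 0) return(dataset)
    m <- dataset@params$genomeMeanSignal
    y <- dataset@response@values
    set.seed(seed)
    y <- pmax(0, y + rnorm(length(y), fraction * m, fraction * m))
    initialize(dataset,
               response = initialize(dataset@response, values = y),
               noise = c(dataset@noise,
                         sprintf("hm_noise(%.3g)", fraction)))
}

#' Randomly drop non-classical sites
#'
#' Emulates experimental variation in the HMR's own ChIP-seq: uniformly
#' removes `round(fraction * #non-classical)` non-classical peaks and the
#' matching rows of the response, labels and cobinding matrix; classical
#' peaks are untouched.
#'
#' @param dataset a [SimulatedDataset].
#' @param fraction fraction of non-classical sites to drop, in
#'   `[0, 0.8]`.
#' @param seed integer seed.
#' @return the reduced dataset (row alignment preserved).
#' @export
dropNonclassicalSites <- function(dataset, fraction,
                                  seed = dataset@seed + 2L) {
    stopifnot(fraction >= 0, fraction <= 0.8)
    nc <- which(dataset@labels == "non_classical")
    k <- round(fraction * length(nc))
    if (k == 0) return(dataset)
    set.seed(seed)
    drop <- sample(nc, k)
    keep <- sort(setdiff(seq_along(dataset@labels), drop))
    X <- dataset@cobinding@matrix
    if (ncol(X)) X <- X[keep, , drop = FALSE]
    initialize(dataset,
               peaks = initialize(dataset@peaks,
                                  ranges = dataset@peaks@ranges[keep]),
               response = initialize(dataset@response,
                                     values = dataset@response@values[keep]),
               labels = dataset@labels[keep],
               cobinding = initialize(dataset@cobinding, matrix = X),
               noise = c(dataset@noise,
                         sprintf("site_loss(%.3g)", fraction)))
}

#' Randomly flip cobinding events
#'
#' Emulates experimental variation in the factors' ChIP-seq: in each
#' cobinding column, a uniformly chosen `round(fraction * n)` entries are
#' bit-flipped (1 to 0 or 0 to 1). Applying the operation twice with the
#' same seed restores the original matrix.
#'
#' @param dataset a [SimulatedDataset] with a cobinding matrix.
#' @param fraction fraction of entries flipped per column, in `[0, 0.2]`.
#' @param seed integer seed.
#' @return the perturbed dataset.
#' @export
flipCobinding <- function(dataset, fraction, seed = dataset@seed + 3L) {
    stopifnot(fraction >= 0, fraction <= 0.2)
    X <- dataset@cobinding@matrix
    n <- nrow(X)
    k <- round(fraction * n)
    if (k == 0 || ncol(X) == 0) return(dataset)
    set.seed(seed)
    for (j in seq_len(ncol(X))) {
        idx <- sample(n, k)
        X[idx, j] <- 1 - X[idx, j]
    }
    initialize(dataset,
               cobinding = initialize(dataset@cobinding, matrix = X),
               noise = c(dataset@noise, sprintf("flip(%.3g)", fraction)))
}

#' Score a cofactor prediction against the planted ground truth
#'
#' Factors of the strong-negative group are the true positives; all
#' other factors are true negatives. Reports the confusion counts,
#' specificity, precision, recall, and the F-beta score with beta = 0.75
#' (precision weighted slightly above recall). An empty prediction has
#' recall 0 and, by convention, precision 0 and F-beta 0.
#'
#' @param predicted character vector of predicted cofactor names (e.g.
#'   `cofactorTable(report)$factor`), a subset of the dataset's factors.
#' @param dataset a [SimulatedDataset] with planted groups.
#' @param beta F-score weight (default 0.75).
#' @return one-row data.frame with columns `tp`, `fp`, `tn`, `fn`,
#'   `specificity`, `precision`, `recall`, `fBeta`.
#' @export
scorePrediction <- function(predicted, dataset, beta = 0.75) {
    groupOf <- dataset@groupOf
    if (!length(groupOf))
        stop("dataset has no planted cobinding groups")
    factors <- names(groupOf)
    if (!all(predicted %in% factors))
        stop("prediction contains unknown factors")
    pos <- factors[groupOf == "strong_negative"]
    tp <- length(intersect(predicted, pos))
    fp <- length(predicted) - tp
    fn <- length(pos) - tp
    tn <- length(factors) - tp - fp - fn
    specificity <- tn / (tn + fp)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    fBeta <- if (precision + recall > 0)
        (1 + beta^2) * precision * recall /
            (beta^2 * precision + recall) else 0
    data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
               specificity = specificity, precision = precision,
               recall = recall, fBeta = fBeta)
}

.replicateSeed <- function(seed, i, salt = 0L) {
    as.integer((as.numeric(seed) + 97L * i + 131L * salt) %% 2147483647)
}

#' Specificity benchmark over replicate simulated datasets
#'
#' Simulates `nDatasets` independent datasets with the default planted
#' groups, runs the cofactor-prediction pipeline with the chosen
#' feature-selection method on each, and scores the predictions against
#' the planted truth. The penalized selectors run the full detector
#' gating; the forward-selection baseline is gated on the
#' strong-correlation refit only (see [predictCofactors()]).
#'
#' @param nDatasets number of replicate datasets (default 5).
#' @param method `"elastic_net"`, `"lasso"` or `"forward"`.
#' @param seed integer master seed.
#' @param nPeaks peaks per dataset (default 5000).
#' @param config a [RegressionConfig]; its seed is re-derived per
#'   replicate.
#' @param ... further arguments to [simulateHmrDataset()].
#' @return list with `replicates` (per-replicate metrics data.frame),
#'   `specificityMean`, `specificitySD` and `method`.
#' @export
runSpecificityExperiment <- function(nDatasets = 5L,
                                     method = c("elastic_net", "lasso",
                                                "forward"),
                                     seed = 1L, nPeaks = 5000L,
                                     config = regressionConfig(), ...) {
    method <- match.arg(method)
    rows <- vector("list", nDatasets)
    for (i in seq_len(nDatasets)) {
        s <- .replicateSeed(seed, i)
        ds <- simulateHmrDataset(nPeaks = nPeaks, seed = s, ...)
        ds <- simulateCobinding(ds, seed = .replicateSeed(seed, i, 1L))
        cfg <- config
        cfg@seed <- .replicateSeed(seed, i, 2L)
        rep <- predictCofactors(ds@cobinding, ds@response, cfg,
                                selector = method)
        m <- scorePrediction(cofactorTable(rep)$factor, ds)
        m$replicate <- i
        rows[[i]] <- m
    }
    reps <- do.call(rbind, rows)
    list(replicates = reps,
         specificityMean = mean(reps$specificity),
         specificitySD = sd(reps$specificity),
         method = method)
}

.defaultNoiseGrid <- function(noiseType) {
    switch(noiseType,
           hm_noise = seq(0.1, 1.0, by = 0.1),
           site_loss = seq(0.1, 0.8, by = 0.1),
           flip = seq(0.02, 0.20, by = 0.02))
}

#' Robustness benchmark across a noise grid
#'
#' Full factorial over noise level x replicate: each replicate dataset is
#' simulated clean, perturbed by the chosen noise model at the given
#' level, run through the pipeline, and scored. Noise types: `hm_noise`
#' (additive Gaussian signal noise, levels 0.1-1.0), `site_loss` (random
#' removal of non-classical sites, levels 0.1-0.8) and `flip` (random
#' bit-flips of cobinding events, levels 0.02-0.2).
#'
#' @param noiseType `"hm_noise"`, `"site_loss"` or `"flip"`.
#' @param grid noise levels; defaults to the type's standard grid.
#' @param nReps replicate datasets per level (default 10).
#' @param method feature-selection method, as in
#'   [runSpecificityExperiment()].
#' @param seed integer master seed.
#' @param nPeaks peaks per dataset.
#' @param config a [RegressionConfig].
#' @param ... further arguments to [simulateHmrDataset()].
#' @return list with `results` (per level x replicate metrics) and
#'   `summary` (per level: mean F-beta, mean specificity).
#' @export
runRobustnessExperiment <- function(noiseType = c("hm_noise",
                                                  "site_loss", "flip"),
                                    grid = NULL, nReps = 10L,
                                    method = c("elastic_net", "lasso",
                                               "forward"),
                                    seed = 1L, nPeaks = 5000L,
                                    config = regressionConfig(), ...) {
    noiseType <- match.arg(noiseType)
    method <- match.arg(method)
    if (is.null(grid))
        grid <- .defaultNoiseGrid(noiseType)
    ok <- switch(noiseType,
                 hm_noise = all(grid >= 0 & grid <= 1),
                 site_loss = all(grid >= 0 & grid <= 0.8),
                 flip = all(grid >= 0 & grid <= 0.2))
    if (!ok)
        stop("noise grid outside the supported range for ", noiseType)
    rows <- list()
    for (i in seq_len(nReps)) {
        s <- .replicateSeed(seed, i)
        base <- simulateHmrDataset(nPeaks = nPeaks, seed = s, ...)
        base <- simulateCobinding(base, seed = .replicateSeed(seed, i, 1L))
        for (lv in grid) {
            noisy <- switch(noiseType,
                hm_noise = addHmNoise(base, lv,
                                      seed = .replicateSeed(seed, i, 3L)),
                site_loss = dropNonclassicalSites(base, lv,
                                      seed = .replicateSeed(seed, i, 4L)),
                flip = flipCobinding(base, lv,
                                      seed = .replicateSeed(seed, i, 5L)))
            cfg <- config
            cfg@seed <- .replicateSeed(seed, i, 6L)
            rep <- predictCofactors(noisy@cobinding, noisy@response, cfg,
                                    selector = method)
            m <- scorePrediction(cofactorTable(rep)$factor, noisy)
            m$level <- lv
            m$replicate <- i
            rows[[length(rows) + 1L]] <- m
        }
    }
    results <- do.call(rbind, rows)
    summary <- do.call(rbind, lapply(split(results, results$level),
        function(d) data.frame(level = d$level[1L],
                               meanFBeta = mean(d$fBeta),
                               meanSpecificity = mean(d$specificity))))
    rownames(summary) <- NULL
    list(results = results, summary = summary, method = method,
         noiseType = noiseType)
}
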