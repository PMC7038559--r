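# Brute-force oracles, independent of the package implementations.

# Per-base mean over [start0, end0) of a toy track given as a data.frame
# (chrom, start, end, value) in 0-based half-open coordinates. Bases not
# covered contribute 0; the window is clipped at 0 and the mean taken over
# the clipped length.
oracleWindowMean <- function(trackDf, chrom, start0, end0) {
    start0 <- max(0, start0)
    len <- end0 - start0
    if (len <= 0) return(0)
    bases <- numeric(len)                 # positions start0 .. end0-1
    rows <- trackDf[trackDf$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
        lo <- max(rows$start[i], start0)
        hi <- min(rows$end[i], end0)
        if (hi > lo)
            bases[(lo - start0 + 1):(hi - start0)] <- rows$value[i]
    }
    mean(bases)
}

# All-pairs interval overlap: binary matrix over HMR intervals x factor
# peak sets, >= 1 bp overlap in half-open coordinates.
oracleOverlapMatrix <- function(hmrDf, factorDfs) {
    n <- nrow(hmrDf)
    X <- matrix(0, n, length(factorDfs),
                dimnames = list(NULL, names(factorDfs)))
    for (j in seq_along(factorDfs)) {
        fd <- factorDfs[[j]]
        for (i in seq_len(n)) {
            hit <- any(fd$chrom == hmrDf$chrom[i] &
                       fd$start < hmrDf$end[i] &
                       fd$end > hmrDf$start[i])
            X[i, j] <- as.numeric(hit)
        }
    }
    X
}

# Exhaustive Otsu: histogram into nBins equal-width bins, then scan every
# internal edge and directly compute the weighted intra-class variance of
# the binned values (bin midpoints weighted by counts); return the edge
# with minimal intra-class variance, lowest edge on ties.
oracleOtsu <- function(values, nBins = 256L) {
    lo <- min(values); hi <- max(values)
    edges <- seq(lo, hi, length.out = nBins + 1L)
    bin <- findInterval(values, edges, rightmost.closed = TRUE,
                        left.open = TRUE, all.inside = TRUE)
    counts <- tabulate(bin, nbins = nBins)
    mids <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
    best <- Inf; bestEdge <- NA_real_
    for (k in seq_len(nBins - 1L)) {
        c0 <- counts[seq_len(k)]; m0 <- mids[seq_len(k)]
        c1 <- counts[(k + 1L):nBins]; m1 <- mids[(k + 1L):nBins]
        n0 <- sum(c0); n1 <- sum(c1)
        if (n0 == 0 || n1 == 0) next
        mu0 <- sum(c0 * m0) / n0; mu1 <- sum(c1 * m1) / n1
        v0 <- sum(c0 * (m0 - mu0)^2) / n0
        v1 <- sum(c1 * (m1 - mu1)^2) / n1
        within <- (n0 * v0 + n1 * v1) / (n0 + n1)
        if (within < best - 1e-12) {
            best <- within
            bestEdge <- edges[k + 1L]
        }
    }
    bestEdge
}

softThreshold <- function(b, lam) sign(b) * pmax(abs(b) - lam, 0)

# Write a small BED file; intervals as (chrom, start, end) 0-based.
writeBed <- function(df, path = tempfile(fileext = ".bed")) {
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
}

writeBedGraph <- function(df, path = tempfile(fileext = ".bedgraph")) {
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
}

# Random piecewise-constant toy track on one or two chromosomes.
randomToyTrack <- function(seed) {
    set.seed(seed)
    chroms <- sample(c("chr1", "chr2"), 1 + rbinom(1, 1, 0.5))
    rows <- do.call(rbind, lapply(chroms, function(ch) {
        k <- sample(3:8, 1)
        bounds <- sort(sample(0:500, k + 1))
        data.frame(chrom = ch, start = bounds[-(k + 1)],
                   end = bounds[-1], value = round(runif(k, 0, 5), 2))
    }))
    rows <- rows[rows$end > rows$start, , drop = FALSE]
    rows
}

toyTrackToSignal <- function(df, name = "toy") {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1, df$end),
                                 score = df$value)
    signalTrack(gr, name = name)
}
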