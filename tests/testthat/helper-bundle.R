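# Writes a small on-disk run bundle (HMR peaks BED, histone-mark
# bedGraph, factor peak BEDs, YAML config) derived from a simulated
# dataset, so the file-to-file pipeline can be exercised end to end.
# Peak i occupies [2000i, 2000i+500); its center is 2000i+250 and the
# +/-1kb signal windows of consecutive peaks tile the chromosome without
# overlap, so the bedGraph reproduces Y exactly.
makeRunBundle <- function(dir, n = 400, seed = 1, factors = c("cofX",
                          "posY"), nPerm = 200, extra = list()) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ds <- simulateHmrDataset(nPeaks = n, seed = seed)
    y <- responseValues(ds)
    nc <- siteLabels(ds) == "non_classical"
    starts <- (seq_len(n) - 1L) * 2000L
    hmrBed <- file.path(dir, "hmr.bed")
    write.table(data.frame("chrSim", starts, starts + 500L), hmrBed,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    centers <- starts + 250L
    bdg <- file.path(dir, "mark.bedgraph")
    write.table(data.frame("chrSim", pmax(centers - 1000L, 0L),
                           centers + 1000L, y), bdg, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    set.seed(seed + 500L)
    factorRecs <- list()
    for (f in factors) {
        p <- if (f == "cofX") ifelse(nc, 0.8, 0.15)
             else ifelse(nc, 0.15, 0.8)
        bound <- rbinom(n, 1, p) == 1
        path <- file.path(dir, paste0(f, ".bed"))
        write.table(data.frame("chrSim", starts[bound] + 100L,
                               starts[bound] + 200L), path, sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        factorRecs[[length(factorRecs) + 1L]] <-
            list(name = f, path = path)
    }
    cfg <- c(list(hmr_peaks = hmrBed,
                  hm_tracks = list(list(name = "simHM", path = bdg)),
                  factors = factorRecs,
                  min_peaks = 1L, n_perm = nPerm, seed = seed,
                  output_dir = file.path(dir, "out")),
             extra)
    cfgPath <- file.path(dir, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    list(config = cfgPath, dir = dir, dataset = ds)
}
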