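# Independent reference implementations used as oracles. These are written
# in a deliberately plain, loop-based style, separate from the package's
# vectorized code paths.

# Reference detrended fluctuation analysis: integrate, detrend each
# non-overlapping box by lm(), pool RMS residuals, slope of log-log fit.
oracleDFA <- function(x, l = 5L) {
    n <- length(x)
    y <- cumsum(x - mean(x))
    sizes <- seq(l, n %/% 4L, by = l)
    fl <- numeric(length(sizes))
    for (si in seq_along(sizes)) {
        s <- sizes[si]
        nb <- n %/% s
        ss <- 0
        for (b in seq_len(nb)) {
            seg <- y[((b - 1L) * s + 1L):(b * s)]
            t <- seq_len(s)
            fit <- stats::lm(seg ~ t)
            ss <- ss + sum(stats::residuals(fit)^2)
        }
        fl[si] <- sqrt(ss / (nb * s))
    }
    as.numeric(stats::coef(stats::lm(log(fl) ~ log(sizes)))[2L])
}

# Brute-force spectral centroid of one box: explicit DFT sums over the
# non-negative frequencies.
oracleCentroid <- function(box, sampleRate) {
    n <- length(box)
    ks <- 0:(n %/% 2L)
    mags <- sapply(ks, function(k) {
        re <- sum(box * cos(-2 * pi * k * (0:(n - 1L)) / n))
        im <- sum(box * sin(-2 * pi * k * (0:(n - 1L)) / n))
        sqrt(re^2 + im^2)
    })
    freqs <- ks * sampleRate / n
    if (sum(mags) <= 0) return(0)
    sum(freqs * mags) / sum(mags)
}

# Direct centered moving average with shrinking symmetric edge windows.
oracleMovAvg <- function(x, window) {
    n <- length(x)
    half <- window %/% 2L
    sapply(seq_len(n), function(i) {
        h <- min(half, i - 1L, n - i)
        mean(x[(i - h):(i + h)])
    })
}

# Tie-corrected Kruskal-Wallis H computed from first principles.
oracleKruskalH <- function(x, g) {
    n <- length(x)
    rk <- rank(x)
    groups <- split(rk, g)
    h <- 12 / (n * (n + 1)) *
        sum(sapply(groups, function(r) length(r) * mean(r)^2)) -
        3 * (n + 1)
    ties <- table(x)
    correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
    h / correction
}

# Quick feature table from simulated walks (shared across model tests).
makeFeatureTable <- function(nPerClass, seed = 11L) {
    ds <- simulateGaitDataset(nPerClass, seed = seed)
    do.call(rbind, lapply(seq_along(ds$walks), function(i)
        computeGaitFeatures(ds$walks[[i]]@series,
                            label = ds$labels$label[i])))
}
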