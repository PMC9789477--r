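makeSeries <- function(ph, fh = NA, pw = NA, fps = 25) {
    detectionSeries("t", data.frame(frame = seq_along(ph) - 1L,
                                    person_h = ph, person_w = pw,
                                    face_h = fh), fps = fps)
}

test_that("gap filling interpolates interior gaps and holds edges", {
    s <- makeSeries(c(10, NA, 14))
    expect_equal(fillGaps(s)@frames$person_h, c(10, 12, 14))

    s <- makeSeries(c(NA, 10, 12))
    expect_equal(fillGaps(s)@frames$person_h, c(10, 10, 12))

    s <- makeSeries(c(NA, 10, NA, NA, 22, NA))
    expect_equal(fillGaps(s)@frames$person_h, c(10, 10, 14, 18, 22, 22))

    expect_error(fillGaps(makeSeries(c(NA, 10, NA))), "unusable")
})

test_that("face-height scaling follows the per-frame, median and constant policies", {
    s <- makeSeries(c(170, 180), fh = c(17, NA))
    out <- scaleByFaceHeight(s)          # frame policy, median fallback
    expect_equal(signalValues(out), c(10, 180 / 17))
    expect_identical(signalStage(out), "face_scaled")

    s2 <- makeSeries(c(180, 200, 220), fh = c(18, 20, NA))
    expect_equal(signalValues(scaleByFaceHeight(s2, "median")),
                 c(180, 200, 220) / 19)
    expect_equal(signalValues(scaleByFaceHeight(s2, "constant", fh = 20)),
                 c(9, 10, 11))

    expect_error(scaleByFaceHeight(makeSeries(c(100, 110))), "no face")
    expect_error(scaleByFaceHeight(makeSeries(c(100, 110)), "constant",
                                   fh = 0), "positive")
    expect_error(scaleByFaceHeight(makeSeries(c(100, NA, 110)),
                                   "constant", fh = 10), "gaps")
})

test_that("min-max normalization pins the range to [0, 1] exactly", {
    s <- heightSignal(c(1, 1.5, 2), stage = "face_scaled")
    expect_equal(signalValues(minmaxNormalize(s)), c(0, 0.5, 1))
    expect_error(minmaxNormalize(heightSignal(rep(5, 4),
                                              stage = "face_scaled")),
                 "degenerate")
    # property: any non-constant series lands exactly on [0, 1]
    for (seed in 1:20) {
        set.seed(seed)
        v <- rnorm(50, sd = runif(1, 0.01, 100)) + runif(1, -50, 50)
        out <- signalValues(minmaxNormalize(heightSignal(v,
                                                         stage = "face_scaled")))
        expect_lte(abs(min(out)), 1e-9)
        expect_lte(abs(max(out) - 1), 1e-9)
    }
})

test_that("moving average matches direct convolution and never inflates variance", {
    s <- heightSignal(c(0, 0, 1, 0, 0), stage = "normalized")
    expect_equal(signalValues(movingAverage(s, 3)),
                 c(0, 1 / 3, 1 / 3, 1 / 3, 0))
    for (seed in 1:10) {
        set.seed(seed)
        v <- runif(40)
        v <- (v - min(v)) / (max(v) - min(v))
        sm <- signalValues(movingAverage(heightSignal(v,
                                                      stage = "normalized"), 5))
        expect_equal(sm, oracleMovAvg(v, 5))
        expect_lte(var(sm), var(v))
    }
    expect_error(movingAverage(heightSignal(c(0, 1), stage = "normalized"),
                               4), "odd")
    expect_error(movingAverage(heightSignal(c(0, 1), stage = "normalized"),
                               5), "longer")
})

test_that("quantization replaces fixed partitions by their means, tail shorter", {
    s <- heightSignal(c(1, 2, 3, 4, 5, 10, 10, 10, 10, 10) / 10,
                      stage = "smoothed")
    expect_equal(signalValues(lloydQuantize(s)),
                 c(rep(0.3, 5), rep(1, 5)))
    # length 12 with partitions 5, 5, 2
    v <- (1:12) / 12
    q <- signalValues(lloydQuantize(heightSignal(v, stage = "smoothed")))
    expect_equal(q, c(rep(mean(v[1:5]), 5), rep(mean(v[6:10]), 5),
                      rep(mean(v[11:12]), 2)))
    # constant input is unchanged
    cs <- heightSignal(rep(0.4, 10), stage = "smoothed")
    expect_equal(signalValues(lloydQuantize(cs)), rep(0.4, 10))
    expect_error(lloydQuantize(heightSignal(c(0.1, 0.2),
                                            stage = "smoothed"), 0),
                 "at least 1")
})

test_that("quantization is idempotent at matching partition size", {
    set.seed(3)
    v <- runif(23)
    q1 <- lloydQuantize(heightSignal(v, stage = "smoothed"), 5)
    q2 <- lloydQuantize(q1, 5)
    expect_equal(signalValues(q2), signalValues(q1))
})

test_that("walks split at the first occurrence of the maximum", {
    tri <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1])
    seg <- splitWalks(heightSignal(tri, stage = "normalized"))
    expect_identical(seg@splitIndex, 50L)
    expect_length(signalValues(seg@forward), 51)
    expect_length(signalValues(seg@backward), 51)

    plateau <- c(seq(0, 1, length.out = 49), rep(1, 5),
                 seq(1, 0, length.out = 48)[-1])
    segP <- splitWalks(heightSignal(plateau, stage = "normalized"))
    expect_identical(segP@splitIndex, 48L)

    mono <- seq(0, 1, length.out = 30)
    expect_warning(segM <- splitWalks(heightSignal(mono,
                                                   stage = "normalized")),
                   "one walking direction")
    expect_length(signalValues(segM@backward), 1)
})

test_that("pipeline stages are enforced in order", {
    raw <- heightSignal(c(1, 2, 3), stage = "raw")
    norm <- heightSignal(c(0, 0.5, 1), stage = "normalized")
    expect_error(movingAverage(raw, 3), "stage")
    expect_error(lloydQuantize(heightSignal(c(1, 2), stage = "raw")),
                 "stage")
    expect_error(splitWalks(heightSignal(c(1, 2), stage = "face_scaled")),
                 "stage")
    expect_error(minmaxNormalize(norm), "stage")
    expect_error(detectEvents(norm), "stage")
})

test_that("face scaling makes the pipeline invariant to pixel rescaling", {
    set.seed(7)
    n <- 60
    ph <- 100 + cumsum(rnorm(n, 1)) + rep(c(0, 3), length.out = n)
    fh <- 14 + rnorm(n, 0, 0.2)
    base <- makeSeries(ph, fh = fh)
    for (c0 in c(0.5, 3)) {
        scaled <- makeSeries(ph * c0, fh = fh * c0)
        a <- signalValues(minmaxNormalize(scaleByFaceHeight(fillGaps(base))))
        b <- signalValues(minmaxNormalize(scaleByFaceHeight(fillGaps(scaled))))
        expect_equal(a, b, tolerance = 1e-12)
    }
})
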