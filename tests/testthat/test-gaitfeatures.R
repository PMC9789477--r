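test_that("events sit at rising plateau starts, in seconds", {
    q <- heightSignal(rep(c(0, 0.1, 0.1, 0.2), each = 5),
                      stage = "quantized")
    expect_equal(detectEvents(q)@timestamps, c(0.2, 0.6))

    stair <- heightSignal(rep(seq(0, 0.6, by = 0.1), each = 10),
                          stage = "quantized")
    expect_length(detectEvents(stair)@timestamps, 6)

    expect_error(detectEvents(heightSignal(rep(0.5, 20),
                                           stage = "quantized")),
                 "insufficient")
    # decreases emit nothing
    down <- heightSignal(rep(c(0.8, 0.5, 0.2), each = 5),
                         stage = "quantized")
    expect_error(detectEvents(down), "insufficient")
})

test_that("stance, swing and stride follow the alternating-interval rule", {
    ev <- function(ts) new("GaitEvents", timestamps = ts,
                           sourceSegment = "forward")
    p <- stridePhases(ev(c(0, 0.4, 0.88)))
    expect_equal(p@stance, 0.4)
    expect_equal(p@swing, 0.48)
    expect_equal(p@stride, 0.88)

    p2 <- stridePhases(ev(c(0, 0.4, 0.9, 1.3, 1.8)))
    expect_equal(p2@stride, c(0.9, 0.9))

    # unpaired trailing interval is dropped
    p3 <- stridePhases(ev(c(0, 0.4, 0.9, 1.3)))
    expect_length(p3@stride, 1)
    expect_error(stridePhases(ev(c(0, 0.5))), "insufficient")

    # stride = stance + swing by construction, asserted anyway
    set.seed(1)
    ts <- cumsum(runif(11, 0.3, 0.6))
    p4 <- stridePhases(ev(ts))
    expect_equal(p4@stride, p4@stance + p4@swing)
    expect_equal(avgStrideTime(p4), mean(p4@stride))
})

test_that("average stride time recovers the simulated cadence", {
    for (cad in c(0.5, 0.8, 1.2)) {
        errs <- vapply(1:5, function(s) {
            w <- simulateWalk(gaitProfile(0, cadence = cad), seed = s)
            f <- computeGaitFeatures(w@series)
            abs(f$S_avg * cad - 1)
        }, numeric(1))
        expect_lt(mean(errs), 0.10)
    }
})

test_that("DFA exponent matches known noise classes and the reference implementation", {
    aw <- dfaAlpha(spectralNoise(2000, slope = 0, seed = 4))
    expect_gt(aw, 0.4); expect_lt(aw, 0.6)

    ab <- dfaAlpha(cumsum(spectralNoise(2000, slope = 0, seed = 5)))
    expect_gt(ab, 1.3); expect_lt(ab, 1.7)

    ap <- mean(vapply(1:5, function(s)
        dfaAlpha(spectralNoise(2000, slope = 1, seed = s)), numeric(1)))
    expect_lt(abs(ap - 1), 0.15)

    # agreement with the independent oracle on matched inputs
    cases <- expand.grid(slope = c(0, 1, 2), seed = 1:7)
    for (i in seq_len(nrow(cases))) {
        x <- spectralNoise(600, slope = cases$slope[i],
                           seed = cases$seed[i])
        expect_lt(abs(dfaAlpha(x) - oracleDFA(x)), 0.05)
    }

    expect_error(dfaAlpha(rnorm(30)), "too short")
    expect_error(dfaAlpha(rep(1, 200)), "degenerate")
})

test_that("amplitude entropy follows the printed sum with the zero convention", {
    expect_equal(signalEntropy(c(0.5, 0.5)), 1.0)
    expect_equal(signalEntropy(1.0), 0.0)
    expect_equal(signalEntropy(c(0.0, 1.0)), 0.0)
    expect_error(signalEntropy(c(0.5, 1.2)), "\\[0, 1\\]")
    # order-free sum
    set.seed(2)
    v <- runif(100)
    expect_equal(signalEntropy(v), signalEntropy(sample(v)))
    expect_gte(signalEntropy(v), 0)
})

test_that("spectral centroids match a brute-force DFT and stay in band", {
    expect_equal(spectralCentroids(rep(0.3, 5), sampleRate = 25), 0)
    # one cycle of a zero-mean sinusoid at fps/boxN sits at that bin
    pure <- 0.4 * sin(2 * pi * (0:4) / 5)
    expect_equal(spectralCentroids(pure, sampleRate = 25), 5,
                 tolerance = 1e-6)
    # with a DC offset the centroid is pulled between 0 and 5 Hz
    box <- 0.5 + pure
    cs <- spectralCentroids(box, sampleRate = 25)
    expect_equal(cs, oracleCentroid(box, 25))
    expect_gt(cs, 1); expect_lt(cs, 5)
    set.seed(8)
    for (i in 1:10) {
        v <- runif(25)
        cs <- spectralCentroids(v, sampleRate = 25)
        expect_length(cs, 5)
        expect_true(all(cs >= 0 & cs <= 12.5))
        for (b in 1:5)
            expect_equal(cs[b], oracleCentroid(v[(5 * b - 4):(5 * b)], 25))
    }
    expect_error(spectralCentroids(runif(10), boxN = 1, sampleRate = 25),
                 "at least 2")
    expect_error(spectralCentroids(runif(10)), "sampleRate")
})

test_that("centroid variability is the mean consecutive difference over N", {
    expect_equal(centroidVariability(c(2, 2, 2)), 0)
    expect_equal(centroidVariability(c(1, 2, 3)), 2 / 3)
    expect_equal(centroidVariability(c(3, 2, 1)), -2 / 3)
    expect_equal(centroidVariability(c(3, 2, 1), absDiff = TRUE), 2 / 3)
    expect_error(centroidVariability(1), "at least 2")
})

test_that("valley-to-peak time uses first occurrences and scales with speed", {
    v <- c(seq(0, 1, length.out = 251), seq(1, 0.5, length.out = 50))
    expect_equal(valleyPeakTime(heightSignal(v, stage = "normalized",
                                             fps = 25)), 10)
    expect_equal(valleyPeakTime(c(0, 1, 0.5, 0.2), sampleRate = 25), 0.04)
    expect_error(valleyPeakTime(rep(0.5, 10), sampleRate = 25),
                 "degenerate")
    # slower walks take longer from valley to peak
    slow <- computeGaitFeatures(simulateWalk(gaitProfile(2), seed = 3)@series)
    fast <- computeGaitFeatures(simulateWalk(gaitProfile(0), seed = 3)@series)
    expect_gt(slow$T, fast$T)
})

test_that("feature extraction yields complete vectors for healthy input and flags degenerate ones", {
    w <- simulateWalk(gaitProfile(0), seed = 21)
    f <- computeGaitFeatures(w@series, label = 0)
    expect_true(all(is.finite(unlist(f[, c("S_avg", "alpha", "E",
                                           "A_delta_C", "T")]))))
    expect_identical(f$flags, "")
    expect_identical(f$label, 0L)

    # near-constant series fails event detection but is flagged, not fatal
    set.seed(1)
    flat <- detectionSeries("flat",
        data.frame(frame = 0:199,
                   person_h = 100 + c(rnorm(199, 0, 0.01), 1),
                   person_w = NA, face_h = 13))
    ff <- suppressWarnings(computeGaitFeatures(flat))
    expect_true(is.na(ff$S_avg))
    expect_match(ff$flags, "S_avg")

    # completion time orders with severity for class-distinct profiles
    fs <- vapply(0:2, function(lab)
        computeGaitFeatures(simulateWalk(gaitProfile(lab),
                                         seed = 31)@series)$T,
        numeric(1))
    expect_true(fs[1] < fs[2] && fs[2] < fs[3])
})

test_that("event timing is invariant to constant height offsets", {
    w <- simulateWalk(gaitProfile(0, noiseSd = 0), seed = 13)
    shifted <- w@series
    fr <- shifted@frames
    fr$person_h <- fr$person_h + 57
    shifted <- detectionSeries(shifted@recordingID, fr, fps = shifted@fps)
    cfg <- gaitConfig(fhPolicy = "constant", constantFh = 30)
    f1 <- computeGaitFeatures(w@series, cfg)
    f2 <- computeGaitFeatures(shifted, cfg)
    expect_equal(f1$S_avg, f2$S_avg)
    expect_equal(f1$T, f2$T)
})
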