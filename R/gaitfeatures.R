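#' Detect gait events on a quantized height signal
#'
#' On a front-view walk the silhouette height grows in spurts: it is
#' constant while the legs pass each other (mid-stance / mid-swing) and
#' steps up when the legs are maximally apart (terminal stance / terminal
#' swing). Each upward step of the quantized staircase is therefore a gait
#' event. An event is emitted at the first frame of every plateau whose
#' level exceeds the preceding plateau's level by more than \code{minRise};
#' decreases and flat repeats emit nothing.
#'
#' A physical rise rarely falls on a partition boundary, so after
#' smoothing and quantization one gait event is typically smeared over a
#' short monotone chain of rising plateaus (a partial rise, the settled
#' level, sometimes a leaked sliver in the preceding partition). Within
#' each maximal chain of consecutive rising plateaus, events are therefore
#' placed where the plateau-to-plateau increment is a (non-strict) local
#' maximum: the partitions carrying the bulk of a rise count, their
#' leakage neighbours do not, and a regular staircase — whose increments
#' are all equal — keeps one event per rise.
#'
#' @param signal a \code{HeightSignal} at stage \code{"quantized"},
#'   normally the forward-walk segment.
#' @param minRise smallest rise (in units of the normalized range) counted
#'   as an event; rises at or below it are treated as residual detection
#'   jitter. The default \code{NULL} estimates the noise floor from the
#'   data: three standard deviations of the plateau-increment noise, with
#'   the noise scale taken from the lower quartile of the absolute
#'   increments (true steps are sparse, large outliers there) and the
#'   threshold capped at a quarter of the largest increment so that
#'   noise-free staircases are never thresholded away. Set 0 for a strict
#'   "any increase" rule.
#' @return A \code{\linkS4class{GaitEvents}} with plateau-start timestamps
#'   in seconds.
#' @examples
#' q <- heightSignal(rep(c(0, 0.1, 0.1, 0.2), each = 5), stage = "quantized")
#' detectEvents(q)   # events at 0.2 s and 0.6 s
#' @export
detectEvents <- function(signal, minRise = NULL) {
    stopifnot(is(signal, "HeightSignal"))
    .stopIfNotStage(signal, "quantized", "detectEvents")
    v <- signal@values
    r <- rle(v)
    nRuns <- length(r$values)
    if (nRuns < 2L)
        stop("insufficient events: signal has no amplitude increases",
             call. = FALSE)
    starts <- cumsum(c(0L, r$lengths[-nRuns]))               # 0-based
    d <- c(-Inf, diff(r$values))
    if (is.null(minRise)) {
        incr <- abs(d[-1L])
        # |N(0,s)| has lower quartile 0.3186 s
        noiseSd <- stats::quantile(incr, 0.25, names = FALSE) / 0.3186
        minRise <- max(0.01, min(3 * noiseSd, 0.25 * max(d[-1L], 0)))
    }
    rising <- d > minRise
    event <- logical(nRuns)
    tol <- 1e-9                       # equal-increment ties must both count
    for (k in which(rising)) {
        leftOK <- !rising[k - 1L] || d[k] >= d[k - 1L] - tol
        rightOK <- k == nRuns || !rising[k + 1L] || d[k] >= d[k + 1L] - tol
        event[k] <- leftOK && rightOK
    }
    if (!any(event))
        stop("insufficient events: signal has no amplitude increases",
             call. = FALSE)
    ts <- starts[event] / signal@fps
    new("GaitEvents", timestamps = ts, sourceSegment = "forward")
}

#' Stance, swing and stride times from gait events
#'
#' Consecutive event intervals alternate between stance (initial contact to
#' terminal stance) and swing (initial swing to terminal swing); a stride
#' is one non-overlapping stance+swing pair. A trailing unpaired interval
#' is dropped.
#'
#' @param events a \code{GaitEvents} with at least 3 timestamps.
#' @return A \code{\linkS4class{StridePhases}}.
#' @examples
#' ev <- new("GaitEvents", timestamps = c(0, 0.4, 0.88),
#'           sourceSegment = "forward")
#' stridePhases(ev)   # stance 0.4, swing 0.48, stride 0.88
#' @export
stridePhases <- function(events) {
    stopifnot(is(events, "GaitEvents"))
    ts <- events@timestamps
    if (length(ts) < 3L)
        stop("insufficient events: at least 3 timestamps are needed for one stride",
             call. = FALSE)
    d <- diff(ts)
    n <- (length(d) %/% 2L) * 2L
    stance <- d[seq(1L, n, by = 2L)]
    swing <- d[seq(2L, n, by = 2L)]
    new("StridePhases", stance = stance, swing = swing,
        stride = stance + swing)
}

#' Average stride time
#'
#' Mean of the stride times; a low value flags the overall short
#' step-length of impaired gait.
#'
#' @param phases a \code{StridePhases}.
#' @return Average stride time in seconds.
#' @export
avgStrideTime <- function(phases) {
    stopifnot(is(phases, "StridePhases"))
    if (!length(phases@stride))
        stop("insufficient events: no complete stride", call. = FALSE)
    mean(phases@stride)
}

#' Detrended fluctuation analysis exponent
#'
#' Estimates the long-range self-affinity of the height signal. The series
#' is integrated (cumulative sum of deviations from its mean), cut into
#' non-overlapping boxes of size s for s = l, 2l, 3l, ... up to a quarter
#' of the series length, each box detrended by its least-squares line, and
#' the RMS residual fluctuation F(s) pooled over boxes. The exponent alpha
#' is the ordinary least-squares slope of log F(s) versus log s: about 0.5
#' for uncorrelated noise, 1 for self-similar (1/f) structure, 1.5 for
#' Brownian-like signals. Healthy gait progresses smoothly; shuffling
#' breaks the self-affinity of the height trace.
#'
#' @param signal a \code{HeightSignal} (any gap-free stage) or a plain
#'   numeric series.
#' @param boxSizeL base box size l in samples (default 5); box sizes are
#'   its multiples. At least 4 box sizes must fit, so the series must be
#'   at least 16 l samples long.
#' @return The scaling exponent alpha (dimensionless).
#' @examples
#' set.seed(1)
#' dfaAlpha(cumsum(rnorm(2000)))   # Brownian: about 1.5
#' @export
dfaAlpha <- function(signal, boxSizeL = 5L) {
    x <- if (is(signal, "HeightSignal")) signal@values else as.numeric(signal)
    if (anyNA(x)) stop("signal contains gaps", call. = FALSE)
    l <- as.integer(boxSizeL)
    if (l < 2L) stop("boxSizeL must be at least 2", call. = FALSE)
    n <- length(x)
    nSizes <- n %/% (4L * l)
    if (nSizes < 4L)
        stop(sprintf("signal too short for DFA: need at least %d samples for boxSizeL = %d",
                     16L * l, l), call. = FALSE)
    y <- cumsum(x - mean(x))
    sizes <- l * seq_len(nSizes)
    fl <- vapply(sizes, function(s) {
        nb <- n %/% s
        m <- matrix(y[seq_len(nb * s)], nrow = s)
        t <- seq_len(s)
        tc <- t - mean(t)
        sxx <- sum(tc^2)
        slope <- colSums(m * tc) / sxx
        resid <- m - outer(tc, slope) -
            matrix(colMeans(m), nrow = s, ncol = nb, byrow = TRUE)
        sqrt(mean(resid^2))
    }, numeric(1))
    if (any(fl <= 0))
        stop("degenerate signal: zero fluctuation at some scale",
             call. = FALSE)
    unname(stats::lm(log(fl) ~ log(sizes))$coefficients[2L])
}

#' Amplitude entropy of a normalized height signal
#'
#' Shannon-style sum \eqn{E = -\sum_i x_i \log_2 x_i} over the normalized
#' amplitudes themselves (not a probability distribution), with the
#' \eqn{0 \log 0 := 0} limit convention. Irregular, shuffling progress
#' raises E relative to a smooth approach.
#'
#' @param signal a \code{HeightSignal} at stage \code{"normalized"} or
#'   later, or a numeric vector with values in [0, 1].
#' @return Entropy E (dimensionless, non-negative).
#' @examples
#' signalEntropy(c(0.5, 0.5))   # 1
#' @export
signalEntropy <- function(signal) {
    x <- if (is(signal, "HeightSignal")) {
        .stopIfNotStage(signal, .stageAtLeast("normalized"), "signalEntropy")
        signal@values
    } else as.numeric(signal)
    if (anyNA(x) || any(x < 0 | x > 1))
        stop("entropy requires amplitudes in [0, 1]", call. = FALSE)
    terms <- ifelse(x > 0, x * log2(x), 0)
    -sum(terms)
}

#' Short-window spectral centroids
#'
#' Cuts the signal into non-overlapping boxes of \code{boxN} samples
#' (an incomplete tail is dropped) and computes, per box, the
#' magnitude-weighted mean frequency \eqn{C = \sum f_i x_i / \sum x_i}
#' over the non-negative discrete frequencies \eqn{f_i = i \cdot fps /
#' boxN} Hz, with \eqn{x_i} the DFT magnitudes. A box of zeros yields 0 Hz.
#'
#' @param signal a \code{HeightSignal} or numeric vector.
#' @param boxN box size in samples (default 5).
#' @param sampleRate sampling rate in Hz; taken from the signal object when
#'   omitted.
#' @return Numeric vector of per-box centroids in Hz, each within
#'   \code{[0, sampleRate/2]}.
#' @export
spectralCentroids <- function(signal, boxN = 5L, sampleRate = NULL) {
    x <- if (is(signal, "HeightSignal")) {
        if (is.null(sampleRate)) sampleRate <- signal@fps
        signal@values
    } else as.numeric(signal)
    if (is.null(sampleRate))
        stop("sampleRate is required for a plain numeric signal",
             call. = FALSE)
    boxN <- as.integer(boxN)
    if (boxN < 2L) stop("boxN must be at least 2", call. = FALSE)
    if (anyNA(x)) stop("signal contains gaps", call. = FALSE)
    nBoxes <- length(x) %/% boxN
    if (nBoxes < 1L) stop("signal shorter than one box", call. = FALSE)
    freqs <- (0:(boxN %/% 2L)) * sampleRate / boxN
    vapply(seq_len(nBoxes), function(b) {
        box <- x[((b - 1L) * boxN + 1L):(b * boxN)]
        mag <- Mod(stats::fft(box))[seq_along(freqs)]
        tot <- sum(mag)
        if (tot <= 0) 0 else sum(freqs * mag) / tot
    }, numeric(1))
}

#' Spectral-centroid variability
#'
#' Mean consecutive difference of the per-box spectral centroids,
#' \eqn{A_{\Delta C} = \sum_{i=2}^{N}(C_i - C_{i-1}) / N}. Festinating
#' gait produces weak, unstable short-window centroids, lowering this
#' feature. The default keeps the signed differences; set \code{absDiff}
#' for a mean absolute-difference variant.
#'
#' @param centroids numeric vector of centroids (Hz), length at least 2.
#' @param absDiff use absolute consecutive differences.
#' @return Centroid variability in Hz.
#' @examples
#' centroidVariability(c(1, 2, 3))   # 2/3
#' @export
centroidVariability <- function(centroids, absDiff = FALSE) {
    centroids <- as.numeric(centroids)
    if (length(centroids) < 2L)
        stop("at least 2 centroids are required", call. = FALSE)
    d <- diff(centroids)
    if (absDiff) d <- abs(d)
    sum(d) / length(centroids)
}

#' Valley-to-peak time
#'
#' Time between the signal's minimum (farthest position) and maximum
#' (closest approach), using first occurrences; effectively the duration
#' of the forward approach, which grows as walking slows.
#'
#' @param signal a \code{HeightSignal} at stage \code{"normalized"} or
#'   later, or a numeric vector.
#' @param sampleRate sampling rate in Hz; taken from the signal object when
#'   omitted.
#' @return Absolute valley-to-peak time in seconds.
#' @export
valleyPeakTime <- function(signal, sampleRate = NULL) {
    x <- if (is(signal, "HeightSignal")) {
        .stopIfNotStage(signal, .stageAtLeast("normalized"), "valleyPeakTime")
        if (is.null(sampleRate)) sampleRate <- signal@fps
        signal@values
    } else as.numeric(signal)
    if (is.null(sampleRate))
        stop("sampleRate is required for a plain numeric signal",
             call. = FALSE)
    if (anyNA(x)) stop("signal contains gaps", call. = FALSE)
    if (max(x) - min(x) <= 0)
        stop("degenerate signal: constant values have no valley or peak",
             call. = FALSE)
    abs(which.max(x) - which.min(x)) / sampleRate
}

#' Extract the five gait features of one recording
#'
#' Computes average stride time on the quantized forward walk (events are
#' only meaningful on the approach, where height steps up) and the
#' signal-shape features — fluctuation exponent alpha, amplitude entropy
#' E, centroid variability A-delta-C and valley-to-peak time T — on the
#' normalized walk (full walk by default, forward-only via
#' \code{config$featureSegment}).
#'
#' A recording for which some feature is not computable (too few events, a
#' degenerate segment) yields a row with \code{NA} in the failing columns
#' and the reasons recorded in \code{flags}; such incomplete rows are
#' excluded from model training by \code{\link{runFeatures}}.
#'
#' @param segments \code{WalkSegments} of the quantized signal.
#' @param fullSignal the normalized full-walk \code{HeightSignal} the
#'   segments were derived from.
#' @param config a \code{\link{gaitConfig}}.
#' @param recordingID,label recording name and optional UPDRS-gait label
#'   for the output row.
#' @return A one-row \code{data.frame} with columns \code{recording_id},
#'   \code{S_avg}, \code{alpha}, \code{E}, \code{A_delta_C}, \code{T},
#'   \code{label}, \code{flags}.
#' @export
extractFeatures <- function(segments, fullSignal, config = gaitConfig(),
                            recordingID = NULL, label = NA_integer_) {
    stopifnot(is(segments, "WalkSegments"), is(fullSignal, "HeightSignal"))
    .stopIfNotStage(fullSignal, .stageAtLeast("normalized"),
                    "extractFeatures")
    if (is.null(recordingID)) recordingID <- fullSignal@recordingID
    flags <- character()
    grab <- function(expr, what) {
        tryCatch(expr, error = function(e) {
            flags <<- c(flags, sprintf("%s: %s", what, conditionMessage(e)))
            NA_real_
        })
    }
    minRise <- if (is.na(config$minRise)) NULL else config$minRise
    sAvg <- grab(avgStrideTime(stridePhases(
        detectEvents(segments@forward, minRise = minRise))), "S_avg")
    shape <- if (config$featureSegment == "forward") {
        initialize(fullSignal,
                   values = fullSignal@values[seq_len(segments@splitIndex + 1L)])
    } else fullSignal
    alpha <- grab(dfaAlpha(shape, boxSizeL = config$boxSizeL), "alpha")
    E <- grab(signalEntropy(shape), "E")
    adc <- grab(centroidVariability(
        spectralCentroids(shape, boxN = config$boxN),
        absDiff = config$absCentroidDiff), "A_delta_C")
    T <- grab(valleyPeakTime(shape), "T")
    data.frame(recording_id = recordingID, S_avg = sAvg, alpha = alpha,
               E = E, A_delta_C = adc, T = T, label = as.integer(label),
               flags = paste(flags, collapse = "; "),
               stringsAsFactors = FALSE)
}
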