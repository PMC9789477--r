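#' Construct a DetectionSeries
#'
#' @param recordingID single string naming the recording.
#' @param frames data.frame with columns \code{frame} (0-based), \code{person_h},
#'   \code{person_w}, \code{face_h}; missing detections as \code{NA}.
#' @param fps frames per second (default 25, the usual clinical recording
#'   rate).
#' @return A \code{\linkS4class{DetectionSeries}}.
#' @examples
#' detectionSeries("rec1",
#'     data.frame(frame = 0:2, person_h = c(100, NA, 110),
#'                person_w = 40, face_h = c(13, NA, 14)))
#' @export
detectionSeries <- function(recordingID, frames, fps = 25) {
    frames$frame <- as.integer(frames$frame)
    for (nm in c("person_h", "person_w", "face_h")) {
        if (is.null(frames[[nm]])) frames[[nm]] <- NA_real_
        frames[[nm]] <- as.numeric(frames[[nm]])
    }
    frames <- frames[order(frames$frame),
                     c("frame", "person_h", "person_w", "face_h"),
                     drop = FALSE]
    rownames(frames) <- NULL
    new("DetectionSeries", recordingID = as.character(recordingID),
        fps = as.numeric(fps), frames = frames)
}

#' Construct a HeightSignal
#'
#' Mostly used internally; the pipeline operations return signals at the
#' appropriate stage themselves.
#'
#' @param values numeric per-frame series.
#' @param fps frames per second.
#' @param recordingID recording name.
#' @param stage pipeline stage label.
#' @return A \code{\linkS4class{HeightSignal}}.
#' @export
heightSignal <- function(values, fps = 25, recordingID = "signal",
                         stage = "raw") {
    new("HeightSignal", recordingID = as.character(recordingID),
        fps = as.numeric(fps), values = as.numeric(values),
        stage = as.character(stage))
}

.stopIfNotStage <- function(signal, allowed, op) {
    if (!signal@stage %in% allowed)
        stop(sprintf("%s expects a signal at stage %s, got '%s'", op,
                     paste(sQuote(allowed), collapse = " or "),
                     signal@stage), call. = FALSE)
    invisible(NULL)
}

.stageAtLeast <- function(stage) {
    .SIGNAL_STAGES[seq(match(stage, .SIGNAL_STAGES), length(.SIGNAL_STAGES))]
}

#' Fill missing person detections in a DetectionSeries
#'
#' Frames where the person detector failed get a person height by linear
#' interpolation between the nearest detections; leading and trailing gaps
#' take the nearest detected value. Face heights are left untouched (the
#' scaling policy of \code{\link{scaleByFaceHeight}} handles missing faces).
#'
#' @param series a \code{DetectionSeries}.
#' @return A \code{DetectionSeries} with no missing person heights.
#' @examples
#' s <- detectionSeries("r", data.frame(frame = 0:2,
#'     person_h = c(10, NA, 14), person_w = NA, face_h = NA))
#' fillGaps(s)@frames$person_h   # 10 12 14
#' @export
fillGaps <- function(series) {
    stopifnot(is(series, "DetectionSeries"))
    fr <- series@frames
    ph <- fr$person_h
    ok <- which(!is.na(ph))
    if (length(ok) < 2L)
        stop("unusable track: need at least 2 frames with a person detection",
             call. = FALSE)
    filled <- stats::approx(x = fr$frame[ok], y = ph[ok], xout = fr$frame,
                            method = "linear", rule = 2)$y
    fr$person_h <- filled
    initialize(series, frames = fr)
}

#' Face-height adjust a detection series
#'
#' Divides the silhouette height by the face height frame by frame,
#' removing inter-subject stature differences (face height is roughly
#' proportional to body height). Policies for frames without a face
#' detection:
#' \describe{
#'   \item{\code{"frame"}}{use the frame's own face height when detected,
#'     otherwise the median of all detected face heights (the default);}
#'   \item{\code{"median"}}{use the recording-wide median of detected face
#'     heights everywhere — appropriate when per-frame face sizes track the
#'     camera distance rather than the subject;}
#'   \item{\code{"constant"}}{use the supplied \code{fh} everywhere.}
#' }
#'
#' @param series a gap-free \code{DetectionSeries} (see
#'   \code{\link{fillGaps}}).
#' @param fhPolicy one of \code{"frame"}, \code{"median"},
#'   \code{"constant"}.
#' @param fh face height in pixels for \code{fhPolicy = "constant"}.
#' @return A \code{HeightSignal} at stage \code{"face_scaled"}.
#' @export
scaleByFaceHeight <- function(series, fhPolicy = c("frame", "median",
                                                   "constant"), fh = NULL) {
    stopifnot(is(series, "DetectionSeries"))
    fhPolicy <- match.arg(fhPolicy)
    fr <- series@frames
    if (anyNA(fr$person_h))
        stop("person heights contain gaps; run fillGaps() first",
             call. = FALSE)
    faces <- fr$face_h[!is.na(fr$face_h)]
    denom <- switch(fhPolicy,
        constant = {
            if (is.null(fh)) stop("fhPolicy 'constant' requires fh",
                                  call. = FALSE)
            rep(as.numeric(fh), nrow(fr))
        },
        median = {
            if (!length(faces))
                stop("no face detections available for scaling", call. = FALSE)
            rep(stats::median(faces), nrow(fr))
        },
        frame = {
            if (!length(faces))
                stop("no face detections available for scaling", call. = FALSE)
            d <- fr$face_h
            d[is.na(d)] <- stats::median(faces)
            d
        })
    if (any(denom <= 0))
        stop("face height must be positive", call. = FALSE)
    heightSignal(fr$person_h / denom, fps = series@fps,
                 recordingID = series@recordingID, stage = "face_scaled")
}

#' Min-max normalize a height signal to [0, 1]
#'
#' Rescales so the lowest point (farthest position) maps to 0 and the
#' highest (closest approach) to 1, removing the effect of camera placement.
#'
#' @param signal a \code{HeightSignal} at stage \code{"raw"} or
#'   \code{"face_scaled"}.
#' @return A \code{HeightSignal} at stage \code{"normalized"}.
#' @examples
#' s <- heightSignal(c(1, 1.5, 2), stage = "face_scaled")
#' signalValues(minmaxNormalize(s))   # 0 0.5 1
#' @export
minmaxNormalize <- function(signal) {
    stopifnot(is(signal, "HeightSignal"))
    .stopIfNotStage(signal, c("raw", "face_scaled"), "minmaxNormalize")
    v <- signal@values
    if (anyNA(v)) stop("signal contains gaps", call. = FALSE)
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0)
        stop("degenerate signal: constant values cannot be normalized",
             call. = FALSE)
    out <- (v - lo) / (hi - lo)
    # guard against last-bit rounding so the stage invariant holds exactly
    out <- pmin(pmax(out, 0), 1)
    initialize(signal, values = out, stage = "normalized")
}

#' Moving-average smoothing
#'
#' Centered moving average that removes frame-to-frame detection jitter.
#' Windows shrink symmetrically at the edges so the output keeps the input
#' length.
#'
#' @param signal a \code{HeightSignal} at stage \code{"normalized"}.
#' @param window odd positive window length in frames; the default of 5
#'   spans 0.2 s at 25 fps, matching the quantization granularity.
#' @return A \code{HeightSignal} at stage \code{"smoothed"}.
#' @export
movingAverage <- function(signal, window = 5L) {
    stopifnot(is(signal, "HeightSignal"))
    .stopIfNotStage(signal, "normalized", "movingAverage")
    window <- as.integer(window)
    if (window < 1L || window %% 2L == 0L)
        stop("window must be an odd positive integer", call. = FALSE)
    v <- signal@values
    n <- length(v)
    if (window > n)
        stop("window longer than the signal", call. = FALSE)
    half <- window %/% 2L
    cs <- cumsum(c(0, v))
    idx <- seq_len(n)
    # symmetric shrink at the edges keeps the filter unbiased for trends
    h <- pmin(half, idx - 1L, n - idx)
    lo <- idx - h
    hi <- idx + h
    out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    out <- pmin(pmax(out, 0), 1)
    initialize(signal, values = out, stage = "smoothed")
}

#' Quantize a height signal into fixed-size partition means
#'
#' Splits the signal into consecutive non-overlapping partitions of
#' \code{partitionSize} frames (a shorter tail is allowed) and replaces
#' each partition by the centroid (arithmetic mean) of its points, yielding
#' a piecewise-constant staircase whose plateaus expose the gait events.
#'
#' @param signal a \code{HeightSignal} at stage \code{"smoothed"}
#'   (\code{"normalized"} input is accepted for workflows that skip
#'   smoothing, and \code{"quantized"} input passes through unchanged —
#'   the operation is idempotent).
#' @param partitionSize frames per partition; the default 5 (0.2 s at
#'   25 fps).
#' @return A \code{HeightSignal} at stage \code{"quantized"}.
#' @examples
#' s <- heightSignal(c(1, 2, 3, 4, 5, 10, 10, 10, 10, 10) / 10,
#'                   stage = "smoothed")
#' signalValues(lloydQuantize(s))   # 0.3 x5, 1.0 x5
#' @export
lloydQuantize <- function(signal, partitionSize = 5L) {
    stopifnot(is(signal, "HeightSignal"))
    .stopIfNotStage(signal, c("normalized", "smoothed", "quantized"),
                    "lloydQuantize")
    partitionSize <- as.integer(partitionSize)
    if (partitionSize < 1L)
        stop("partitionSize must be at least 1", call. = FALSE)
    v <- signal@values
    n <- length(v)
    if (n < partitionSize)
        stop("signal shorter than one partition", call. = FALSE)
    part <- (seq_len(n) - 1L) %/% partitionSize
    means <- vapply(split(v, part), mean, numeric(1))
    out <- means[as.character(part)]
    names(out) <- NULL
    initialize(signal, values = out, stage = "quantized")
}

#' Split a walk into forward and backward segments
#'
#' The subject walks toward the camera, turns, and walks back; the height
#' signal peaks at the closest approach. The walk is split at the first
#' frame attaining the global maximum. If that frame is the first or last
#' frame the recording contains only one walking direction; a warning is
#' issued and the degenerate segment has length 1.
#'
#' @param signal a \code{HeightSignal} at stage \code{"normalized"} or
#'   later.
#' @return A \code{\linkS4class{WalkSegments}}; the turn frame belongs to
#'   both segments.
#' @export
splitWalks <- function(signal) {
    stopifnot(is(signal, "HeightSignal"))
    .stopIfNotStage(signal, .stageAtLeast("normalized"), "splitWalks")
    v <- signal@values
    if (!length(v)) stop("empty signal", call. = FALSE)
    split <- which.max(v)                 # first occurrence on ties
    if (split == 1L || split == length(v))
        warning("maximum at the signal boundary: only one walking direction present",
                call. = FALSE)
    fwd <- initialize(signal, values = v[seq_len(split)])
    bwd <- initialize(signal, values = v[seq(split, length(v))])
    new("WalkSegments", forward = fwd, backward = bwd,
        splitIndex = split - 1L)
}
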