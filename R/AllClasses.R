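#' @import methods
NULL

.SIGNAL_STAGES <- c("raw", "face_scaled", "normalized", "smoothed", "quantized")

#' DetectionSeries: per-frame silhouette and face measurements
#'
#' One recording's worth of per-frame detections: the silhouette bounding-box
#' height and width in pixels and, when a face was found, the face height in
#' pixels. Frames where no person was detected carry \code{NA}; gap handling
#' is deferred to \code{\link{fillGaps}}.
#'
#' @slot recordingID single string identifying the recording.
#' @slot fps frames per second of the source video (default source material
#'   runs at 25 fps).
#' @slot frames \code{data.frame} with columns \code{frame} (0-based integer,
#'   unique, sorted), \code{person_h}, \code{person_w}, \code{face_h}
#'   (positive numerics or \code{NA}).
#' @exportClass DetectionSeries
setClass("DetectionSeries",
    representation(recordingID = "character", fps = "numeric",
                   frames = "data.frame"))

setValidity("DetectionSeries", function(object) {
    msg <- character()
    if (length(object@recordingID) != 1L || is.na(object@recordingID))
        msg <- c(msg, "recordingID must be a single non-NA string")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
        msg <- c(msg, "fps must be a single positive number")
    fr <- object@frames
    need <- c("frame", "person_h", "person_w", "face_h")
    if (!all(need %in% names(fr))) {
        msg <- c(msg, sprintf("frames must have columns %s",
                              paste(need, collapse = ", ")))
    } else if (nrow(fr) > 0L) {
        if (anyNA(fr$frame) || any(duplicated(fr$frame)))
            msg <- c(msg, "frame indices must be unique and non-NA")
        if (is.unsorted(fr$frame))
            msg <- c(msg, "frames must be sorted by frame index")
        ph <- fr$person_h
        if (any(!is.na(ph) & ph <= 0))
            msg <- c(msg, "person_h must be positive when present")
        fh <- fr$face_h
        both <- !is.na(ph) & !is.na(fh)
        if (any(fh[both] >= ph[both]))
            msg <- c(msg, "face_h must be smaller than person_h")
        if (!any(!is.na(ph)))
            msg <- c(msg, "at least one frame must have a person detection")
    }
    if (length(msg)) msg else TRUE
})

#' HeightSignal: the 1-D silhouette-height series of one recording
#'
#' The scalar per-frame height signal at a given pre-processing stage. The
#' stages form a pipeline \code{raw -> face_scaled -> normalized -> smoothed
#' -> quantized}; each processing operation checks the stage of its input so
#' the order cannot be scrambled silently.
#'
#' @slot recordingID single string.
#' @slot fps frames per second.
#' @slot values numeric series, one value per frame, frame 0 first. No
#'   \code{NA} once past the raw stage.
#' @slot stage one of \code{"raw"}, \code{"face_scaled"}, \code{"normalized"},
#'   \code{"smoothed"}, \code{"quantized"}. From \code{"normalized"} onward
#'   all values lie in [0, 1]; a freshly normalized full walk attains 0 and
#'   1 exactly (the \code{\link{minmaxNormalize}} contract).
#' @exportClass HeightSignal
setClass("HeightSignal",
    representation(recordingID = "character", fps = "numeric",
                   values = "numeric", stage = "character"))

setValidity("HeightSignal", function(object) {
    msg <- character()
    if (length(object@stage) != 1L || !object@stage %in% .SIGNAL_STAGES)
        msg <- c(msg, sprintf("stage must be one of %s",
                              paste(.SIGNAL_STAGES, collapse = ", ")))
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
        msg <- c(msg, "fps must be a single positive number")
    v <- object@values
    st <- object@stage[1L]
    if (!identical(st, "raw") && length(v) && anyNA(v))
        msg <- c(msg, "values must be gap-free past the raw stage")
    # normalized-and-later signals live in [0, 1]; exact attainment of the
    # extremes is the contract of minmaxNormalize on the full walk and is
    # not required of segments sliced from it
    tol <- 1e-9
    if (st %in% c("normalized", "smoothed", "quantized") && length(v) &&
        !anyNA(v)) {
        if (min(v) < -tol || max(v) > 1 + tol)
            msg <- c(msg, "values past normalization must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' WalkSegments: forward and backward walk split of a height signal
#'
#' The forward walk (approach toward the camera) covers frames 0 to
#' \code{splitIndex}; the backward walk (retreat) covers \code{splitIndex}
#' to the end. The split sits at the first frame attaining the global
#' maximum height, i.e. the closest approach / turning point.
#'
#' @slot forward,backward \code{HeightSignal} segments (the split frame
#'   belongs to both).
#' @slot splitIndex 0-based frame index of the turn.
#' @exportClass WalkSegments
setClass("WalkSegments",
    representation(forward = "HeightSignal", backward = "HeightSignal",
                   splitIndex = "integer"))

setValidity("WalkSegments", function(object) {
    msg <- character()
    if (length(object@splitIndex) != 1L || is.na(object@splitIndex) ||
        object@splitIndex < 0L)
        msg <- c(msg, "splitIndex must be a single non-negative integer")
    nf <- length(object@forward@values)
    if (nf != object@splitIndex + 1L)
        msg <- c(msg, "forward segment must cover frames 0..splitIndex")
    if (length(object@backward@values) < 1L)
        msg <- c(msg, "backward segment must contain at least the turn frame")
    if (length(msg)) msg else TRUE
})

#' GaitEvents: timestamps of amplitude-increase gait events
#'
#' Ordered timestamps (seconds) at which the quantized height signal steps
#' up, each marking a terminal-stance or terminal-swing instant when the
#' legs are maximally apart and the silhouette grows.
#'
#' @slot timestamps strictly increasing numeric vector, seconds
#'   (plateau-start frame / fps).
#' @slot sourceSegment which part of the walk the events came from:
#'   \code{"forward"}, \code{"backward"} or \code{"full"}.
#' @exportClass GaitEvents
setClass("GaitEvents",
    representation(timestamps = "numeric", sourceSegment = "character"))

setValidity("GaitEvents", function(object) {
    msg <- character()
    ts <- object@timestamps
    if (length(ts) && (anyNA(ts) || any(diff(ts) <= 0)))
        msg <- c(msg, "timestamps must be strictly increasing")
    if (!object@sourceSegment %in% c("forward", "backward", "full"))
        msg <- c(msg, "sourceSegment must be forward, backward or full")
    if (length(msg)) msg else TRUE
})

#' StridePhases: stance, swing and stride times
#'
#' Consecutive event intervals assigned alternately to stance and swing;
#' strides are non-overlapping stance+swing pairs.
#'
#' @slot stance,swing,stride numeric vectors of equal length N (seconds);
#'   \code{stride == stance + swing} elementwise.
#' @exportClass StridePhases
setClass("StridePhases",
    representation(stance = "numeric", swing = "numeric", stride = "numeric"))

setValidity("StridePhases", function(object) {
    msg <- character()
    n <- length(object@stride)
    if (length(object@stance) != n || length(object@swing) != n)
        msg <- c(msg, "stance, swing and stride must have equal length")
    else {
        if (n && any(c(object@stance, object@swing) <= 0))
            msg <- c(msg, "phase times must be positive")
        if (n && any(abs(object@stride - object@stance - object@swing) > 1e-9))
            msg <- c(msg, "stride must equal stance + swing")
    }
    if (length(msg)) msg else TRUE
})

#' GaitProfile: class-conditional parameters of the gait simulator
#'
#' Parameters controlling one simulated walk. Defaults per UPDRS-gait label
#' are supplied by \code{\link{gaitProfile}}: healthy walks are fast with
#' large height steps; level 1 is slower with smaller, more irregular steps;
#' level 2 has the smallest steps, festination bursts and the longest
#' completion time.
#'
#' @slot label UPDRS-gait level 0, 1 or 2.
#' @slot cadence strides per second.
#' @slot stepAmplitude per-event height rise, pixels (two events per stride).
#' @slot amplitudeJitter,cadenceJitter relative (coefficient-of-variation)
#'   jitter on rise size and event interval.
#' @slot festinationRate probability per stride of replacing it with a burst
#'   of 3 quick small rises.
#' @slot turnDwell seconds spent at maximum height while turning.
#' @slot forwardDuration seconds of forward walk.
#' @slot noiseSd additive Gaussian noise on the pixel height, sd in pixels.
#' @slot subjectHeightPx silhouette height in pixels at closest approach.
#' @slot faceRatio face height as a fraction of body height (anthropometric
#'   ratio, about 0.13).
#' @exportClass GaitProfile
setClass("GaitProfile",
    representation(label = "integer", cadence = "numeric",
                   stepAmplitude = "numeric", amplitudeJitter = "numeric",
                   cadenceJitter = "numeric", festinationRate = "numeric",
                   turnDwell = "numeric", forwardDuration = "numeric",
                   noiseSd = "numeric", subjectHeightPx = "numeric",
                   faceRatio = "numeric"))

setValidity("GaitProfile", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    if (!(length(object@label) == 1L && object@label %in% 0:2))
        msg <- c(msg, "label must be 0, 1 or 2")
    for (nm in c("cadence", "stepAmplitude", "turnDwell", "forwardDuration",
                 "noiseSd", "subjectHeightPx", "faceRatio",
                 "amplitudeJitter", "cadenceJitter", "festinationRate")) {
        x <- slot(object, nm)
        if (!num1(x)) msg <- c(msg, sprintf("%s must be a finite scalar", nm))
    }
    if (!length(msg)) {
        if (object@cadence <= 0 || object@stepAmplitude <= 0 ||
            object@forwardDuration <= 0 || object@subjectHeightPx <= 0)
            msg <- c(msg, "cadence, stepAmplitude, forwardDuration and subjectHeightPx must be positive")
        if (object@faceRatio <= 0 || object@faceRatio >= 0.5)
            msg <- c(msg, "faceRatio must lie in (0, 0.5)")
        if (min(object@amplitudeJitter, object@cadenceJitter,
                object@festinationRate, object@turnDwell, object@noiseSd) < 0)
            msg <- c(msg, "jitters, festinationRate, turnDwell and noiseSd must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticWalk: a simulated recording with its ground truth
#'
#' @slot series the simulated \code{DetectionSeries}.
#' @slot truthEvents strictly increasing ground-truth event times (seconds)
#'   of the forward walk.
#' @slot truthSplitIndex 0-based frame index of the scripted turn.
#' @slot profile the \code{GaitProfile} used.
#' @slot seed integer seed that, with the profile and fps, fully determines
#'   the walk.
#' @exportClass SyntheticWalk
setClass("SyntheticWalk",
    representation(series = "DetectionSeries", truthEvents = "numeric",
                   truthSplitIndex = "integer", profile = "GaitProfile",
                   seed = "integer"))

setValidity("SyntheticWalk", function(object) {
    msg <- character()
    te <- object@truthEvents
    if (length(te) && (anyNA(te) || any(diff(te) <= 0)))
        msg <- c(msg, "truthEvents must be strictly increasing")
    if (length(object@truthSplitIndex) != 1L || object@truthSplitIndex < 0L)
        msg <- c(msg, "truthSplitIndex must be a single non-negative integer")
    if (length(msg)) msg else TRUE
})

#' PukSVM: one-vs-all PUK-kernel SVM severity model
#'
#' Three binary soft-margin SVMs (one per UPDRS-gait level against the other
#' two) over a precomputed Pearson-VII-universal-kernel gram matrix, plus
#' the feature standardization fitted on the training split.
#'
#' @slot models list of three fitted \code{kernlab::ksvm} binary machines,
#'   in class order 0, 1, 2.
#' @slot signs orientation (+1/-1) applied to each machine's decision values
#'   so that larger means "more like this class".
#' @slot classes integer class labels (0, 1, 2).
#' @slot center,scale per-feature standardization parameters fitted on the
#'   training split only.
#' @slot trainX standardized training feature matrix (needed to evaluate the
#'   kernel against new samples).
#' @slot omega,sigma PUK kernel tailing factor and half-width.
#' @slot cost soft-margin regularization constant (the SVM's C).
#' @slot featureNames column names the model expects.
#' @exportClass PukSVM
setClass("PukSVM",
    representation(models = "list", signs = "numeric", classes = "integer",
                   center = "numeric", scale = "numeric", trainX = "matrix",
                   omega = "numeric", sigma = "numeric", cost = "numeric",
                   featureNames = "character"))

setValidity("PukSVM", function(object) {
    msg <- character()
    if (length(object@models) != length(object@classes))
        msg <- c(msg, "one binary model per class is required")
    if (length(object@signs) != length(object@classes))
        msg <- c(msg, "one decision sign per class is required")
    pars <- c(object@omega, object@sigma, object@cost)
    if (length(pars) == 3L && any(pars <= 0))
        msg <- c(msg, "omega, sigma and C must be positive")
    if (length(msg)) msg else TRUE
})

#' GaitEvalReport: cross-validated classification performance
#'
#' @slot foldAccuracy accuracy of each CV fold.
#' @slot confusion pooled confusion matrix, rows = true class, columns =
#'   predicted class.
#' @slot tpr per-class true-positive rate (diagonal / row sum).
#' @slot auc per-class one-vs-all AUC from pooled out-of-fold decision
#'   scores.
#' @slot macroAUC mean of the per-class AUCs.
#' @slot roc list of per-class ROC point tables (columns \code{fpr},
#'   \code{tpr}).
#' @slot folds integer fold assignment per sample.
#' @slot seed seed used for the stratified fold draw.
#' @exportClass GaitEvalReport
setClass("GaitEvalReport",
    representation(foldAccuracy = "numeric", confusion = "matrix",
                   tpr = "numeric", auc = "numeric", macroAUC = "numeric",
                   roc = "list", folds = "integer", seed = "integer"))

setValidity("GaitEvalReport", function(object) {
    msg <- character()
    cm <- object@confusion
    if (nrow(cm) != ncol(cm)) msg <- c(msg, "confusion matrix must be square")
    if (any(object@foldAccuracy < 0 | object@foldAccuracy > 1))
        msg <- c(msg, "fold accuracies must lie in [0, 1]")
    ok <- !is.na(object@auc)
    if (any(object@auc[ok] < 0 | object@auc[ok] > 1))
        msg <- c(msg, "AUCs must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
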