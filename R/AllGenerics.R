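#' Accessors for FrontalGait objects
#'
#' Small accessor generics shared across the package's classes:
#' \code{recordingID} and \code{fps} identify a recording and its frame
#' rate; \code{signalValues} and \code{signalStage} expose a
#' \code{HeightSignal}'s series and pipeline stage; \code{nFrames} counts
#' frames.
#'
#' @param object a FrontalGait object.
#' @return \code{recordingID}: a string; \code{fps}, \code{signalValues}:
#'   numeric; \code{signalStage}: a string; \code{nFrames}: an integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordingID", function(object) standardGeneric("recordingID"))

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))

#' @rdname accessors
#' @export
setGeneric("signalStage", function(object) standardGeneric("signalStage"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("recordingID", "DetectionSeries", function(object) object@recordingID)

#' @rdname accessors
#' @export
setMethod("recordingID", "HeightSignal", function(object) object@recordingID)

#' @rdname accessors
#' @export
setMethod("recordingID", "SyntheticWalk",
          function(object) object@series@recordingID)

#' @rdname accessors
#' @export
setMethod("fps", "DetectionSeries", function(object) object@fps)

#' @rdname accessors
#' @export
setMethod("fps", "HeightSignal", function(object) object@fps)

#' @rdname accessors
#' @export
setMethod("signalValues", "HeightSignal", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("signalStage", "HeightSignal", function(object) object@stage)

#' @rdname accessors
#' @export
setMethod("nFrames", "DetectionSeries", function(object) nrow(object@frames))

#' @rdname accessors
#' @export
setMethod("nFrames", "HeightSignal", function(object) length(object@values))

setMethod("show", "DetectionSeries", function(object) {
    fr <- object@frames
    cat("DetectionSeries:", object@recordingID, "\n")
    cat(sprintf("  %d frames at %.5g fps (%.2f s)\n", nrow(fr), object@fps,
                nrow(fr) / object@fps))
    cat(sprintf("  person detected in %d frames, face in %d\n",
                sum(!is.na(fr$person_h)), sum(!is.na(fr$face_h))))
    invisible(NULL)
})

setMethod("show", "HeightSignal", function(object) {
    v <- object@values
    cat(sprintf("HeightSignal: %s [stage %s]\n", object@recordingID,
                object@stage))
    cat(sprintf("  %d frames at %.5g fps; range [%.4g, %.4g]\n",
                length(v), object@fps,
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
    invisible(NULL)
})

setMethod("show", "WalkSegments", function(object) {
    cat(sprintf("WalkSegments: split at frame %d (%.2f s)\n",
                object@splitIndex, object@splitIndex / object@forward@fps))
    cat(sprintf("  forward %d frames, backward %d frames\n",
                length(object@forward@values), length(object@backward@values)))
    invisible(NULL)
})

setMethod("show", "GaitEvents", function(object) {
    cat(sprintf("GaitEvents: %d events on the %s segment\n",
                length(object@timestamps), object@sourceSegment))
    if (length(object@timestamps))
        cat("  t =", paste(sprintf("%.2f", utils::head(object@timestamps, 8L)),
                           collapse = " "),
            if (length(object@timestamps) > 8L) "..." else "", "\n")
    invisible(NULL)
})

setMethod("show", "StridePhases", function(object) {
    cat(sprintf("StridePhases: %d strides\n", length(object@stride)))
    if (length(object@stride))
        cat(sprintf("  mean stance %.3f s, swing %.3f s, stride %.3f s\n",
                    mean(object@stance), mean(object@swing),
                    mean(object@stride)))
    invisible(NULL)
})

setMethod("show", "GaitProfile", function(object) {
    cat(sprintf("GaitProfile: UPDRS-gait level %d\n", object@label))
    cat(sprintf("  cadence %.2f strides/s, step %.1f px, forward %.1f s, turn dwell %.1f s\n",
                object@cadence, object@stepAmplitude, object@forwardDuration,
                object@turnDwell))
    cat(sprintf("  jitter (amp %.2f, cad %.2f), festination %.2f, noise sd %.1f px\n",
                object@amplitudeJitter, object@cadenceJitter,
                object@festinationRate, object@noiseSd))
    invisible(NULL)
})

setMethod("show", "SyntheticWalk", function(object) {
    cat(sprintf("SyntheticWalk: %s (label %d, seed %d)\n",
                object@series@recordingID, object@profile@label, object@seed))
    cat(sprintf("  %d frames, %d ground-truth events, turn at frame %d\n",
                nrow(object@series@frames), length(object@truthEvents),
                object@truthSplitIndex))
    invisible(NULL)
})

setMethod("show", "PukSVM", function(object) {
    cat("PukSVM one-vs-all severity model\n")
    cat(sprintf("  classes %s; PUK omega %.3g, sigma %.3g; C %.3g\n",
                paste(object@classes, collapse = "/"), object@omega,
                object@sigma, object@cost))
    cat(sprintf("  trained on %d samples x %d features\n",
                nrow(object@trainX), ncol(object@trainX)))
    invisible(NULL)
})

setMethod("show", "GaitEvalReport", function(object) {
    cat("GaitEvalReport\n")
    cat(sprintf("  %d folds, averaged accuracy %.4f\n",
                length(object@foldAccuracy), mean(object@foldAccuracy)))
    cat(sprintf("  per-class TPR: %s\n",
                paste(sprintf("%.3f", object@tpr), collapse = " ")))
    cat(sprintf("  per-class AUC: %s (macro %.4f)\n",
                paste(sprintf("%.3f", object@auc), collapse = " "),
                object@macroAUC))
    cat("  pooled confusion matrix (rows = true):\n")
    print(object@confusion)
    invisible(NULL)
})
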