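#' Run the full signal pipeline and feature extraction on one recording
#'
#' Chains the per-recording steps: gap filling, face-height scaling,
#' min-max normalization, moving-average smoothing, partition
#' quantization, forward/backward split, and the five-feature
#' extraction.
#'
#' @param series a \code{\linkS4class{DetectionSeries}}.
#' @param config a \code{\link{gaitConfig}}.
#' @param label optional UPDRS-gait label for the output row.
#' @return A one-row feature \code{data.frame} (see
#'   \code{\link{extractFeatures}}).
#' @examples
#' w <- simulateWalk(gaitProfile(0), seed = 3)
#' computeGaitFeatures(w@series)
#' @export
computeGaitFeatures <- function(series, config = gaitConfig(),
                                label = NA_integer_) {
    stopifnot(is(series, "DetectionSeries"))
    scaled <- scaleByFaceHeight(fillGaps(series), fhPolicy = config$fhPolicy,
                                fh = if (config$fhPolicy == "constant")
                                    config$constantFh else NULL)
    normalized <- minmaxNormalize(scaled)
    quantized <- lloydQuantize(movingAverage(normalized,
                                             config$smoothingWindow),
                               config$partitionSize)
    segments <- suppressWarnings(splitWalks(quantized))
    extractFeatures(segments, normalized, config = config,
                    recordingID = series@recordingID, label = label)
}

#' Track a recording and write its detection CSV
#'
#' Thin wrapper over \code{\link{trackVideo}} +
#' \code{\link{writeDetections}} used by the command-line \code{track}
#' subcommand.
#'
#' @param videoPath TIFF frame stack or directory of frames.
#' @param outPath output detection CSV.
#' @param config a \code{\link{gaitConfig}} (supplies fps).
#' @return The written path, invisibly.
#' @export
runTrack <- function(videoPath, outPath, config = gaitConfig()) {
    series <- trackVideo(videoPath, fps = config$fps)
    writeDetections(series, outPath)
    message(sprintf("tracked %s: %d frames -> %s", videoPath,
                    nFrames(series), outPath))
    invisible(outPath)
}

#' Extract features for a batch of detection CSVs
#'
#' Applies the signal pipeline and feature extraction to every detection
#' CSV, joins labels by recording id when a label table is given, and
#' writes the feature CSV. Recordings that fail a pipeline stage or
#' yield an incomplete feature vector are excluded with a warning count;
#' a failure never aborts the batch.
#'
#' @param detectionPaths character vector of detection CSV paths.
#' @param outPath output feature CSV.
#' @param labels optional label \code{data.frame} or label CSV path
#'   (columns \code{recording_id}, \code{label}).
#' @param config a \code{\link{gaitConfig}}.
#' @return The feature table of the retained recordings, invisibly.
#' @export
runFeatures <- function(detectionPaths, outPath, labels = NULL,
                        config = gaitConfig()) {
    if (!length(detectionPaths))
        stop("no detection files given", call. = FALSE)
    if (is.character(labels)) labels <- readLabels(labels)
    rows <- lapply(detectionPaths, function(p) {
        tryCatch({
            series <- readDetections(p)
            lab <- NA_integer_
            if (!is.null(labels)) {
                hit <- match(series@recordingID, labels$recording_id)
                if (!is.na(hit)) lab <- labels$label[hit]
            }
            computeGaitFeatures(series, config = config, label = lab)
        }, error = function(e) {
            data.frame(recording_id = basename(p), S_avg = NA_real_,
                       alpha = NA_real_, E = NA_real_,
                       A_delta_C = NA_real_, T = NA_real_,
                       label = NA_integer_,
                       flags = conditionMessage(e),
                       stringsAsFactors = FALSE)
        })
    })
    tab <- do.call(rbind, rows)
    incomplete <- apply(is.na(tab[, .FEATURE_COLS]), 1L, any)
    if (any(incomplete))
        message(sprintf("excluded %d incomplete recording(s): %s",
                        sum(incomplete),
                        paste(tab$recording_id[incomplete], collapse = ", ")))
    kept <- tab[!incomplete, , drop = FALSE]
    rownames(kept) <- NULL
    writeFeatureTable(kept, outPath)
    invisible(kept)
}

#' Rank-test the features across severity levels
#'
#' Wraps \code{\link{rankFeatures}} and writes its result as JSON.
#'
#' @param features feature table or feature CSV path.
#' @param outPath output JSON path.
#' @return The rank-test \code{data.frame}, invisibly.
#' @export
runAnalyze <- function(features, outPath) {
    if (is.character(features)) features <- readFeatureTable(features)
    res <- rankFeatures(features)
    jsonlite::write_json(res, outPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(res)
}

#' Train a severity model from a feature table
#'
#' @param features feature table or feature CSV path with labels.
#' @param modelPath output model file.
#' @param config a \code{\link{gaitConfig}} (supplies omega, sigma, C).
#' @return The trained \code{\linkS4class{PukSVM}}, invisibly.
#' @export
runTrainModel <- function(features, modelPath, config = gaitConfig()) {
    if (is.character(features)) features <- readFeatureTable(features)
    model <- trainSeverityModel(features, omega = config$omega,
                                sigma = config$sigma, C = config$C)
    writeSeverityModel(model, modelPath)
    invisible(model)
}

#' Cross-validate a feature table and write the evaluation report
#'
#' Wraps \code{\link{crossValidate}} (and optionally
#' \code{\link{rankFeatures}}); the seed is recorded in the report so a
#' run is reproducible from its outputs.
#'
#' @param features feature table or feature CSV path with labels.
#' @param outPath output report JSON.
#' @param rankPath optional output JSON for the rank test.
#' @param config a \code{\link{gaitConfig}}.
#' @return The \code{\linkS4class{GaitEvalReport}}, invisibly.
#' @export
runEvaluate <- function(features, outPath, rankPath = NULL,
                        config = gaitConfig()) {
    if (is.character(features)) features <- readFeatureTable(features)
    if (is.null(features$label) || all(is.na(features$label)))
        stop("feature table has no labels; cannot evaluate", call. = FALSE)
    report <- crossValidate(features, omega = config$omega,
                            sigma = config$sigma, C = config$C,
                            folds = config$folds, seed = config$seed)
    writeEvalReport(report, outPath)
    if (!is.null(rankPath)) runAnalyze(features, rankPath)
    message(sprintf("averaged accuracy %.4f, macro AUC %.4f -> %s",
                    mean(report@foldAccuracy), report@macroAUC, outPath))
    invisible(report)
}

#' Simulate a dataset and write it in the pipeline's file dialects
#'
#' Generates a balanced synthetic dataset, writes one detection CSV per
#' walk plus a \code{labels.csv}, and optionally renders each walk as a
#' silhouette TIFF stack.
#'
#' @param nPerClass walks per severity level.
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{gaitConfig}} (supplies fps and seed).
#' @param render also render silhouette frame stacks (slower).
#' @return The label \code{data.frame}, invisibly.
#' @export
runSimulate <- function(nPerClass, outDir, config = gaitConfig(),
                        render = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ds <- simulateGaitDataset(nPerClass, fps = config$fps,
                              seed = config$seed)
    for (w in ds$walks) {
        id <- w@series@recordingID
        writeDetections(w@series, file.path(outDir, paste0(id, ".csv")))
        if (render)
            renderWalkVideo(w, file.path(outDir, paste0(id, ".tif")))
    }
    writeLabels(ds$labels, file.path(outDir, "labels.csv"))
    writeGaitConfig(config, file.path(outDir, "config.txt"))
    message(sprintf("simulated %d walks (%d per class) -> %s",
                    nrow(ds$labels), nPerClass, outDir))
    invisible(ds$labels)
}
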