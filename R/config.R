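#' Pipeline configuration
#'
#' Collects every tunable of the tracking, signal, feature and
#' classification stages with the standard defaults: 25 fps source video,
#' 5-frame smoothing window and 5-frame quantization partitions (0.2 s at
#' 25 fps), 5-sample boxes for both the fluctuation analysis and the
#' spectral centroids, PUK kernel shape omega = 0.2 / sigma = 1.0, C = 1,
#' and stratified 10-fold cross-validation.
#'
#' @param fps frames per second of the source recordings.
#' @param smoothingWindow odd moving-average window, frames.
#' @param partitionSize quantization partition, frames.
#' @param boxSizeL base box size for detrended fluctuation analysis.
#' @param boxN box size for spectral centroids.
#' @param fhPolicy face-height policy: \code{"frame"}, \code{"median"} or
#'   \code{"constant"} (see \code{\link{scaleByFaceHeight}}).
#' @param constantFh face height in pixels when \code{fhPolicy =
#'   "constant"}.
#' @param featureSegment compute the signal-shape features (alpha, E,
#'   A-delta-C, T) on the \code{"full"} walk (default) or the
#'   \code{"forward"} walk only.
#' @param absCentroidDiff if \code{TRUE}, centroid variability uses mean
#'   absolute consecutive differences instead of the signed mean.
#' @param minRise smallest plateau-to-plateau rise (in units of the
#'   normalized height range) accepted as a gait event; smaller rises are
#'   treated as residual detection jitter. \code{NA} (the default) lets
#'   \code{\link{detectEvents}} estimate the noise floor per recording.
#' @param omega,sigma PUK kernel tailing factor and half-width.
#' @param C soft-margin regularization constant.
#' @param folds number of cross-validation folds.
#' @param seed integer seed driving every randomized step.
#' @return A \code{GaitConfig} (validated named list).
#' @examples
#' gaitConfig()
#' gaitConfig(fhPolicy = "median", folds = 5)
#' @export
gaitConfig <- function(fps = 25, smoothingWindow = 5L, partitionSize = 5L,
                       boxSizeL = 5L, boxN = 5L,
                       fhPolicy = c("frame", "median", "constant"),
                       constantFh = NA_real_,
                       featureSegment = c("full", "forward"),
                       absCentroidDiff = FALSE, minRise = NA_real_,
                       omega = 0.2, sigma = 1.0, C = 1.0, folds = 10L,
                       seed = 1L) {
    cfg <- list(fps = as.numeric(fps),
                smoothingWindow = as.integer(smoothingWindow),
                partitionSize = as.integer(partitionSize),
                boxSizeL = as.integer(boxSizeL),
                boxN = as.integer(boxN),
                fhPolicy = match.arg(fhPolicy),
                constantFh = as.numeric(constantFh),
                featureSegment = match.arg(featureSegment),
                absCentroidDiff = isTRUE(absCentroidDiff),
                minRise = as.numeric(minRise),
                omega = as.numeric(omega), sigma = as.numeric(sigma),
                C = as.numeric(C), folds = as.integer(folds),
                seed = as.integer(seed))
    for (nm in c("fps", "smoothingWindow", "partitionSize", "boxSizeL",
                 "boxN", "omega", "sigma", "C", "folds"))
        if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
            stop(sprintf("config '%s' must be positive", nm), call. = FALSE)
    if (cfg$smoothingWindow %% 2L == 0L)
        stop("smoothingWindow must be odd", call. = FALSE)
    if (!is.na(cfg$minRise) && (!is.finite(cfg$minRise) || cfg$minRise < 0))
        stop("minRise must be non-negative or NA for adaptive",
             call. = FALSE)
    if (cfg$fhPolicy == "constant" &&
        (!is.finite(cfg$constantFh) || cfg$constantFh <= 0))
        stop("fhPolicy 'constant' requires a positive constantFh",
             call. = FALSE)
    structure(cfg, class = "GaitConfig")
}

#' @export
print.GaitConfig <- function(x, ...) {
    cat("GaitConfig\n")
    for (nm in names(x))
        cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
    invisible(x)
}

#' Read / write a pipeline configuration
#'
#' Flat \code{key = value} text format so that every run can drop its
#' resolved configuration next to its outputs and be reproduced from it.
#'
#' @param config a \code{GaitConfig}.
#' @param path file path.
#' @return \code{readGaitConfig}: a \code{GaitConfig};
#'   \code{writeGaitConfig}: the path, invisibly.
#' @export
writeGaitConfig <- function(config, path) {
    stopifnot(inherits(config, "GaitConfig"))
    lines <- vapply(names(config), function(nm) {
        v <- config[[nm]]
        sprintf("%s = %s", nm,
                if (is.numeric(v)) format(v, digits = 17) else as.character(v))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGaitConfig
#' @export
readGaitConfig <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    keys <- vapply(kv, function(p) trimws(p[[1]]), character(1))
    vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = "=")),
                   character(1))
    args <- stats::setNames(as.list(vals), keys)
    defaults <- formals(gaitConfig)
    for (nm in names(args)) {
        if (!nm %in% names(defaults))
            stop(sprintf("unknown config key '%s'", nm), call. = FALSE)
        if (nm %in% c("fhPolicy", "featureSegment")) next
        if (nm == "absCentroidDiff") args[[nm]] <- as.logical(args[[nm]])
        else args[[nm]] <- if (identical(args[[nm]], "NA")) NA_real_
                           else as.numeric(args[[nm]])
    }
    do.call(gaitConfig, args)
}
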