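.fmtNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
    }, character(1))
    out
}

.parseNum <- function(x) {
    x[!nzchar(x)] <- NA_character_
    as.numeric(x)
}

#' Read / write a detection CSV
#'
#' Plain-text dialect for per-frame detections: comment lines
#' \code{# recording_id=...} and \code{# fps=...}, a header
#' \code{frame,person_h,person_w,face_h}, and one row per frame with
#' missing detections as empty fields. Numbers are written with 17
#' significant digits so a write/read cycle reproduces the series
#' exactly.
#'
#' @param series a \code{\linkS4class{DetectionSeries}}.
#' @param path file path.
#' @return \code{readDetections}: a \code{DetectionSeries};
#'   \code{writeDetections}: the path, invisibly.
#' @export
writeDetections <- function(series, path) {
    stopifnot(is(series, "DetectionSeries"))
    fr <- series@frames
    lines <- c(sprintf("# recording_id=%s", series@recordingID),
               sprintf("# fps=%s", formatC(series@fps, digits = 17,
                                           format = "g")),
               "frame,person_h,person_w,face_h",
               paste(fr$frame, .fmtNum(fr$person_h), .fmtNum(fr$person_w),
                     .fmtNum(fr$face_h), sep = ","))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
    if (!file.exists(path))
        stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
    lines <- readLines(path)
    meta <- grep("^#", lines, value = TRUE)
    getMeta <- function(key, default = NA_character_) {
        hit <- grep(sprintf("^#\\s*%s=", key), meta, value = TRUE)
        if (!length(hit)) return(default)
        sub(sprintf("^#\\s*%s=", key), "", hit[1L])
    }
    recID <- getMeta("recording_id", "recording")
    fpsVal <- as.numeric(getMeta("fps", "25"))
    body <- lines[!grepl("^#", lines)]
    if (!length(body) || body[1L] != "frame,person_h,person_w,face_h")
        stop("not a detection CSV: bad or missing header", call. = FALSE)
    body <- body[-1L]
    parts <- strsplit(body, ",", fixed = TRUE)
    getCol <- function(i) vapply(parts, function(p) {
        if (length(p) >= i) p[i] else ""
    }, character(1))
    detectionSeries(recID,
        data.frame(frame = as.integer(getCol(1L)),
                   person_h = .parseNum(getCol(2L)),
                   person_w = .parseNum(getCol(3L)),
                   face_h = .parseNum(getCol(4L))),
        fps = fpsVal)
}

#' Read / write a feature table CSV
#'
#' Columns \code{recording_id,S_avg,alpha,E,A_delta_C,T,label,flags};
#' numerics at 17 significant digits, missing values as empty fields.
#'
#' @param features feature table (see \code{\link{extractFeatures}}).
#' @param path file path.
#' @return \code{readFeatureTable}: a \code{data.frame};
#'   \code{writeFeatureTable}: the path, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
    cols <- c("recording_id", .FEATURE_COLS, "label", "flags")
    for (nm in setdiff(cols, names(features)))
        features[[nm]] <- if (nm == "flags") "" else NA
    lines <- c(paste(cols, collapse = ","),
               vapply(seq_len(nrow(features)), function(i) {
                   paste(c(features$recording_id[i],
                           .fmtNum(unlist(features[i, .FEATURE_COLS])),
                           ifelse(is.na(features$label[i]), "",
                                  as.character(features$label[i])),
                           gsub(",", ";", features$flags[i])),
                         collapse = ",")
               }, character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(recording_id = "character",
                                         flags = "character"))
    need <- c("recording_id", .FEATURE_COLS, "label")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("feature CSV lacks columns: %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
    for (nm in .FEATURE_COLS) df[[nm]] <- as.numeric(df[[nm]])
    df$label <- as.integer(df$label)
    if (is.null(df$flags)) df$flags <- ""
    df$flags[is.na(df$flags)] <- ""
    df
}

#' Read / write a label CSV
#'
#' Columns \code{recording_id,label} (and optionally \code{seed}, logged
#' by the simulator).
#'
#' @param labels \code{data.frame} with \code{recording_id} and
#'   \code{label}.
#' @param path file path.
#' @return \code{readLabels}: a \code{data.frame}; \code{writeLabels}:
#'   the path, invisibly.
#' @export
writeLabels <- function(labels, path) {
    utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(recording_id = "character"))
    if (!all(c("recording_id", "label") %in% names(df)))
        stop("label CSV needs recording_id and label columns",
             call. = FALSE)
    df$label <- as.integer(df$label)
    df
}

#' Read / write an evaluation report
#'
#' JSON serialization of a \code{\linkS4class{GaitEvalReport}}: fold
#' accuracies, pooled confusion matrix, per-class TPR, per-class
#' ROC point arrays and AUCs, macro AUC, fold assignment and seed.
#'
#' @param report a \code{GaitEvalReport}.
#' @param path file path.
#' @return \code{readEvalReport}: a \code{GaitEvalReport};
#'   \code{writeEvalReport}: the path, invisibly.
#' @export
writeEvalReport <- function(report, path) {
    stopifnot(is(report, "GaitEvalReport"))
    obj <- list(fold_accuracy = report@foldAccuracy,
                averaged_accuracy = mean(report@foldAccuracy),
                confusion = unname(apply(report@confusion, 1L, as.numeric,
                                         simplify = FALSE)),
                tpr = report@tpr,
                auc = report@auc,
                macro_auc = report@macroAUC,
                roc = lapply(report@roc, function(r)
                    list(fpr = r$fpr, tpr = r$tpr)),
                folds = report@folds,
                seed = report@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    cm <- if (is.matrix(obj$confusion)) obj$confusion
          else do.call(rbind, lapply(obj$confusion, as.numeric))
    storage.mode(cm) <- "double"
    dimnames(cm) <- list(0:(nrow(cm) - 1L), 0:(ncol(cm) - 1L))
    rocs <- lapply(seq_len(nrow(cm)), function(i)
        data.frame(fpr = as.numeric(obj$roc[[i]]$fpr),
                   tpr = as.numeric(obj$roc[[i]]$tpr)))
    new("GaitEvalReport", foldAccuracy = as.numeric(obj$fold_accuracy),
        confusion = cm, tpr = as.numeric(obj$tpr),
        auc = as.numeric(obj$auc), macroAUC = as.numeric(obj$macro_auc),
        roc = rocs, folds = as.integer(obj$folds),
        seed = as.integer(obj$seed))
}
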