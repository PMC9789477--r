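#' Silhouette-based person detector
#'
#' Builds a deterministic detector for footage where the walking subject
#' is darker than the background (rendered silhouette stacks,
#' background-subtracted clips): pixels below \code{threshold} are
#' foreground, connected components are labeled, and each sufficiently
#' large component yields one bounding box. The returned closure has the
#' detector interface used throughout the package — \code{function(img)}
#' returning a \code{data.frame} with columns \code{x}, \code{y} (1-based
#' top-left), \code{w}, \code{h} (pixels), zero rows when nothing is
#' found — so any pretrained pedestrian detector can be plugged in behind
#' the same interface.
#'
#' @param threshold intensity below which a pixel is foreground (images
#'   are scaled to [0, 1]).
#' @param minArea smallest component (pixels) reported as a detection.
#' @return A detector function.
#' @export
thresholdPersonDetector <- function(threshold = 0.5, minArea = 50L) {
    force(threshold); force(minArea)
    function(img) {
        img <- .asGrayMatrix(img)
        fg <- img < threshold
        if (!any(fg))
            return(data.frame(x = integer(0), y = integer(0),
                              w = integer(0), h = integer(0)))
        lab <- EBImage::bwlabel(fg)
        labs <- sort(unique(as.vector(lab)))
        labs <- labs[labs > 0]
        boxes <- lapply(labs, function(l) {
            idx <- which(lab == l, arr.ind = TRUE)
            if (nrow(idx) < minArea) return(NULL)
            data.frame(x = min(idx[, 1L]), y = min(idx[, 2L]),
                       w = diff(range(idx[, 1L])) + 1L,
                       h = diff(range(idx[, 2L])) + 1L)
        })
        boxes <- boxes[!vapply(boxes, is.null, logical(1))]
        if (!length(boxes))
            return(data.frame(x = integer(0), y = integer(0),
                              w = integer(0), h = integer(0)))
        do.call(rbind, boxes)
    }
}

#' Head-block face detector
#'
#' Estimates the face height from the silhouette's shape: within the
#' tallest detected component, foreground rows are scanned from the top
#' and the contiguous run that is markedly narrower than the widest body
#' row (the head above the shoulders) gives the face height. Returns
#' \code{NA} when no silhouette is present or the top of the silhouette
#' is not narrower than the body (occluded or missing head).
#'
#' @param threshold foreground intensity threshold.
#' @param widthRatio a top row belongs to the head while its foreground
#'   width is below this fraction of the maximal body width.
#' @return A detector \code{function(img)} returning a face height in
#'   pixels or \code{NA}.
#' @export
thresholdFaceDetector <- function(threshold = 0.5, widthRatio = 0.7) {
    personDet <- thresholdPersonDetector(threshold)
    force(widthRatio)
    function(img) {
        img <- .asGrayMatrix(img)
        box <- .tallestBox(personDet(img))
        if (is.null(box)) return(NA_real_)
        sub <- img[box$x:(box$x + box$w - 1L),
                   box$y:(box$y + box$h - 1L), drop = FALSE] < threshold
        rowWidth <- colSums(sub)          # foreground width per image row
        maxW <- max(rowWidth)
        if (maxW == 0) return(NA_real_)
        head <- rowWidth < widthRatio * maxW & rowWidth > 0
        if (!head[1L]) return(NA_real_)   # top of silhouette not narrower
        fh <- which(!head)[1L] - 1L
        if (is.na(fh)) fh <- length(head) # never widens: treat all as head
        if (fh <= 0L || fh >= box$h) return(NA_real_)
        as.numeric(fh)
    }
}

.asGrayMatrix <- function(img) {
    if (is(img, "Image")) {
        if (EBImage::colorMode(img) != EBImage::Grayscale)
            img <- EBImage::channel(img, "gray")
        img <- EBImage::imageData(img)
    }
    if (!is.numeric(img) || length(dim(img)) < 2L || !length(img))
        stop("malformed image: need a non-empty numeric matrix",
             call. = FALSE)
    if (length(dim(img)) == 3L) {
        if (dim(img)[3L] == 1L) img <- img[, , 1L]
        else img <- apply(img, c(1L, 2L), mean)   # collapse color channels
    }
    img
}

.tallestBox <- function(boxes) {
    if (is.null(boxes) || !nrow(boxes)) return(NULL)
    boxes[which.max(boxes$h), , drop = FALSE]
}

#' Detect the walking subject in one frame
#'
#' Runs the person detector and keeps the tallest box — in a clinical
#' gait recording a single subject walks toward the camera and dominates
#' the frame, so smaller detections are clutter.
#'
#' @param img image matrix, array or \code{EBImage::Image}.
#' @param detector a person detector (see
#'   \code{\link{thresholdPersonDetector}}).
#' @return Named numeric \code{c(x, y, w, h)} or \code{NULL} when nothing
#'   is detected.
#' @export
detectPerson <- function(img, detector = thresholdPersonDetector()) {
    box <- .tallestBox(detector(img))
    if (is.null(box)) return(NULL)
    c(x = box$x, y = box$y, w = box$w, h = box$h)
}

#' Detect the subject's face height in one frame
#'
#' @param img image matrix, array or \code{EBImage::Image}.
#' @param detector a face detector (see
#'   \code{\link{thresholdFaceDetector}}).
#' @return Face height in pixels, or \code{NA} when no face is found.
#' @export
detectFace <- function(img, detector = thresholdFaceDetector()) {
    as.numeric(detector(img))
}

.readFrames <- function(videoPath) {
    if (dir.exists(videoPath)) {
        files <- sort(list.files(videoPath, full.names = TRUE,
                                 pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
                                 ignore.case = TRUE))
        if (!length(files))
            stop(sprintf("no image frames found in '%s'", videoPath),
                 call. = FALSE)
        return(lapply(files, function(f) .asGrayMatrix(EBImage::readImage(f))))
    }
    if (!file.exists(videoPath))
        stop(sprintf("cannot read video '%s': no such file", videoPath),
             call. = FALSE)
    img <- EBImage::readImage(videoPath)
    if (EBImage::colorMode(img) != EBImage::Grayscale)
        img <- EBImage::channel(img, "gray")
    dat <- EBImage::imageData(img)
    if (length(dim(dat)) == 2L) return(list(dat))
    lapply(seq_len(dim(dat)[3L]), function(i) dat[, , i])
}

#' Track a walking subject through a frame stack
#'
#' Decodes every frame of a multi-frame TIFF stack (or a directory of
#' numbered image frames), runs the person and face detectors on each,
#' and assembles the per-frame detections into a
#' \code{\linkS4class{DetectionSeries}}. Frames without a detection are
#' recorded as missing — gap filling is left to \code{\link{fillGaps}}.
#' Detection is deterministic: the same file always yields the same
#' series.
#'
#' @param videoPath path to a TIFF frame stack or a directory of frames.
#' @param fps frames per second of the recording; frame stacks carry no
#'   rate metadata, so this defaults to the usual 25.
#' @param personDetector,faceDetector detector functions (see
#'   \code{\link{thresholdPersonDetector}},
#'   \code{\link{thresholdFaceDetector}}).
#' @param recordingID recording name; defaults to the file name.
#' @return A \code{\linkS4class{DetectionSeries}} with one row per frame.
#' @export
trackVideo <- function(videoPath, fps = 25,
                       personDetector = thresholdPersonDetector(),
                       faceDetector = thresholdFaceDetector(),
                       recordingID = NULL) {
    frames <- .readFrames(videoPath)
    if (is.null(recordingID))
        recordingID <- sub("\\.[^.]+$", "", basename(videoPath))
    n <- length(frames)
    ph <- pw <- fh <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        box <- detectPerson(frames[[i]], personDetector)
        if (!is.null(box)) {
            ph[i] <- box[["h"]]
            pw[i] <- box[["w"]]
            fh[i] <- detectFace(frames[[i]], faceDetector)
        }
    }
    if (!any(!is.na(ph)))
        stop("empty track: no person detected in any frame", call. = FALSE)
    detectionSeries(recordingID,
                    data.frame(frame = 0:(n - 1L), person_h = ph,
                               person_w = pw, face_h = fh),
                    fps = fps)
}
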