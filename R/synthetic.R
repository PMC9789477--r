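#' Class-conditional gait profile
#'
#' Returns the simulator parameters for one UPDRS-gait level, individually
#' overridable. The defaults encode the qualitative contrasts seen in
#' clinical front-view walks:
#' \itemize{
#'   \item level 0 (healthy): brisk cadence, large height steps, little
#'     irregularity, short turn, shortest completion time;
#'   \item level 1 (mild): slower, smaller and more irregular steps
#'     (shuffling), longer turn and walk;
#'   \item level 2 (moderate): smallest steps, festination bursts, most
#'     irregularity, longest turn and walk.
#' }
#' No quantitative clinical values are published for these signals; the
#' numbers below are the package's chosen study conditions.
#'
#' @param label UPDRS-gait level 0, 1 or 2.
#' @param ... named overrides for any \code{\linkS4class{GaitProfile}}
#'   slot (e.g. \code{cadence}, \code{noiseSd}).
#' @return A \code{\linkS4class{GaitProfile}}.
#' @examples
#' gaitProfile(0)
#' gaitProfile(2, noiseSd = 0)
#' @export
gaitProfile <- function(label, ...) {
    label <- as.integer(label)
    if (!label %in% 0:2) stop("label must be 0, 1 or 2", call. = FALSE)
    defaults <- switch(as.character(label),
        "0" = list(cadence = 1.1, stepAmplitude = 8, amplitudeJitter = 0.05,
                   cadenceJitter = 0.05, festinationRate = 0,
                   turnDwell = 0.8, forwardDuration = 7, noiseSd = 1.0),
        "1" = list(cadence = 0.8, stepAmplitude = 5, amplitudeJitter = 0.15,
                   cadenceJitter = 0.15, festinationRate = 0,
                   turnDwell = 1.5, forwardDuration = 10, noiseSd = 1.5),
        "2" = list(cadence = 0.65, stepAmplitude = 3, amplitudeJitter = 0.25,
                   cadenceJitter = 0.25, festinationRate = 0.35,
                   turnDwell = 2.5, forwardDuration = 13, noiseSd = 2.0))
    args <- c(list(label = label), defaults,
              list(subjectHeightPx = 250, faceRatio = 0.13))
    dots <- list(...)
    bad <- setdiff(names(dots), c(names(defaults), "subjectHeightPx",
                                  "faceRatio"))
    if (length(bad))
        stop(sprintf("unknown profile fields: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
    args[names(dots)] <- dots
    do.call(new, c(list("GaitProfile"), args))
}

# Event schedule of one forward walk: two rises per stride at half-stride
# intervals; a festinating stride is replaced by 3 quick small rises.
.forwardEvents <- function(profile) {
    dt <- 1 / (2 * profile@cadence)
    times <- numeric(0)
    rises <- numeric(0)
    t <- dt
    while (t < profile@forwardDuration) {
        festinate <- profile@festinationRate > 0 &&
            stats::runif(1) < profile@festinationRate
        nEv <- if (festinate) 3L else 2L
        shrink <- if (festinate) 0.45 else 1
        for (e in seq_len(nEv)) {
            gap <- dt * shrink *
                max(0.2, 1 + profile@cadenceJitter * stats::rnorm(1))
            rise <- profile@stepAmplitude * shrink *
                max(0.2, 1 + profile@amplitudeJitter * stats::rnorm(1))
            if (t >= profile@forwardDuration) break
            times <- c(times, t)
            rises <- c(rises, rise)
            t <- t + gap
        }
    }
    list(times = times, rises = rises)
}

#' Simulate the height signal of one walk
#'
#' Builds the plateau-and-rise staircase a front-view camera sees: the
#' silhouette height steps up at each gait event during the forward walk,
#' dwells at its maximum while the subject turns, and descends as the
#' mirror image of the approach. Event intervals and rise sizes are
#' jittered per the profile, festination replaces strides by bursts of
#' quick small rises, and Gaussian pixel noise is added to the detected
#' height. The face height is the anthropometric fraction of the subject's
#' height with proportionally scaled noise. Fully deterministic given
#' (profile, fps, seed).
#'
#' @param profile a \code{\linkS4class{GaitProfile}}.
#' @param fps frames per second (default 25).
#' @param seed integer seed.
#' @return A \code{\linkS4class{SyntheticWalk}} whose detection series has
#'   one row per frame and whose ground truth records the forward-walk
#'   event times and the turn frame.
#' @examples
#' w <- simulateWalk(gaitProfile(0), seed = 7)
#' w
#' @export
simulateWalk <- function(profile, fps = 25, seed = 1L) {
    stopifnot(is(profile, "GaitProfile"))
    validObject(profile)
    seed <- as.integer(seed)
    .withSeed(seed, {
        ev <- .forwardEvents(profile)
        totalRise <- sum(ev$rises)
        h0 <- profile@subjectHeightPx - totalRise
        if (h0 <= 10)
            stop("step amplitude too large: staircase exceeds the subject height",
                 call. = FALSE)
        nFwd <- floor(profile@forwardDuration * fps) + 1L
        tFwd <- (seq_len(nFwd) - 1L) / fps
        fwd <- h0 + vapply(tFwd,
                           function(t) sum(ev$rises[ev$times <= t]),
                           numeric(1))
        nDwell <- round(profile@turnDwell * fps)
        clean <- c(fwd, rep(max(fwd), nDwell), rev(fwd))
        n <- length(clean)
        turn <- which.max(fwd) - 1L                      # 0-based
        noisy <- clean + stats::rnorm(n, 0, profile@noiseSd)
        noisy <- pmax(noisy, 1)
        fh0 <- profile@faceRatio * profile@subjectHeightPx
        face <- fh0 + stats::rnorm(n, 0, profile@noiseSd * profile@faceRatio)
        face <- pmin(pmax(face, 1), noisy * 0.49)
        frames <- data.frame(frame = 0:(n - 1L), person_h = noisy,
                             person_w = 0.35 * noisy, face_h = face)
        series <- detectionSeries(sprintf("sim_L%d_s%d", profile@label, seed),
                                  frames, fps = fps)
        new("SyntheticWalk", series = series, truthEvents = ev$times,
            truthSplitIndex = as.integer(turn), profile = profile,
            seed = seed)
    })
}

#' Simulate a labeled, balanced dataset of walks
#'
#' Draws \code{nPerClass} walks per UPDRS-gait level. Each walk gets its
#' own seed from the master seed and a profile jittered around the class
#' defaults (cadence, step amplitude, durations varied by a few percent)
#' so that samples within a class differ, mirroring a balanced clinical
#' collection.
#'
#' @param nPerClass walks per class.
#' @param fps frames per second.
#' @param seed master seed; per-walk seeds are drawn from it and logged in
#'   the label table.
#' @return A list with \code{walks} (list of
#'   \code{\linkS4class{SyntheticWalk}}) and \code{labels} (a
#'   \code{data.frame} with \code{recording_id}, \code{label},
#'   \code{seed}).
#' @export
simulateGaitDataset <- function(nPerClass, fps = 25, seed = 1L) {
    nPerClass <- as.integer(nPerClass)
    if (nPerClass < 1L) stop("nPerClass must be at least 1", call. = FALSE)
    nWalks <- 3L * nPerClass
    plan <- .withSeed(as.integer(seed), {
        walkSeeds <- sample.int(.Machine$integer.max - 1L, nWalks)
        mult <- matrix(stats::runif(nWalks * 4L, 0.92, 1.08), ncol = 4L)
        list(walkSeeds = walkSeeds, mult = mult)
    })
    labels <- rep(0:2, each = nPerClass)
    walks <- vector("list", nWalks)
    ids <- character(nWalks)
    for (i in seq_len(nWalks)) {
        m <- plan$mult[i, ]
        base <- gaitProfile(labels[i])
        prof <- gaitProfile(labels[i],
            cadence = base@cadence * m[1L],
            stepAmplitude = base@stepAmplitude * m[2L],
            forwardDuration = base@forwardDuration * m[3L],
            turnDwell = base@turnDwell * m[4L])
        w <- simulateWalk(prof, fps = fps, seed = plan$walkSeeds[i])
        id <- sprintf("sim%03d_L%d", i, labels[i])
        w@series@recordingID <- id
        walks[[i]] <- w
        ids[i] <- id
    }
    list(walks = walks,
         labels = data.frame(recording_id = ids, label = labels,
                             seed = plan$walkSeeds,
                             stringsAsFactors = FALSE))
}

#' Noise with a power-law spectrum
#'
#' Generates a zero-mean, unit-variance series whose power spectral
#' density falls off as \eqn{f^{-slope}}, by spectrally shaping seeded
#' Gaussian white noise: \code{slope = 0} gives white noise (fluctuation
#' exponent about 0.5), \code{slope = 1} pink/1-over-f noise (about 1),
#' \code{slope = 2} Brownian-like noise (about 1.5). Used to validate the
#' detrended fluctuation analysis.
#'
#' @param n series length.
#' @param slope spectral exponent (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of length \code{n}.
#' @examples
#' x <- spectralNoise(2000, slope = 1, seed = 1)
#' @export
spectralNoise <- function(n, slope = 1, seed = 1L) {
    n <- as.integer(n)
    if (n < 8L) stop("n too small", call. = FALSE)
    if (slope < 0) stop("slope must be non-negative", call. = FALSE)
    .withSeed(as.integer(seed), {
        w <- stats::rnorm(n)
        W <- stats::fft(w)
        k <- c(0, seq_len(n - 1L))
        f <- pmin(k, n - k) / n      # absolute discrete frequency
        filt <- c(0, f[-1L]^(-slope / 2))
        x <- Re(stats::fft(W * filt, inverse = TRUE)) / n
        as.numeric(scale(x))
    })
}

.renderSpriteFrame <- function(h, faceRatio, width = 352L, height = 288L,
                               bg = 1, fg = 0.1) {
    h <- as.integer(round(h))
    img <- matrix(bg, nrow = width, ncol = height)   # EBImage x-y layout
    if (h < 4L) return(img)
    if (h + 8L > height)
        stop("sprite taller than frame", call. = FALSE)
    w <- max(4L, as.integer(round(0.35 * h)))
    bottom <- height - 4L
    top <- bottom - h + 1L
    cx <- width %/% 2L
    fh <- max(2L, as.integer(round(faceRatio * h)))
    torsoH <- as.integer(round(0.45 * h))
    headW <- max(2L, as.integer(round(0.45 * w)))
    cols <- function(wid) (cx - wid %/% 2L):(cx - wid %/% 2L + wid - 1L)
    # head block (narrow), torso block (full width), two leg columns
    img[cols(headW), top:(top + fh - 1L)] <- fg
    img[cols(w), (top + fh):(top + fh + torsoH - 1L)] <- fg
    legTop <- top + fh + torsoH
    legW <- max(1L, as.integer(round(0.28 * w)))
    left <- cx - w %/% 2L
    img[left:(left + legW - 1L), legTop:bottom] <- fg
    img[(left + w - legW):(left + w - 1L), legTop:bottom] <- fg
    img
}

#' Render a synthetic walk as a silhouette frame stack
#'
#' Draws, for every frame of the walk, a dark human-like sprite (narrow
#' head block, full-width torso, two legs) of the scripted pixel height,
#' horizontally centered on a light background, and writes the frames as
#' a multi-frame TIFF stack readable by \code{\link{trackVideo}}.
#' Rendering is deterministic given the walk.
#'
#' @param walk a \code{\linkS4class{SyntheticWalk}}.
#' @param path output file (\code{.tif}).
#' @param width,height frame size in pixels (default 352 x 288).
#' @return The path, invisibly.
#' @export
renderWalkVideo <- function(walk, path, width = 352L, height = 288L) {
    stopifnot(is(walk, "SyntheticWalk"))
    fr <- walk@series@frames
    arr <- array(1, dim = c(width, height, nrow(fr)))
    ratio <- walk@profile@faceRatio
    for (i in seq_len(nrow(fr)))
        arr[, , i] <- .renderSpriteFrame(fr$person_h[i], ratio,
                                         width = width, height = height)
    EBImage::writeImage(EBImage::Image(arr, colormode = "Grayscale"),
                        path, type = "tiff")
    invisible(path)
}
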