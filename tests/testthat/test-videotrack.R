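# Small frames keep the image tests fast; the sprite renderer is the
# package's own, so detector accuracy is judged against its geometry.

renderFrame <- function(h, faceRatio = 0.13, width = 160L, height = 200L) {
    FrontalGait:::.renderSpriteFrame(h, faceRatio, width = width,
                                     height = height)
}

test_that("a blank frame yields no person and no face", {
    blank <- matrix(1, 80, 100)
    expect_null(detectPerson(blank))
    expect_true(is.na(detectFace(blank)))
    expect_error(detectPerson("not an image"), "malformed")
})

test_that("the detector recovers the rendered sprite height and head size", {
    for (h in c(60, 100, 150)) {
        img <- renderFrame(h)
        box <- detectPerson(img)
        expect_false(is.null(box))
        expect_lt(abs(box[["h"]] - h) / h, 0.15)
        fh <- detectFace(img)
        expect_false(is.na(fh))
        expect_lt(abs(fh - 0.13 * h) / (0.13 * h), 0.25)
    }
})

test_that("with two subjects the taller box wins", {
    img <- matrix(1, 200, 180)
    img[10:40, 20:169] <- 0.1     # height 150
    img[120:150, 70:169] <- 0.1   # height 100
    box <- detectPerson(img)
    expect_equal(box[["h"]], 150)
})

test_that("an occluded face is reported absent, not guessed", {
    img <- matrix(1, 120, 160)
    img[30:80, 40:139] <- 0.1     # full-width block, no narrow head
    expect_true(is.na(detectFace(img)))
    expect_false(is.null(detectPerson(img)))
})

test_that("tracking a rendered stack recovers the scripted rise and fall", {
    w <- simulateWalk(gaitProfile(0, noiseSd = 0, forwardDuration = 2.5,
                                  turnDwell = 0.4, subjectHeightPx = 160),
                      seed = 6)
    path <- withr::local_tempfile(fileext = ".tif")
    renderWalkVideo(w, path, width = 200L, height = 200L)
    det <- trackVideo(path)
    expect_identical(nFrames(det), nrow(w@series@frames))
    got <- det@frames$person_h
    scripted <- w@series@frames$person_h
    expect_gt(cor(got, scripted), 0.95)
    # height rises to the turn then falls
    turn <- which.max(got)
    expect_lte(abs((turn - 1L) - w@truthSplitIndex), 2)
    expect_gt(got[turn], got[1])
    expect_gt(got[turn], got[length(got)])
    # determinism: re-tracking the same file reproduces the series
    det2 <- trackVideo(path)
    expect_identical(det@frames, det2@frames)
})

test_that("frames without a subject propagate as missing detections", {
    dirp <- withr::local_tempdir()
    for (i in 1:6) {
        img <- if (i %in% c(4, 5)) matrix(1, 120, 160)
               else renderFrame(90, width = 120L, height = 160L)
        EBImage::writeImage(EBImage::Image(img),
                            file.path(dirp, sprintf("f%02d.tif", i)),
                            type = "tiff")
    }
    det <- trackVideo(dirp)
    expect_identical(which(is.na(det@frames$person_h)), c(4L, 5L))
    # a static sprite gives a near-constant series
    ph <- det@frames$person_h[c(1:3, 6)]
    expect_lt(sd(ph) / mean(ph), 0.05)
    expect_error(trackVideo(file.path(dirp, "missing.tif")), "no such file")
})

test_that("an empty stack aborts with an empty-track error", {
    dirp <- withr::local_tempdir()
    for (i in 1:2)
        EBImage::writeImage(EBImage::Image(matrix(1, 60, 60)),
                            file.path(dirp, sprintf("f%d.tif", i)),
                            type = "tiff")
    expect_error(trackVideo(dirp), "empty track")
})
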