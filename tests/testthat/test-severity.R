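test_that("PUK kernel evaluates the Pearson VII form exactly", {
    expect_equal(pukKernel(c(1, 2, 3), c(1, 2, 3)), 1.0)
    # unit distance at the default shape: (1 + (2 sqrt(31))^2)^(-0.2)
    kUnit <- (1 + (2 * sqrt(2^(1 / 0.2) - 1))^2)^(-0.2)
    expect_equal(pukKernel(0, 1), kUnit, tolerance = 1e-12)
    expect_equal(round(kUnit, 4), 0.3807)
    set.seed(4)
    for (i in 1:10) {
        a <- rnorm(5); b <- rnorm(5)
        expect_equal(pukKernel(a, b), pukKernel(b, a))
        expect_gt(pukKernel(a, b), 0)
        expect_lte(pukKernel(a, b), 1)
    }
    expect_error(pukKernel(1:2, 1:3), "equal length")
    expect_error(pukKernel(1, 2, omega = -1), "positive")
})

test_that("PUK gram matrices are symmetric, unit-diagonal and PSD", {
    expect_equal(pukGram(matrix(2.5, 1, 1)), matrix(1, 1, 1))
    set.seed(9)
    X <- matrix(rnorm(100), 20, 5)
    X[7, ] <- X[3, ]                      # duplicated rows
    K <- pukGram(X)
    expect_equal(K, t(K))
    expect_equal(unname(diag(K)), rep(1, 20))
    expect_equal(K[3, 7], 1)
    for (n in c(10, 30, 50)) {
        Xr <- matrix(rnorm(n * 5), n, 5)
        ev <- eigen(pukGram(Xr), symmetric = TRUE, only.values = TRUE)$values
        expect_gte(min(ev), -1e-8)
    }
    expect_error(pukGram(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("one-vs-all training separates simulated classes and validates input", {
    feats <- makeFeatureTable(10, seed = 5)
    model <- trainSeverityModel(feats)
    pr <- predict(model, feats)
    expect_gte(mean(pr$class == feats$label), 0.95)
    expect_true(all(is.finite(pr$scores)))
    expect_identical(dim(pr$scores), c(nrow(feats), 3L))

    same <- feats; same$label <- 1L
    expect_error(trainSeverityModel(same), "at least 2")

    # contradictory duplicates train without error (soft margin)
    cols <- c("S_avg", "alpha", "E", "A_delta_C", "T")
    dup <- feats
    dup[1, cols] <- dup[2, cols]          # same x, labels differ
    expect_s4_class(trainSeverityModel(dup), "PukSVM")
})

test_that("prediction takes the maximal score with ties toward the lower class", {
    scores <- rbind(c(0.5, 0.5, -1), c(-1, 0.2, 0.2), c(0, 0, 0))
    expect_identical(FrontalGait:::.aggregateScores(scores),
                     c(0L, 1L, 0L))
})

test_that("standardization is fitted on the training split only", {
    feats <- makeFeatureTable(8, seed = 6)
    sub <- feats[c(1:5, 9:13, 17:21), ]   # stratified subset, 5 per class
    model <- trainSeverityModel(sub)
    expect_equal(unname(model@center),
                 unname(colMeans(as.matrix(sub[, c("S_avg", "alpha", "E",
                                                   "A_delta_C", "T")]))))
    full <- colMeans(as.matrix(feats[, c("S_avg", "alpha", "E",
                                         "A_delta_C", "T")]))
    expect_false(isTRUE(all.equal(unname(model@center), unname(full))))
    # shifting held-out rows changes their standardized image, hence scores
    shifted <- feats[16:20, ]
    shifted$S_avg <- shifted$S_avg + 5
    expect_false(identical(predict(model, feats[16:20, ])$scores,
                           predict(model, shifted)$scores))
})

test_that("stratified cross-validation partitions every class evenly", {
    feats <- makeFeatureTable(10, seed = 7)
    rep5 <- crossValidate(feats, folds = 5, seed = 3)
    # every sample tested exactly once
    expect_length(rep5@folds, nrow(feats))
    expect_true(all(table(rep5@folds) == 6))
    for (k in 1:5)
        expect_true(all(table(feats$label[rep5@folds == k]) == 2))
    expect_equal(sum(rep5@confusion), nrow(feats))
    expect_equal(unname(rowSums(rep5@confusion)), rep(10, 3))
    expect_true(all(rep5@tpr >= 0 & rep5@tpr <= 1))
    expect_true(all(rep5@auc >= 0 & rep5@auc <= 1))
    expect_error(crossValidate(feats, folds = 11), "at least 11")
})

test_that("a perfectly separated dataset yields unit AUC and accuracy", {
    feats <- makeFeatureTable(10, seed = 8)
    rep10 <- crossValidate(feats, folds = 5, seed = 1)
    expect_gte(mean(rep10@foldAccuracy), 0.95)
    expect_gte(min(rep10@auc), 0.99)
    expect_equal(rep10@macroAUC, mean(rep10@auc))
    # ROC point sets span (0,0) to (1,1)
    for (r in rep10@roc) {
        expect_equal(min(r$fpr), 0); expect_equal(max(r$fpr), 1)
        expect_true(all(diff(r$tpr) >= 0))
    }
})

test_that("fold assignment is seed-reproducible and seed-sensitive", {
    feats <- makeFeatureTable(10, seed = 9)
    a <- crossValidate(feats, folds = 5, seed = 2)
    b <- crossValidate(feats, folds = 5, seed = 2)
    c <- crossValidate(feats, folds = 5, seed = 4)
    expect_identical(a@folds, b@folds)
    expect_identical(a@foldAccuracy, b@foldAccuracy)
    expect_false(identical(a@folds, c@folds))
})

test_that("the rank test matches the tie-corrected H formula and conserves ranks", {
    set.seed(12)
    feats <- data.frame(recording_id = as.character(1:9),
                        S_avg = c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                        alpha = rep(c(1, 2, 3), 3),
                        E = c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                        A_delta_C = rnorm(9),
                        T = c(5, 6, 4, 5, 6, 4, 5, 6, 4),
                        label = rep(0:2, each = 3))
    res <- rankFeatures(feats)
    expect_identical(res$feature,
                     c("S_avg", "alpha", "E", "A_delta_C", "T"))
    # well-separated groups are significant
    expect_lt(res$p[res$feature == "S_avg"], 0.05)
    # identical groups: H = 0, p = 1 (alpha and T repeat per level)
    expect_equal(res$H[res$feature == "alpha"], 0)
    expect_equal(res$p[res$feature == "alpha"], 1)
    expect_equal(res$H[res$feature == "T"], 0)
    # H agrees with the first-principles oracle
    g <- factor(feats$label)
    for (fc in c("S_avg", "A_delta_C", "T"))
        expect_equal(res$H[res$feature == fc],
                     oracleKruskalH(feats[[fc]], g), tolerance = 1e-12)
    # mean ranks average to (n+1)/2 weighted by group size
    mr <- as.matrix(res[, c("meanRank_0", "meanRank_1", "meanRank_2")])
    expect_equal(unname(rowMeans(mr)), rep(5, 5))
    expect_error(rankFeatures(data.frame(S_avg = 1:4, alpha = 1, E = 1,
                                         A_delta_C = 1, T = 1,
                                         label = 0L)),
                 "two severity levels")
})

test_that("model serialization round-trips through its versioned file", {
    feats <- makeFeatureTable(5, seed = 10)
    model <- trainSeverityModel(feats)
    path <- withr::local_tempfile(fileext = ".rds")
    writeSeverityModel(model, path)
    back <- readSeverityModel(path)
    expect_identical(predict(back, feats)$class,
                     predict(model, feats)$class)
    saveRDS(list(format = "other"), path)
    expect_error(readSeverityModel(path), "not a FrontalGait model")
})
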