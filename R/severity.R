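.FEATURE_COLS <- c("S_avg", "alpha", "E", "A_delta_C", "T")

#' Pearson VII universal (PUK) kernel
#'
#' \deqn{k(V_i, V_j) = 1 / \left[1 + \left(2\,\|V_i - V_j\|\,
#' \sqrt{2^{1/\omega} - 1} / \sigma\right)^2\right]^{\omega}}
#'
#' A modified Pearson VII function of the Euclidean distance: \code{sigma}
#' sets the half-width of the peak and \code{omega} its tailing factor,
#' letting one kernel family interpolate between Gaussian-like and
#' Lorentzian-like shapes. Equal vectors give exactly 1 and the kernel is
#' symmetric and positive.
#'
#' @param v1,v2 equal-length numeric feature vectors.
#' @param omega tailing factor (> 0), default 0.2.
#' @param sigma half-width (> 0), default 1.0.
#' @return Kernel value in (0, 1].
#' @examples
#' pukKernel(c(0, 0), c(0, 0))      # 1
#' pukKernel(0, 1)                  # about 0.3807 at the defaults
#' @export
pukKernel <- function(v1, v2, omega = 0.2, sigma = 1.0) {
    v1 <- as.numeric(v1); v2 <- as.numeric(v2)
    if (length(v1) != length(v2))
        stop("feature vectors must have equal length", call. = FALSE)
    if (omega <= 0 || sigma <= 0)
        stop("omega and sigma must be positive", call. = FALSE)
    d <- sqrt(sum((v1 - v2)^2))
    .pukFromDist(d, omega, sigma)
}

.pukFromDist <- function(d, omega, sigma) {
    (1 + (2 * d * sqrt(2^(1 / omega) - 1) / sigma)^2)^(-omega)
}

.crossDist <- function(A, B) {
    sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(sq, 0))
}

#' PUK gram matrix
#'
#' Kernel matrix of a standardized feature matrix: symmetric, unit
#' diagonal, entries in (0, 1], positive semi-definite up to numerical
#' tolerance.
#'
#' @param X numeric matrix, one sample per row.
#' @param omega,sigma PUK shape parameters.
#' @return The n x n kernel matrix.
#' @export
pukGram <- function(X, omega = 0.2, sigma = 1.0) {
    X <- as.matrix(X)
    if (!all(is.finite(X)))
        stop("features must be finite", call. = FALSE)
    K <- .pukFromDist(as.matrix(stats::dist(X)), omega, sigma)
    diag(K) <- 1
    dimnames(K) <- NULL
    K
}

.standardize <- function(X, center = NULL, scale = NULL) {
    X <- as.matrix(X)
    if (is.null(center)) {
        center <- colMeans(X)
        scale <- apply(X, 2L, stats::sd)
        scale[!is.finite(scale) | scale <= 0] <- 1   # constant feature guard
    }
    list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
         center = center, scale = scale)
}

.featureMatrix <- function(features) {
    missing <- setdiff(.FEATURE_COLS, names(features))
    if (length(missing))
        stop(sprintf("feature table lacks columns: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    X <- as.matrix(features[, .FEATURE_COLS, drop = FALSE])
    storage.mode(X) <- "double"
    X
}

#' Train the one-vs-all PUK-kernel severity model
#'
#' Fits three binary soft-margin SVMs over a precomputed PUK gram matrix,
#' one per UPDRS-gait level against the other two. Features are
#' standardized (center/scale per column) on the training data before the
#' kernel, since the five features mix seconds, hertz and dimensionless
#' quantities and the kernel is a function of Euclidean distance.
#'
#' @param features feature table (see \code{\link{extractFeatures}}) with
#'   an integer \code{label} column covering all of 0, 1, 2, at least two
#'   samples each.
#' @param omega,sigma PUK kernel shape (defaults 0.2 and 1.0).
#' @param C soft-margin regularization constant (default 1).
#' @return A \code{\linkS4class{PukSVM}}.
#' @export
trainSeverityModel <- function(features, omega = 0.2, sigma = 1.0, C = 1.0) {
    X <- .featureMatrix(features)
    y <- as.integer(features$label)
    if (anyNA(y) || anyNA(X) || !all(is.finite(X)))
        stop("training requires finite features and labels for every row",
             call. = FALSE)
    classes <- 0:2
    counts <- table(factor(y, levels = classes))
    if (any(counts < 2L))
        stop(sprintf("every class needs at least 2 training samples (got %s)",
                     paste(counts, collapse = "/")), call. = FALSE)
    std <- .standardize(X)
    K <- pukGram(std$X, omega, sigma)
    models <- vector("list", length(classes))
    signs <- numeric(length(classes))
    for (i in seq_along(classes)) {
        yc <- factor(ifelse(y == classes[i], "pos", "rest"),
                     levels = c("pos", "rest"))
        m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yc, type = "C-svc",
                           C = C)
        f <- kernlab::predict(m,
            kernlab::as.kernelMatrix(K[, kernlab::SVindex(m), drop = FALSE]),
            type = "decision")[, 1L]
        # orient the decision function: larger must mean "this class";
        # kernlab's sign convention w.r.t. factor levels is not contractual
        signs[i] <- if (mean(f[y == classes[i]]) >= mean(f[y != classes[i]]))
            1 else -1
        models[[i]] <- m
    }
    new("PukSVM", models = models, signs = signs, classes = classes,
        center = std$center, scale = std$scale, trainX = std$X,
        omega = omega, sigma = sigma, cost = C,
        featureNames = .FEATURE_COLS)
}

#' Predict UPDRS-gait severity
#'
#' Evaluates the three one-vs-all decision functions on new feature rows
#' and assigns the class with the maximal decision score; ties break
#' toward the lower class index.
#'
#' @param object a trained \code{\linkS4class{PukSVM}}.
#' @param newdata feature table or numeric matrix with the model's feature
#'   columns.
#' @param ... ignored.
#' @return A list with \code{class} (integer vector of predicted levels)
#'   and \code{scores} (n x 3 matrix of oriented decision values).
#' @export
setMethod("predict", "PukSVM", function(object, newdata, ...) {
    X <- if (is.data.frame(newdata)) .featureMatrix(newdata)
         else as.matrix(newdata)
    if (!all(is.finite(X)))
        stop("features must be finite for prediction", call. = FALSE)
    Xs <- .standardize(X, object@center, object@scale)$X
    Kc <- .pukFromDist(.crossDist(Xs, object@trainX), object@omega,
                       object@sigma)
    scores <- vapply(seq_along(object@classes), function(i) {
        m <- object@models[[i]]
        sv <- kernlab::SVindex(m)
        object@signs[i] * kernlab::predict(m,
            kernlab::as.kernelMatrix(Kc[, sv, drop = FALSE]),
            type = "decision")[, 1L]
    }, numeric(nrow(Xs)))
    scores <- matrix(scores, nrow = nrow(Xs),
                     dimnames = list(NULL, paste0("score_", object@classes)))
    cls <- object@classes[max.col(scores, ties.method = "first")]
    list(class = as.integer(cls), scores = scores)
})

.aggregateScores <- function(scores, classes = 0:2) {
    as.integer(classes[max.col(scores, ties.method = "first")])
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    force(expr)
}

.stratifiedFolds <- function(y, folds, seed) {
    .withSeed(seed, {
        assignment <- integer(length(y))
        for (cl in unique(y)) {
            idx <- sample(which(y == cl))
            assignment[idx] <- rep_len(seq_len(folds), length(idx))
        }
        assignment
    })
}

#' Stratified cross-validation of the severity model
#'
#' Splits the samples into stratified folds (every sample tested exactly
#' once, class proportions preserved per fold), refits the feature
#' standardization and the three one-vs-all machines on each training
#' split, and pools the out-of-fold predictions into a confusion matrix,
#' per-class true-positive rates, per-class ROC curves with AUC, and the
#' macro-averaged AUC.
#'
#' @param features feature table with labels (all of 0, 1, 2 present, at
#'   least \code{folds} samples per class).
#' @param omega,sigma,C model hyperparameters (see
#'   \code{\link{trainSeverityModel}}).
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold draw.
#' @return A \code{\linkS4class{GaitEvalReport}}.
#' @export
crossValidate <- function(features, omega = 0.2, sigma = 1.0, C = 1.0,
                          folds = 10L, seed = 1L) {
    X <- .featureMatrix(features)
    y <- as.integer(features$label)
    if (anyNA(y) || !all(is.finite(X)))
        stop("cross-validation requires finite features and labels",
             call. = FALSE)
    folds <- as.integer(folds)
    counts <- table(factor(y, levels = 0:2))
    if (any(counts < folds))
        stop(sprintf("every class needs at least %d samples for %d folds (got %s)",
                     folds, folds, paste(counts, collapse = "/")),
             call. = FALSE)
    assignment <- .stratifiedFolds(y, folds, seed)
    n <- length(y)
    pooledScores <- matrix(NA_real_, n, 3L,
                           dimnames = list(NULL, paste0("score_", 0:2)))
    pooledPred <- integer(n)
    foldAcc <- numeric(folds)
    for (k in seq_len(folds)) {
        test <- assignment == k
        model <- trainSeverityModel(features[!test, , drop = FALSE],
                                    omega = omega, sigma = sigma, C = C)
        pr <- predict(model, features[test, , drop = FALSE])
        pooledScores[test, ] <- pr$scores
        pooledPred[test] <- pr$class
        foldAcc[k] <- mean(pr$class == y[test])
    }
    cm <- table(true = factor(y, levels = 0:2),
                predicted = factor(pooledPred, levels = 0:2))
    cm <- unclass(cm)
    tpr <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_)
    rocs <- vector("list", 3L)
    aucs <- numeric(3L)
    for (i in 1:3) {
        cl <- i - 1L
        r <- pROC::roc(response = factor(y == cl, levels = c(FALSE, TRUE)),
                       predictor = pooledScores[, i], direction = "<",
                       quiet = TRUE)
        aucs[i] <- as.numeric(pROC::auc(r))
        rocs[[i]] <- data.frame(fpr = rev(1 - r$specificities),
                                tpr = rev(r$sensitivities))
    }
    new("GaitEvalReport", foldAccuracy = foldAcc, confusion = cm,
        tpr = as.numeric(tpr), auc = aucs, macroAUC = mean(aucs),
        roc = rocs, folds = assignment, seed = as.integer(seed))
}

#' Kruskal-Wallis screen of the gait features
#'
#' Non-parametric one-way analysis of variance of each feature across the
#' UPDRS-gait levels: values are ranked over all samples (mid-ranks for
#' ties), the tie-corrected H statistic is referred to a chi-square
#' distribution with (levels - 1) degrees of freedom, and the per-level
#' mean ranks show the direction of each effect.
#'
#' @param features feature table with a \code{label} column (at least two
#'   levels, two samples per level).
#' @return A \code{data.frame} with one row per feature: \code{feature},
#'   \code{H}, \code{p}, and \code{meanRank_<level>} columns.
#' @export
rankFeatures <- function(features) {
    y <- as.integer(features$label)
    if (anyNA(y)) stop("rank test requires labels for every row",
                       call. = FALSE)
    levelsPresent <- sort(unique(y))
    if (length(levelsPresent) < 2L)
        stop("rank test requires at least two severity levels",
             call. = FALSE)
    if (any(table(y) < 2L))
        stop("rank test requires at least two samples per level",
             call. = FALSE)
    g <- factor(y)
    rows <- lapply(.FEATURE_COLS, function(fc) {
        x <- as.numeric(features[[fc]])
        kt <- stats::kruskal.test(x, g)
        rk <- rank(x)
        mr <- tapply(rk, g, mean)
        out <- data.frame(feature = fc, H = unname(kt$statistic),
                          p = kt$p.value, stringsAsFactors = FALSE)
        for (lv in levelsPresent)
            out[[paste0("meanRank_", lv)]] <- unname(mr[[as.character(lv)]])
        out
    })
    do.call(rbind, rows)
}

#' Save / load a trained severity model
#'
#' Single-file serialization with a format version so that stored models
#' can be rejected cleanly when the layout changes.
#'
#' @param model a \code{PukSVM}.
#' @param path file path.
#' @return \code{readSeverityModel}: the \code{PukSVM};
#'   \code{writeSeverityModel}: the path, invisibly.
#' @export
writeSeverityModel <- function(model, path) {
    stopifnot(is(model, "PukSVM"))
    saveRDS(list(format = "FrontalGait-PukSVM", version = 1L, model = model),
            path)
    invisible(path)
}

#' @rdname writeSeverityModel
#' @export
readSeverityModel <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "FrontalGait-PukSVM"))
        stop("not a FrontalGait model file", call. = FALSE)
    if (!identical(obj$version, 1L))
        stop(sprintf("unsupported model format version %s", obj$version),
             call. = FALSE)
    validObject(obj$model)
    obj$model
}
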