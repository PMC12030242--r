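#' Random modeling/validation split
#'
#' Draws `floor(fraction * n)` sample ids uniformly without replacement
#' for the modeling set; the rest form the validation set. Deterministic
#' under `seed`.
#'
#' @param ids sample identifiers (or a single integer n, expanded to
#'   `seq_len(n)`).
#' @param fraction modeling fraction (default 2/3).
#' @param seed integer seed.
#' @return A list with `modeling` and `validation` id vectors.
#' @examples
#' s <- splitDataset(90, seed = 1)
#' c(length(s$modeling), length(s$validation))   # 60 30
#' @export
splitDataset <- function(ids, fraction = 2 / 3, seed = 1L) {
    if (length(ids) == 1L && is.numeric(ids)) ids <- seq_len(ids)
    n <- length(ids)
    if (n < 3L) stop("too few samples to split")
    n_model <- floor(fraction * n)
    pick <- local_seed(seed, sort(sample.int(n, n_model)))
    list(modeling = ids[pick], validation = ids[-pick])
}

#' Regression model specifications
#'
#' Hyperparameter defaults of the three estimators: polynomial-kernel
#' support vector regression with `C = 20` and `gamma = 0.02`
#' (degree 3); partial least squares regression whose latent-variable
#' count is grown while each added component raises the cumulative
#' explained Y-variance by at least 5 percentage points (capped at
#' `max_lvs`); and gradient boosting with 100 trees, learning rate 0.03
#' and maximum depth 5.
#'
#' @param name `"SVM"`, `"PLSR"` or `"XGBoost"`.
#' @param ... overrides of the defaults listed above.
#' @return A list of class `ModelSpec`.
#' @export
modelSpec <- function(name = c("SVM", "PLSR", "XGBoost"), ...) {
    name <- match.arg(name)
    defaults <- switch(name,
        SVM = list(cost = 20, gamma = 0.02, degree = 3, coef0 = 0),
        PLSR = list(max_lvs = 10L, lv_gain = 0.05),
        XGBoost = list(nrounds = 100L, eta = 0.03, max_depth = 5L))
    over <- list(...)
    defaults[names(over)] <- over
    structure(c(list(name = name), defaults), class = "ModelSpec")
}

# standardize columns with train-fitted center/scale; zero-variance and
# exactly duplicated columns are dropped (recorded in `keep`)
fit_scaler <- function(X) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    keep <- scl > 1e-12
    keep[keep] <- !duplicated(t(X[, keep, drop = FALSE]))
    if (!any(keep)) stop("degenerate input: all features constant")
    list(center = ctr[keep], scale = scl[keep], keep = colnames(X)[keep])
}

apply_scaler <- function(scaler, X) {
    X <- X[, scaler$keep, drop = FALSE]
    sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

pls_ncomp <- function(fit, Xs, y, max_lvs, lv_gain) {
    pred <- predict(fit, Xs)$predict
    sst <- sum((y - mean(y))^2)
    cum <- vapply(seq_len(dim(pred)[3]), function(k) {
        1 - sum((y - pred[, 1, k])^2) / sst
    }, numeric(1))
    k <- 1L
    while (k < length(cum) && (cum[k + 1] - cum[k]) >= lv_gain)
        k <- k + 1L
    k
}

#' Fit an LAI regression model
#'
#' Fits one of the three estimators to a training feature matrix.
#' Features are standardized (center/scale fitted on the training set
#' only) for SVM and PLSR; gradient boosting uses the raw features.
#' The PLSR latent-variable count is chosen by the 5%-gain rule of
#' [modelSpec()]. A constant training target yields a degenerate model
#' that predicts the constant.
#'
#' @param spec a [modelSpec()].
#' @param X numeric training matrix (samples x features, named
#'   columns).
#' @param y numeric training target.
#' @return An object of class `laiFit` usable with [predictLAI()].
#' @export
fitLAIModel <- function(spec, X, y) {
    stopifnot(inherits(spec, "ModelSpec"))
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != length(y)) stop("X and y lengths differ")
    if (anyNA(X) || anyNA(y)) stop("missing values in model inputs")
    if (stats::sd(y) == 0) {
        return(structure(list(spec = spec, constant = y[1],
                              columns = colnames(X)), class = "laiFit"))
    }
    fit <- list(spec = spec, columns = colnames(X), constant = NULL)
    if (spec$name == "XGBoost") {
        fit$model <- xgboost::xgb.train(
            params = list(eta = spec$eta, max_depth = spec$max_depth,
                          objective = "reg:squarederror", nthread = 1L),
            data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
            nrounds = spec$nrounds, verbose = 0)
    } else {
        fit$scaler <- fit_scaler(X)
        Xs <- apply_scaler(fit$scaler, X)
        if (spec$name == "SVM") {
            fit$model <- e1071::svm(
                x = Xs, y = y, type = "eps-regression",
                kernel = "polynomial", cost = spec$cost,
                gamma = spec$gamma, degree = spec$degree,
                coef0 = spec$coef0, scale = FALSE)
        } else {
            # cap components at the column rank so collinear (e.g.
            # duplicated) features cannot make the coefficient solve
            # singular
            max_lvs <- min(spec$max_lvs, qr(Xs)$rank, nrow(Xs) - 2L)
            max_lvs <- max(1L, max_lvs)
            pfit <- mixOmics::pls(Xs, y, ncomp = max_lvs,
                                  mode = "regression", scale = FALSE)
            fit$ncomp <- pls_ncomp(pfit, Xs, y, max_lvs, spec$lv_gain)
            fit$model <- pfit
        }
    }
    structure(fit, class = "laiFit")
}

#' @rdname fitLAIModel
#' @param fit a fitted `laiFit`.
#' @param X_new feature matrix with (at least) the training columns.
#' @return `predictLAI` returns the numeric prediction vector.
#' @export
predictLAI <- function(fit, X_new) {
    stopifnot(inherits(fit, "laiFit"))
    X_new <- as.matrix(X_new)
    if (!is.null(fit$constant))
        return(rep(fit$constant, nrow(X_new)))
    X_new <- X_new[, fit$columns, drop = FALSE]
    spec <- fit$spec
    if (spec$name == "XGBoost")
        return(as.numeric(predict(fit$model,
                                  xgboost::xgb.DMatrix(X_new,
                                                       nthread = 1L))))
    Xs <- apply_scaler(fit$scaler, X_new)
    if (spec$name == "SVM")
        return(as.numeric(predict(fit$model, Xs)))
    as.numeric(predict(fit$model, Xs)$predict[, 1, fit$ncomp])
}

#' @rdname fitLAIModel
#' @param X_train,y_train,X_eval convenience wrapper: fit on the
#'   training data and predict `X_eval`.
#' @export
fitPredict <- function(spec, X_train, y_train, X_eval) {
    predictLAI(fitLAIModel(spec, X_train, y_train), X_eval)
}

#' Regression evaluation metrics
#'
#' Determination coefficient `R2 = 1 - SSres/SStot`, root mean square
#' error and mean relative error
#' `MRE = (100/n) sum |y - yhat| / y` (percent).
#'
#' @param y_true observed values (> 0 for MRE).
#' @param y_pred predictions, same length.
#' @return A list with `R2`, `RMSE` and `MRE`; `R2` is `NA` when
#'   `y_true` has zero variance.
#' @examples
#' evaluateMetrics(c(1, 2, 3), c(1, 2, 4))   # RMSE sqrt(1/3), MRE 11.1%
#' @export
evaluateMetrics <- function(y_true, y_pred) {
    stopifnot(length(y_true) == length(y_pred))
    res <- y_true - y_pred
    sst <- sum((y_true - mean(y_true))^2)
    r2 <- if (sst <= 0) NA_real_ else 1 - sum(res^2) / sst
    list(R2 = r2, RMSE = sqrt(mean(res^2)),
         MRE = 100 * mean(abs(res) / y_true))
}

#' The fifteen input combinations
#'
#' All non-empty subsets of the four feature blocks: screened
#' vegetation indices (VIs), screened texture features (TFs), the six
#' best two-feature texture index columns (TIs) and the five best
#' three-feature texture index columns (TTIs).
#'
#' @return Named list of character vectors of block names, in grid
#'   order.
#' @export
inputCombinations <- function() {
    blocks <- c("VIs", "TFs", "TIs", "TTIs")
    subsets <- unlist(lapply(1:4, function(k)
        utils::combn(blocks, k, simplify = FALSE)), recursive = FALSE)
    names(subsets) <- vapply(subsets, paste, character(1),
                             collapse = " + ")
    subsets
}

#' Resolve the model input blocks from extracted features
#'
#' Screens the vegetation indices and texture features against LAI
#' (p < `alpha`), runs the exhaustive texture-index search, and
#' materializes the four input blocks used by the estimation grid:
#' the selected VI columns, the selected TF columns, one column per
#' two-feature family evaluated at its best tuple (TIs) and one per
#' three-feature family (TTIs).
#'
#' @param se a `SummarizedExperiment` from [extractFeatures()].
#' @param alpha screening significance level.
#' @param min_frac minimum finite-sample fraction for search tuples.
#' @return A list with `blocks` (named list of matrices), `screens`
#'   (VI and TF screening tables), `best` (the per-family best
#'   combination table) and `tuples` (named list of label tuples per
#'   family).
#' @export
buildModelInputs <- function(se, alpha = 0.05, min_frac = 0.8) {
    lai <- sampleLAI(se)
    vi <- featureBlock(se, "VI")
    tf <- featureBlock(se, "TF")
    vi_screen <- screenVariables(vi, lai, alpha)
    tf_screen <- screenVariables(tf, lai, alpha)
    best <- bestCombinationTable(tf, lai, min_frac = min_frac,
                                 alpha = alpha)
    fam <- textureIndexFamilies()
    tuples <- lapply(seq_len(nrow(best)), function(i)
        strsplit(best$labels[i], ", ", fixed = TRUE)[[1]])
    names(tuples) <- best$family
    index_col <- function(f) {
        tup <- tuples[[f]]
        if (fam$arity[fam$family == f] == 2L)
            tiValue(f, tf[, tup[1]], tf[, tup[2]])
        else
            ttiValue(f, tf[, tup[1]], tf[, tup[2]], tf[, tup[3]])
    }
    ti_names <- fam$family[fam$arity == 2L]
    tti_names <- fam$family[fam$arity == 3L]
    TIs <- vapply(ti_names, index_col, numeric(nrow(tf)))
    TTIs <- vapply(tti_names, index_col, numeric(nrow(tf)))
    rownames(TIs) <- rownames(tf); rownames(TTIs) <- rownames(tf)
    list(blocks = list(
             VIs = vi[, vi_screen$variable[vi_screen$selected],
                      drop = FALSE],
             TFs = tf[, tf_screen$variable[tf_screen$selected],
                      drop = FALSE],
             TIs = TIs, TTIs = TTIs),
         screens = list(VI = vi_screen, TF = tf_screen),
         best = best, tuples = tuples)
}

assemble_X <- function(inputs, combination) {
    mats <- inputs$blocks[combination]
    X <- do.call(cbind, mats)
    if (is.null(X) || ncol(X) == 0)
        stop("degenerate input: combination resolves to no columns")
    if (anyNA(X)) {
        bad <- apply(X, 2, anyNA)
        X <- X[, !bad, drop = FALSE]
        if (ncol(X) == 0)
            stop("degenerate input: all columns contain missing values")
    }
    X
}

#' Run the input-combination by model estimation grid
#'
#' Fits every combination of the fifteen input blocks and the three
#' estimators on one shared modeling/validation split and evaluates
#' both sets, yielding the 45-cell results grid.
#'
#' @param inputs resolved blocks from [buildModelInputs()].
#' @param lai ground-truth LAI vector aligned with the block rows.
#' @param split a [splitDataset()] assignment over `seq_along(lai)`;
#'   one split is shared by all cells.
#' @param specs list of [modelSpec()]s (default: the three defaults).
#' @return A `data.frame` with 45 rows and columns `combination`,
#'   `model`, `R2_cal`, `RMSE_cal`, `MRE_cal`, `R2_val`, `RMSE_val`,
#'   `MRE_val`.
#' @export
runGrid <- function(inputs, lai, split = splitDataset(length(lai)),
                    specs = list(modelSpec("SVM"), modelSpec("PLSR"),
                                 modelSpec("XGBoost"))) {
    combos <- inputCombinations()
    rows <- list()
    for (cn in names(combos)) {
        X <- assemble_X(inputs, combos[[cn]])
        Xm <- X[split$modeling, , drop = FALSE]
        Xv <- X[split$validation, , drop = FALSE]
        ym <- lai[split$modeling]
        yv <- lai[split$validation]
        for (spec in specs) {
            fit <- fitLAIModel(spec, Xm, ym)
            mc <- evaluateMetrics(ym, predictLAI(fit, Xm))
            mv <- evaluateMetrics(yv, predictLAI(fit, Xv))
            rows[[length(rows) + 1L]] <- data.frame(
                combination = cn, model = spec$name,
                R2_cal = mc$R2, RMSE_cal = mc$RMSE, MRE_cal = mc$MRE,
                R2_val = mv$R2, RMSE_val = mv$RMSE, MRE_val = mv$MRE,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Train a deployable LAI model
#'
#' Fits one estimator on one input combination over the full feature
#' set (or a supplied subset of rows) and bundles everything
#' [predictMap()] needs: the fitted model, the resolved input columns,
#' the best index tuples and the GLCM configuration.
#'
#' @param inputs resolved blocks from [buildModelInputs()].
#' @param lai ground-truth LAI vector.
#' @param combination character vector of block names (e.g.
#'   `c("VIs", "TFs", "TTIs")`).
#' @param spec a [modelSpec()].
#' @param rows optional row indices to train on (default all).
#' @param config the [glcmConfig()] that produced the features.
#' @return An object of class `laiModel`.
#' @export
trainLAIModel <- function(inputs, lai, combination,
                          spec = modelSpec("XGBoost"),
                          rows = seq_along(lai), config = glcmConfig()) {
    X <- assemble_X(inputs, combination)
    fit <- fitLAIModel(spec, X[rows, , drop = FALSE], lai[rows])
    structure(list(fit = fit, combination = combination,
                   columns = colnames(X),
                   vi_names = colnames(inputs$blocks$VIs),
                   tf_names = colnames(inputs$blocks$TFs),
                   tuples = inputs$tuples, config = config),
              class = "laiModel")
}

#' Per-pixel LAI inversion map
#'
#' Predicts LAI for every masked pixel of a scene from features of the
#' sliding window centered on it: vegetation indices from the window
#' mean reflectance, texture features from the window GLCMs, and
#' texture indices evaluated at the training-time best tuples. Pixels
#' outside the mask, or whose centered window leaves the raster, are
#' `NA`.
#'
#' @param image a [MultispectralImage-class].
#' @param mask logical vegetation mask.
#' @param model a trained [trainLAIModel()] object.
#' @return Numeric matrix of predicted LAI (same rows/cols as the
#'   image; `NA` = no data).
#' @export
predictMap <- function(image, mask, model) {
    stopifnot(inherits(model, "laiModel"))
    config <- model$config
    px <- plotTextureFeatures(image, mask, config, per_pixel = TRUE)
    tf <- px$features
    n <- nrow(tf)
    win <- config$window
    half <- win %/% 2L
    means <- lapply(1:6, function(b)
        cpp_window_mean(image@data[, , b], win))
    # center (r, c) is 0-based; window-mean matrix index is
    # (r - half + 1, c - half + 1)
    ridx <- px$row - half + 1L
    cidx <- px$col - half + 1L
    refl <- vapply(1:6, function(b)
        means[[b]][cbind(ridx, cidx)], numeric(n))
    colnames(refl) <- c("R_B", "R_G", "R_RED", "R_RE1", "R_RE2", "R_NIR")
    cols <- list()
    if ("VIs" %in% model$combination && length(model$vi_names))
        cols$VIs <- computeVIs(refl)[, model$vi_names, drop = FALSE]
    if ("TFs" %in% model$combination && length(model$tf_names))
        cols$TFs <- tf[, model$tf_names, drop = FALSE]
    fam <- textureIndexFamilies()
    index_cols <- function(famnames) {
        out <- vapply(famnames, function(f) {
            tup <- model$tuples[[f]]
            if (fam$arity[fam$family == f] == 2L)
                tiValue(f, tf[, tup[1]], tf[, tup[2]])
            else
                ttiValue(f, tf[, tup[1]], tf[, tup[2]], tf[, tup[3]])
        }, numeric(n))
        out
    }
    if ("TIs" %in% model$combination)
        cols$TIs <- index_cols(fam$family[fam$arity == 2L])
    if ("TTIs" %in% model$combination)
        cols$TTIs <- index_cols(fam$family[fam$arity == 3L])
    X <- do.call(cbind, cols)
    X <- X[, model$columns, drop = FALSE]
    ok <- stats::complete.cases(X)
    pred <- rep(NA_real_, n)
    if (any(ok))
        pred[ok] <- predictLAI(model$fit, X[ok, , drop = FALSE])
    out <- matrix(NA_real_, nrow(mask), ncol(mask))
    out[cbind(px$row + 1L, px$col + 1L)] <- pred
    out
}
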