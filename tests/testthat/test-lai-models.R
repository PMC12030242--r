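test_that("the modeling/validation split is a deterministic 2/3
           partition", {
    s <- splitDataset(90, seed = 4)
    expect_length(s$modeling, 60)
    expect_length(s$validation, 30)
    expect_setequal(c(s$modeling, s$validation), 1:90)
    expect_length(intersect(s$modeling, s$validation), 0)
    expect_identical(splitDataset(90, seed = 4), s)
    expect_false(identical(splitDataset(90, seed = 5)$modeling,
                           s$modeling))
    expect_error(splitDataset(2), "too few")
})

test_that("evaluation metrics match hand formulas", {
    m <- evaluateMetrics(c(1, 2, 3), c(1, 2, 4))
    expect_equal(m$RMSE, sqrt(1 / 3), tolerance = 1e-12)
    expect_equal(m$MRE, 100 / 9, tolerance = 1e-10)
    expect_equal(m$R2, 1 - 1 / 2, tolerance = 1e-12)
    perfect <- evaluateMetrics(c(1, 2, 3), c(1, 2, 3))
    expect_equal(unlist(perfect), c(R2 = 1, RMSE = 0, MRE = 0))
    # predicting the mean gives R2 = 0; constant truth flags R2
    y <- c(1, 2, 3, 4)
    expect_equal(evaluateMetrics(y, rep(mean(y), 4))$R2, 0)
    expect_true(is.na(evaluateMetrics(rep(2, 4), y)$R2))
    # random-vector oracle
    set.seed(12)
    yt <- runif(50, 0.5, 4); yp <- yt + rnorm(50, 0, 0.3)
    m2 <- evaluateMetrics(yt, yp)
    expect_equal(m2$R2, 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2),
                 tolerance = 1e-10)
    expect_equal(m2$RMSE, sqrt(sum((yt - yp)^2) / 50), tolerance = 1e-10)
    expect_equal(m2$MRE, 100 * mean(abs(yt - yp) / yt), tolerance = 1e-10)
})

test_that("PLSR recovers a noise-free linear target and tolerates
           duplicated columns", {
    set.seed(14)
    X <- matrix(rnorm(60 * 4), 60)
    colnames(X) <- paste0("f", 1:4)
    y <- 2 * X[, 1] + 1
    tr <- 1:40; ev <- 41:60
    pred <- fitPredict(modelSpec("PLSR"), X[tr, ], y[tr], X[ev, ])
    expect_gt(evaluateMetrics(y[ev], pred)$R2, 0.99)
    Xd <- cbind(X, f1b = X[, 1])
    pred_d <- fitPredict(modelSpec("PLSR"), Xd[tr, ], y[tr], Xd[ev, ])
    expect_equal(pred, pred_d, tolerance = 1e-6)
})

test_that("constant targets give constant predictions", {
    set.seed(15)
    X <- matrix(rnorm(30 * 3), 30); colnames(X) <- paste0("f", 1:3)
    for (m in c("SVM", "PLSR", "XGBoost")) {
        p <- fitPredict(modelSpec(m), X[1:20, ], rep(2.5, 20), X[21:30, ])
        expect_equal(p, rep(2.5, 10))
    }
    expect_error(fitLAIModel(modelSpec("SVM"),
                             matrix(1, 10, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             rnorm(10)), "degenerate")
})

test_that("scaling is fitted on the training set only", {
    set.seed(16)
    X <- matrix(rnorm(60 * 3, mean = 5), 60)
    colnames(X) <- paste0("f", 1:3)
    y <- X[, 1] + rnorm(60, 0, 0.2)
    tr <- 1:40; ev <- 41:60
    got <- fitPredict(modelSpec("SVM"), X[tr, ], y[tr], X[ev, ])
    # independent train-only-scaled reference
    ctr <- colMeans(X[tr, ]); scl <- apply(X[tr, ], 2, sd)
    Xs_tr <- scale(X[tr, ], ctr, scl); Xs_ev <- scale(X[ev, ], ctr, scl)
    ref <- as.numeric(predict(
        e1071::svm(x = Xs_tr, y = y[tr], type = "eps-regression",
                   kernel = "polynomial", cost = 20, gamma = 0.02,
                   degree = 3, coef0 = 0, scale = FALSE), Xs_ev))
    expect_equal(got, ref, tolerance = 1e-8)
    # a leaky scaler fitted on all rows changes the predictions
    ctr2 <- colMeans(X); scl2 <- apply(X, 2, sd)
    leak <- as.numeric(predict(
        e1071::svm(x = scale(X[tr, ], ctr2, scl2), y = y[tr],
                   type = "eps-regression", kernel = "polynomial",
                   cost = 20, gamma = 0.02, degree = 3, coef0 = 0,
                   scale = FALSE), scale(X[ev, ], ctr2, scl2)))
    expect_gt(max(abs(leak - got)), 1e-6)
})

test_that("the estimation grid covers 15 x 3 cells deterministically", {
    ce <- cached_experiment()
    inputs <- buildModelInputs(ce$se)
    lai <- sampleLAI(ce$se)
    split <- splitDataset(length(lai), seed = 7)
    grid <- runGrid(inputs, lai, split)
    expect_equal(nrow(grid), 45)
    expect_equal(length(unique(grid$combination)), 15)
    expect_setequal(unique(grid$model), c("SVM", "PLSR", "XGBoost"))
    expect_true(all(grid$RMSE_val >= 0 & grid$MRE_val >= 0))
    expect_true(all(grid$R2_val <= 1))
    expect_identical(grid, runGrid(inputs, lai, split))
    cached_env$inputs <- inputs
    cached_env$grid <- grid
})

test_that("per-pixel inversion maps respect the mask and track
           plot-level predictions", {
    ce <- cached_experiment()
    inputs <- cached_env$inputs
    if (is.null(inputs)) inputs <- buildModelInputs(ce$se)
    lai <- sampleLAI(ce$se)
    model <- trainLAIModel(inputs, lai, c("VIs", "TFs", "TTIs"),
                           modelSpec("XGBoost"))
    s <- ce$ex$samples[[1]]
    lmap <- predictMap(msImage(s), vegMask(s), model)
    expect_identical(dim(lmap), dim(vegMask(s)))
    # no-data exactly complements the evaluable centers
    half <- 3L
    interior <- matrix(FALSE, nrow(lmap), ncol(lmap))
    interior[(half + 1):(nrow(lmap) - half),
             (half + 1):(ncol(lmap) - half)] <- TRUE
    expect_true(all(is.na(lmap[!vegMask(s) | !interior])))
    # constant scene -> constant map (spectral model: degenerate
    # textures legitimately invalidate index columns, so use VIs)
    rad0 <- canopyRadiativeModel(tex_sd_base = rep(0, 6),
                                 tex_sd_max = rep(0, 6),
                                 tex_jitter_sd = 0, plot_band_sd = 0,
                                 cover_k = Inf)
    sc <- renderScene(2, rad0, shape = c(15, 15), seed = 2)
    vi_model <- trainLAIModel(inputs, lai, "VIs", modelSpec("XGBoost"))
    cmap <- predictMap(sc$image, sc$mask, vi_model)
    vals <- cmap[!is.na(cmap)]
    expect_gt(length(vals), 0)
    expect_lt(diff(range(vals)), 1e-8)
    # window-level means track plot-level predictions across plots
    X <- do.call(cbind, inputs$blocks[c("VIs", "TFs", "TTIs")])
    plot_pred <- predictLAI(model$fit, X)
    map_mean <- vapply(ce$ex$samples[1:8], function(sm)
        mean(predictMap(msImage(sm), vegMask(sm), model), na.rm = TRUE),
        numeric(1))
    expect_gt(cor(map_mean, plot_pred[1:8], method = "spearman"), 0.5)
})
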