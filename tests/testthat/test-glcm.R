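test_that("quantization follows the min-max binning rule", {
    expect_equal(as.vector(quantizeBand(matrix(c(0, 0.5, 1), 1), G = 2)),
                 c(0L, 1L, 1L))
    expect_true(all(quantizeBand(matrix(0.4, 5, 5), G = 8) == 0L))
    # monotone transforms preserve level ranks
    set.seed(2)
    x <- matrix(runif(64), 8, 8)
    q1 <- quantizeBand(x, G = 16)
    q2 <- quantizeBand(sqrt(x), G = 16)
    expect_true(all(sign(outer(as.vector(q1), as.vector(q1), "-")) *
                    sign(outer(as.vector(q2), as.vector(q2), "-")) >= 0))
})

test_that("window GLCMs count pairs correctly and normalize", {
    cfg <- glcmConfig(window = 3, offset = c(1, 0), gray_levels = 2,
                      symmetric = FALSE)
    w <- matrix(c(0L, 0L, 1L, 1L), 2, 2)      # columns (0,0) and (1,1)
    g <- glcmFromWindow(w, cfg)
    expect_equal(g@P, matrix(c(0, 0, 1, 0), 2, 2))  # all mass on (0,1)
    # constant window: all mass at the diagonal cell
    gc <- glcmFromWindow(matrix(3L, 4, 4),
                         glcmConfig(gray_levels = 8, offset = c(1, 1)))
    expect_equal(gc@P[4, 4], 1)
    # symmetric equals (A + t(A)) / 2 of the asymmetric matrix
    set.seed(5)
    w2 <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    cfgA <- glcmConfig(gray_levels = 4, symmetric = FALSE)
    cfgS <- glcmConfig(gray_levels = 4, symmetric = TRUE)
    A <- glcmFromWindow(w2, cfgA)@P
    S <- glcmFromWindow(w2, cfgS)@P
    expect_equal(S, (A + t(A)) / 2, tolerance = 1e-12)
    expect_equal(sum(S), 1, tolerance = 1e-12)
    expect_error(glcmFromWindow(matrix(0L, 1, 1), cfgA), "degenerate")
})

test_that("degenerate and closed-form GLCM statistics are exact", {
    # single-cell distribution
    P <- matrix(0, 8, 8); P[4, 4] <- 1
    f <- glcmFeatures(methods::new("GLCM", P = P, levels = 8L,
                                   symmetric = TRUE))
    expect_equal(unname(f), c(3, 0, 1, 0, 0, 0, 1, 0))
    # uniform over the 4 cells of a 2-level GLCM
    Pu <- matrix(0.25, 2, 2)
    fu <- glcmFeatures(methods::new("GLCM", P = Pu, levels = 2L,
                                    symmetric = TRUE))
    expect_equal(unname(fu["SEM"]), 0.25)
    expect_equal(unname(fu["ENT"]), log(4))
})

test_that("GLCM statistics match the double-loop oracle on random
           matrices", {
    set.seed(11)
    for (rep in 1:20) {
        G <- sample(c(3, 5, 8), 1)
        P <- matrix(rexp(G * G), G, G)
        P <- (P + t(P)); P <- P / sum(P)
        f <- glcmFeatures(methods::new("GLCM", P = P, levels = as.integer(G),
                                       symmetric = TRUE))
        expect_equal(unname(f), unname(oracle_glcm_stats(P)),
                     tolerance = 1e-10)
        # Jensen bound: contrast dominates squared dissimilarity
        expect_gte(f[["CON"]], f[["DIS"]]^2 - 1e-12)
    }
})

test_that("plot-level features equal the brute-force sliding-window
           oracle", {
    set.seed(7)
    for (rep in 1:4) {
        nr <- sample(9:12, 1); nc <- sample(9:12, 1)
        arr <- array(runif(nr * nc * 6), dim = c(nr, nc, 6))
        img <- MultispectralImage(arr)
        mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
        cfg <- glcmConfig(window = 7, offset = c(1, 1), gray_levels = 8)
        got <- plotTextureFeatures(img, mask, cfg)
        for (b in 1:6) {
            want <- oracle_plot_features(arr[, , b], mask, 7, 1, 1, 8,
                                         TRUE)
            expect_equal(unname(got[(b - 1) * 8 + 1:8]), unname(want),
                         tolerance = 1e-10)
        }
    }
})

test_that("constant scenes and shifted scenes give the expected
           plot features", {
    img <- MultispectralImage(array(0.5, dim = c(9, 9, 6)))
    mask <- matrix(TRUE, 9, 9)
    f <- plotTextureFeatures(img, mask)
    zeroes <- grepl("^(VAR|CON|DIS|ENT)", names(f))
    ones <- grepl("^(HOM|SEM)", names(f))
    expect_true(all(f[zeroes] == 0))
    expect_true(all(f[ones] == 1))
    # band-wise constant offsets cancel in min-max quantization
    set.seed(13)
    arr <- array(runif(11 * 11 * 6, 0.1, 0.6), dim = c(11, 11, 6))
    shift <- array(rep(seq(0.01, 0.06, by = 0.01),
                       each = 11 * 11), dim = c(11, 11, 6))
    m <- matrix(TRUE, 11, 11)
    expect_equal(plotTextureFeatures(MultispectralImage(arr), m),
                 plotTextureFeatures(MultispectralImage(arr + shift), m),
                 tolerance = 1e-12)
    expect_error(plotTextureFeatures(
        MultispectralImage(array(0.1, dim = c(5, 5, 6))),
        matrix(TRUE, 5, 5)), "smaller")
})

test_that("feature bounds hold on generated scenes", {
    ce <- cached_experiment()
    tf <- featureBlock(ce$se, "TF")
    for (stat in c("HOM", "SEM")) {
        v <- tf[, grepl(paste0("^", stat), colnames(tf))]
        expect_true(all(v > 0 & v <= 1))
    }
    for (stat in c("VAR", "CON", "DIS", "ENT")) {
        v <- tf[, grepl(paste0("^", stat), colnames(tf))]
        expect_true(all(v >= 0))
    }
    v <- tf[, grepl("^COR", colnames(tf))]
    expect_true(all(v >= -1 & v <= 1))
})
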