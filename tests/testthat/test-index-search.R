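test_that("texture index algebra holds", {
    expect_equal(tiValue("NDTI", 3, 1), 0.5)
    expect_equal(tiValue("RTI", 2.7, 2.7), 1)
    expect_equal(tiValue("DTI", 2.7, 2.7), 0)
    expect_equal(tiValue("NDTI", 1.3, 1.3), 0)
    for (t in c(0.1, 1, 7.5))
        expect_equal(ttiValue("NDTTI", t, t, t), -1 / 3, tolerance = 1e-12)
    expect_equal(ttiValue("RDTTI", 1, 2, 4), 0.25)
    expect_equal(ttiValue("RATTI", 1, 2, 4), 1.75)
    expect_equal(ttiValue("DTTI", 5, 2, 1), 2)
    expect_equal(ttiValue("RTTI", 8, 2, 2), 2)
    # undefined values are NA markers, never errors
    expect_true(is.na(tiValue("RTI", 1, 0)))
    expect_true(is.na(tiValue("NDTI", 1, -1)))
    expect_true(is.na(ttiValue("RDTTI", 0, 1, 1)))
    # bounded families stay in (-1, 1) on positive features
    set.seed(9)
    a <- runif(50, .1, 9); b <- runif(50, .1, 9); c3 <- runif(50, .1, 9)
    expect_true(all(abs(tiValue("NDTI", a, b)) < 1))
    expect_true(all(abs(ttiValue("NDTTI", a, b, c3)) < 1))
})

test_that("pearson correlation and p-value match the closed-form
           t-statistic", {
    x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
    got <- pearsonWithP(x, y)
    # textbook computation
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tt <- r * sqrt((5 - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = 3)
    expect_equal(got$r, r, tolerance = 1e-12)
    expect_equal(got$p, p, tolerance = 1e-12)
    # perfect linearity and constructed orthogonality
    expect_equal(pearsonWithP(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
    x0 <- c(-1, 0, 1, 0); y0 <- c(0, -1, 0, 1)
    expect_equal(pearsonWithP(x0, y0)$r, 0, tolerance = 1e-12)
    expect_error(pearsonWithP(x, rep(1, 5)), "zero variance")
})

test_that("screening selects exact-signal columns and flags constants", {
    set.seed(6)
    lai <- runif(30, 0.5, 3)
    F <- cbind(signal = lai, noise = rnorm(30), const = rep(1, 30))
    sc <- screenVariables(F, lai)
    expect_equal(sc$r[sc$variable == "signal"], 1, tolerance = 1e-12)
    expect_true(sc$selected[sc$variable == "signal"])
    expect_true(is.na(sc$r[sc$variable == "const"]))
    expect_false(sc$selected[sc$variable == "const"])
})

test_that("a planted difference pair is recovered with |r| = 1", {
    set.seed(10)
    n <- 40
    lai <- runif(n, 0.5, 3.5)
    F <- random_positive_features(n, 6, seed = 10,
                                  labels = paste0("T", 1:6))
    F[, 1] <- lai + 5          # T1 - T2 == lai exactly
    F[, 2] <- rep(5, n)
    sr <- searchFamily("DTI", F, lai)
    expect_equal(sr$best$labels, "T1, T2")
    expect_equal(sr$best$abs_r, 1, tolerance = 1e-9)
})

test_that("the NDTI diagonal is invalid (identically zero)", {
    F <- random_positive_features(30, 5, seed = 3)
    lai <- runif(30, 1, 3)
    sr <- searchFamily("NDTI", F, lai)
    expect_true(all(is.na(diag(sr$tensor))))
})

test_that("search equals brute-force enumeration for every family on a
           reduced alphabet", {
    n <- 25
    F <- random_positive_features(n, 6, seed = 17)
    set.seed(18)
    lai <- as.vector(0.5 * F[, 1] + runif(n))
    fam <- textureIndexFamilies()
    for (i in seq_len(nrow(fam))) {
        got <- searchFamily(fam$family[i], F, lai)
        want <- oracle_search(fam$family[i], fam$arity[i], F, lai)
        expect_equal(unname(got$tensor), want$tensor, tolerance = 1e-10,
                     info = fam$family[i])
        labs <- colnames(F)[want$best$tuple]
        expect_equal(got$best$labels, paste(labs, collapse = ", "),
                     info = fam$family[i])
        expect_equal(got$best$abs_r, want$best$abs_r, tolerance = 1e-10)
    }
})

test_that("search |r| agrees with pearson on materialized index
           columns", {
    F <- random_positive_features(30, 6, seed = 23)
    set.seed(24)
    lai <- as.vector(F[, 2] + rnorm(30, 0, 0.5))
    for (fam in c("RTI", "NDTI", "NDTTI", "RATTI")) {
        sr <- searchFamily(fam, F, lai)
        set.seed(25)
        arity <- textureIndexFamilies()$arity[
            textureIndexFamilies()$family == fam]
        for (rep in 1:25) {
            idx <- sample(6, arity, replace = TRUE)
            v <- if (arity == 2) tiValue(fam, F[, idx[1]], F[, idx[2]])
                 else ttiValue(fam, F[, idx[1]], F[, idx[2]], F[, idx[3]])
            cell <- if (arity == 2) sr$tensor[idx[1], idx[2]]
                    else sr$tensor[idx[1], idx[2], idx[3]]
            if (!is.na(cell))
                expect_equal(cell, abs(pearsonWithP(v, lai)$r),
                             tolerance = 1e-10)
        }
    }
})

test_that("augmenting with a zero column nests DTI inside DTTI", {
    F <- random_positive_features(35, 5, seed = 31)
    set.seed(32)
    lai <- as.vector(F[, 3] + rnorm(35, 0, 0.4))
    best2 <- searchFamily("DTI", F, lai)$best$abs_r
    Fz <- cbind(F, Z0 = rep(0, 35))
    best3 <- searchFamily("DTTI", Fz, lai)$best$abs_r
    expect_gte(best3, best2 - 1e-12)
})

test_that("the best-combination table is complete, bounded and
           deterministic", {
    ce <- cached_experiment()
    tf <- featureBlock(ce$se, "TF")
    lai <- sampleLAI(ce$se)
    tab <- bestCombinationTable(tf, lai)
    expect_equal(nrow(tab), 11)
    expect_setequal(tab$family, textureIndexFamilies()$family)
    expect_true(all(tab$abs_r >= 0 & tab$abs_r <= 1))
    expect_identical(tab, bestCombinationTable(tf, lai))
})
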