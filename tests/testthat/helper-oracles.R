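# Independent brute-force oracles, written from the definitions and kept
# free of the package's computational paths.

# naive 8 statistics from an explicit normalized co-occurrence matrix,
# gray levels 0..G-1, by double loop
oracle_glcm_stats <- function(P) {
    G <- nrow(P)
    mea <- var <- hom <- con <- dis <- ent <- sem <- 0
    mu_i <- mu_j <- var_i <- var_j <- cov <- 0
    for (i in seq_len(G)) for (j in seq_len(G)) {
        p <- P[i, j]
        mu_i <- mu_i + (i - 1) * p
        mu_j <- mu_j + (j - 1) * p
    }
    for (i in seq_len(G)) for (j in seq_len(G)) {
        p <- P[i, j]
        li <- i - 1; lj <- j - 1
        mea <- mea + li * p
        var <- var + (li - mu_i)^2 * p
        var_i <- var_i + (li - mu_i)^2 * p
        var_j <- var_j + (lj - mu_j)^2 * p
        cov <- cov + (li - mu_i) * (lj - mu_j) * p
        hom <- hom + p / (1 + (li - lj)^2)
        con <- con + (li - lj)^2 * p
        dis <- dis + abs(li - lj) * p
        if (p > 0) ent <- ent - p * log(p)
        sem <- sem + p^2
    }
    cor <- if (var_i > 1e-14 && var_j > 1e-14)
        cov / sqrt(var_i * var_j) else 0
    c(MEA = mea, VAR = var, HOM = hom, CON = con, DIS = dis, ENT = ent,
      SEM = sem, COR = cor)
}

# pair-counting GLCM of one window by full enumeration
oracle_window_glcm <- function(w, dx, dy, G, symmetric) {
    P <- matrix(0, G, G)
    nr <- nrow(w); nc <- ncol(w)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        pr <- r + dy; pc <- c + dx
        if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) {
            P[w[r, c] + 1, w[pr, pc] + 1] <-
                P[w[r, c] + 1, w[pr, pc] + 1] + 1
            if (symmetric)
                P[w[pr, pc] + 1, w[r, c] + 1] <-
                    P[w[pr, pc] + 1, w[r, c] + 1] + 1
        }
    }
    P / sum(P)
}

# plot-level texture features by looping every full window whose center
# is masked; quantization re-derived from the binning definition
oracle_plot_features <- function(band, mask, win, dx, dy, G, symmetric) {
    lo <- min(band[mask]); hi <- max(band[mask])
    q <- if (hi > lo)
        pmin(G - 1, pmax(0, floor(G * (band - lo) / (hi - lo))))
    else matrix(0, nrow(band), ncol(band))
    dim(q) <- dim(band)
    half <- win %/% 2
    acc <- NULL
    for (r in seq(half + 1, nrow(band) - half)) {
        for (c in seq(half + 1, ncol(band) - half)) {
            if (!mask[r, c]) next
            w <- q[(r - half):(r + half), (c - half):(c + half)]
            P <- oracle_window_glcm(w, dx, dy, G, symmetric)
            acc <- rbind(acc, oracle_glcm_stats(P))
        }
    }
    colMeans(acc)
}

# index family formulas restated independently
oracle_index <- function(family, ti, tj, tk = NULL) {
    v <- switch(family,
        RTI = ti / tj, DTI = ti - tj, ATI = ti + tj,
        NDTI = (ti - tj) / (ti + tj),
        RDTI = 1 / ti - 1 / tj, RATI = 1 / ti + 1 / tj,
        RTTI = ti / tj / tk, DTTI = ti - tj - tk,
        NDTTI = (ti - tj - tk) / (ti + tj + tk),
        RDTTI = 1 / ti - 1 / tj - 1 / tk,
        RATTI = 1 / ti + 1 / tj + 1 / tk)
    v[!is.finite(v)] <- NA
    v
}

# exhaustive search by materializing every tuple column
oracle_search <- function(family, arity, F, lai, min_frac = 0.8) {
    K <- ncol(F)
    n <- nrow(F)
    best <- list(abs_r = -1, tuple = NULL)
    tensor <- array(NA_real_, dim = rep(K, arity))
    ks <- if (arity == 3) seq_len(K) else 1L
    for (i in seq_len(K)) for (j in seq_len(K)) for (k in ks) {
        v <- if (arity == 2) oracle_index(family, F[, i], F[, j])
             else oracle_index(family, F[, i], F[, j], F[, k])
        keep <- is.finite(v)
        if (sum(keep) < ceiling(min_frac * n)) next
        # numerically constant columns (population variance below 1e-12)
        # carry no information and are invalid
        pvar <- function(z) mean((z - mean(z))^2)
        if (pvar(v[keep]) <= 1e-12 || pvar(lai[keep]) <= 1e-12) next
        r <- cor(v[keep], lai[keep])
        if (arity == 2) tensor[i, j] <- abs(r) else tensor[i, j, k] <- abs(r)
        if (abs(r) > best$abs_r) {
            best$abs_r <- abs(r)
            best$tuple <- if (arity == 2) c(i, j) else c(i, j, k)
        }
    }
    list(tensor = tensor, best = best)
}

# one shared default synthetic run for tests that need real features
cached_env <- new.env()
cached_experiment <- function() {
    if (is.null(cached_env$se)) {
        ex <- generateExperiment(seed = 42L)
        cached_env$ex <- ex
        cached_env$se <- extractFeatures(ex$samples)
    }
    list(ex = cached_env$ex, se = cached_env$se)
}

random_positive_features <- function(n, K, seed, labels = NULL) {
    set.seed(seed)
    F <- matrix(runif(n * K, 0.2, 5), n, K)
    colnames(F) <- if (is.null(labels)) paste0("T", seq_len(K)) else labels
    F
}
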