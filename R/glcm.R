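#' GLCM extraction configuration
#'
#' Settings for sliding-window gray-level co-occurrence texture
#' extraction: an odd window size (default 7 x 7), the pixel offset at
#' which gray-level pairs are counted (default one pixel right and one
#' down), the number of gray levels used for quantization, and whether
#' the matrix is symmetrized by also counting reversed pairs.
#'
#' The offset convention is `(dx, dy)` = (column shift, row shift):
#' pixel `(r, c)` is paired with `(r + dy, c + dx)`.
#'
#' @param window odd integer window size, >= 3.
#' @param offset integer vector `c(dx, dy)`, not both zero.
#' @param gray_levels number of quantization levels G >= 2 (default 32).
#' @param symmetric logical, symmetrize the matrix (default `TRUE`).
#' @return A list of class `GLCMConfig`.
#' @export
glcmConfig <- function(window = 7L, offset = c(1L, 1L), gray_levels = 32L,
                       symmetric = TRUE) {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
        stop("window must be odd and >= 3")
    offset <- as.integer(offset)
    if (length(offset) != 2L || all(offset == 0L))
        stop("offset must be a nonzero (dx, dy) pair")
    gray_levels <- as.integer(gray_levels)
    if (gray_levels < 2L) stop("gray_levels must be >= 2")
    structure(list(window = window, offset = offset,
                   gray_levels = gray_levels,
                   symmetric = isTRUE(symmetric)),
              class = "GLCMConfig")
}

#' The eight texture feature names
#'
#' @return Character vector `MEA, VAR, HOM, CON, DIS, ENT, SEM, COR`.
#' @export
textureFeatureNames <- function() {
    c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEM", "COR")
}

#' The 48 texture feature labels
#'
#' Labels are feature name plus band index, e.g. `DIS5` = dissimilarity
#' of band 5 (the 750 nm red-edge channel), ordered band-major.
#'
#' @return Character vector of length 48.
#' @export
textureFeatureLabels <- function() {
    as.vector(t(outer(1:6, textureFeatureNames(),
                      function(b, f) paste0(f, b))))
}

#' Quantize a reflectance band to gray levels
#'
#' Linear min-max scaling over the masked pixels followed by flooring
#' into `G` bins; the top of the range maps to bin `G - 1`. Pixels
#' outside the mask are scaled with the same affine map and clipped, so
#' a quantized level exists everywhere. A constant band maps to all
#' zeros.
#'
#' @param band numeric matrix of reflectance.
#' @param G number of gray levels.
#' @param mask logical matrix; range is computed over `mask` (default:
#'   all pixels).
#' @return Integer matrix with values in `0 .. G-1`.
#' @examples
#' quantizeBand(matrix(c(0, 0.5, 1), 1), G = 2)   # 0 1 1
#' @export
quantizeBand <- function(band, G, mask = NULL) {
    stopifnot(all(is.finite(band)))
    if (is.null(mask)) mask <- matrix(TRUE, nrow(band), ncol(band))
    lo <- min(band[mask])
    hi <- max(band[mask])
    if (hi <= lo) {
        q <- matrix(0L, nrow(band), ncol(band))
        return(q)
    }
    q <- floor(G * (band - lo) / (hi - lo))
    q[q > G - 1] <- G - 1
    q[q < 0] <- 0
    storage.mode(q) <- "integer"
    q
}

#' Build a GLCM from one quantized window
#'
#' Counts gray-level pairs `(x, x + offset)` whose members both lie
#' inside the window, optionally adds the transposed counts, and
#' normalizes to probabilities.
#'
#' @param window integer matrix of quantized gray levels.
#' @param config a [glcmConfig()].
#' @return A [GLCM-class] object.
#' @examples
#' w <- matrix(c(0L, 0L, 1L, 1L), 2, 2)   # columns 0 0 / 1 1
#' g <- glcmFromWindow(w, glcmConfig(window = 3, offset = c(1, 0),
#'                                   gray_levels = 2, symmetric = FALSE))
#' g@P   # all mass on the (0, 1) pair
#' @export
glcmFromWindow <- function(window, config = glcmConfig()) {
    G <- config$gray_levels
    dx <- config$offset[1]; dy <- config$offset[2]
    nr <- nrow(window); nc <- ncol(window)
    P <- matrix(0, G, G)
    for (r in seq_len(nr)) {
        pr <- r + dy
        if (pr < 1 || pr > nr) next
        for (c in seq_len(nc)) {
            pc <- c + dx
            if (pc < 1 || pc > nc) next
            a <- window[r, c] + 1L
            b <- window[pr, pc] + 1L
            P[a, b] <- P[a, b] + 1
            if (config$symmetric) P[b, a] <- P[b, a] + 1
        }
    }
    tot <- sum(P)
    if (tot == 0)
        stop("degenerate window: no valid pixel pair at the offset")
    methods::new("GLCM", P = P / tot, levels = as.integer(G),
                 symmetric = config$symmetric)
}

#' Texture statistics of a GLCM
#'
#' Computes the eight co-occurrence statistics from a normalized GLCM
#' whose gray levels are the integers `0 .. G-1`:
#' mean `MEA = sum i P(i,j)`; variance `VAR = sum (i - u)^2 P(i,j)`;
#' homogeneity `HOM = sum P(i,j) / (1 + (i-j)^2)`; contrast
#' `CON = sum (i-j)^2 P(i,j)`; dissimilarity `DIS = sum |i-j| P(i,j)`;
#' entropy `ENT = -sum P(i,j) log P(i,j)` (natural log, `0 log 0 = 0`);
#' second moment `SEM = sum P(i,j)^2`; and correlation
#' `COR = sum (i - mu_i)(j - mu_j) P(i,j) / sqrt(VAR_i VAR_j)`, defined
#' as 0 when either marginal variance vanishes.
#'
#' @param glcm a [GLCM-class] with probabilities summing to 1.
#' @return Named numeric vector of the 8 statistics.
#' @export
glcmFeatures <- function(glcm) {
    P <- glcm@P
    if (abs(sum(P) - 1) > 1e-9)
        stop("GLCM must be normalized to sum 1")
    G <- glcm@levels
    lev <- 0:(G - 1)
    pi_ <- rowSums(P)
    pj_ <- colSums(P)
    mu_i <- sum(lev * pi_)
    mu_j <- sum(lev * pj_)
    var_i <- sum((lev - mu_i)^2 * pi_)
    var_j <- sum((lev - mu_j)^2 * pj_)
    I <- matrix(lev, G, G)
    J <- t(I)
    D <- I - J
    mea <- mu_i
    var <- var_i
    hom <- sum(P / (1 + D^2))
    con <- sum(D^2 * P)
    dis <- sum(abs(D) * P)
    ent <- -sum(ifelse(P > 0, P * log(P), 0))
    sem <- sum(P^2)
    cor <- if (var_i > 1e-14 && var_j > 1e-14)
        sum((I - mu_i) * (J - mu_j) * P) / sqrt(var_i * var_j) else 0
    c(MEA = mea, VAR = var, HOM = hom, CON = con, DIS = dis, ENT = ent,
      SEM = sem, COR = cor)
}

#' Plot-level texture features
#'
#' Slides the GLCM window over every pixel whose centered window lies
#' fully inside the raster and whose center pixel is masked, computes
#' the eight texture statistics per window and band, and averages them
#' over windows. Each band is quantized once over its masked pixels
#' before sliding. Returns the 48 labeled plot-level texture features
#' (8 statistics x 6 bands).
#'
#' @param image a [MultispectralImage-class].
#' @param mask logical matrix of vegetation pixels.
#' @param config a [glcmConfig()].
#' @param per_pixel if `TRUE`, return the per-window values instead of
#'   their mean: a list with a features matrix (one row per evaluated
#'   center, 48 columns) and the 0-based center coordinates.
#' @return Named numeric vector of length 48 (labels of
#'   [textureFeatureLabels()]), or the per-pixel list.
#' @export
plotTextureFeatures <- function(image, mask, config = glcmConfig(),
                                per_pixel = FALSE) {
    d <- dim(image@data)
    stopifnot(identical(dim(mask), d[1:2]))
    if (d[1] < config$window || d[2] < config$window)
        stop("scene smaller than the texture window")
    labs <- textureFeatureLabels()
    if (!per_pixel) {
        out <- numeric(0)
        for (b in seq_len(d[3])) {
            q <- quantizeBand(image@data[, , b], config$gray_levels, mask)
            res <- cpp_window_texture(q, mask, config$window,
                                      config$offset[1], config$offset[2],
                                      config$gray_levels, config$symmetric,
                                      FALSE)
            if (res$n_windows == 0)
                stop("empty ROI: no masked pixel admits a full window")
            out <- c(out, res$mean)
        }
        names(out) <- labs
        return(out)
    }
    feats <- NULL; row0 <- NULL; col0 <- NULL
    for (b in seq_len(d[3])) {
        q <- quantizeBand(image@data[, , b], config$gray_levels, mask)
        res <- cpp_window_texture(q, mask, config$window,
                                  config$offset[1], config$offset[2],
                                  config$gray_levels, config$symmetric,
                                  TRUE)
        if (res$n_windows == 0)
            stop("empty ROI: no masked pixel admits a full window")
        if (is.null(feats)) {
            feats <- matrix(NA_real_, res$n_windows, 48)
            colnames(feats) <- labs
            row0 <- res$row; col0 <- res$col
        }
        feats[, (b - 1) * 8 + 1:8] <- res$features
    }
    list(features = feats, row = row0, col = col0)
}
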