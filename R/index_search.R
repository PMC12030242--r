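#' Texture index families
#'
#' The eleven algebraic families combining two or three texture
#' features: ratio (RTI), difference (DTI), addition (ATI), normalized
#' difference (NDTI), reciprocal difference (RDTI) and reciprocal
#' addition (RATI) of a pair, and their three-feature analogues RTTI,
#' DTTI, NDTTI, RDTTI and RATTI.
#'
#' @return A `data.frame` with columns `family`, `arity` and the
#'   internal formula `code`.
#' @export
textureIndexFamilies <- function() {
    data.frame(
        family = c("RTI", "DTI", "ATI", "NDTI", "RDTI", "RATI",
                   "RTTI", "DTTI", "NDTTI", "RDTTI", "RATTI"),
        arity = c(rep(2L, 6), rep(3L, 5)),
        code = 1:11,
        stringsAsFactors = FALSE)
}

family_code <- function(family) {
    fam <- textureIndexFamilies()
    i <- match(family, fam$family)
    if (is.na(i)) stop("unknown texture index family: ", family)
    fam[i, ]
}

#' Evaluate a texture index family
#'
#' Two-feature families: `RTI = Ti/Tj`, `DTI = Ti - Tj`,
#' `ATI = Ti + Tj`, `NDTI = (Ti - Tj)/(Ti + Tj)`,
#' `RDTI = 1/Ti - 1/Tj`, `RATI = 1/Ti + 1/Tj`. Three-feature families:
#' `RTTI = Ti/Tj/Tk`, `DTTI = Ti - Tj - Tk`,
#' `NDTTI = (Ti - Tj - Tk)/(Ti + Tj + Tk)`,
#' `RDTTI = 1/Ti - 1/Tj - 1/Tk`, `RATTI = 1/Ti + 1/Tj + 1/Tk`.
#' Division by zero or other non-finite results are returned as `NA`
#' (invalid marker), never as an error.
#'
#' @param family family name (see [textureIndexFamilies()]).
#' @param Ti,Tj,Tk numeric vectors of texture feature values (`Tk` only
#'   for arity-3 families).
#' @return Numeric vector of index values with `NA` where undefined.
#' @examples
#' tiValue("NDTI", 3, 1)          # 0.5
#' ttiValue("RDTTI", 1, 2, 4)     # 0.25
#' @export
tiValue <- function(family, Ti, Tj) {
    info <- family_code(family)
    if (info$arity != 2L) stop(family, " has arity ", info$arity)
    v <- switch(family,
        RTI = Ti / Tj,
        DTI = Ti - Tj,
        ATI = Ti + Tj,
        NDTI = (Ti - Tj) / (Ti + Tj),
        RDTI = 1 / Ti - 1 / Tj,
        RATI = 1 / Ti + 1 / Tj)
    v[!is.finite(v)] <- NA_real_
    v
}

#' @rdname tiValue
#' @export
ttiValue <- function(family, Ti, Tj, Tk) {
    info <- family_code(family)
    if (info$arity != 3L) stop(family, " has arity ", info$arity)
    v <- switch(family,
        RTTI = Ti / Tj / Tk,
        DTTI = Ti - Tj - Tk,
        NDTTI = (Ti - Tj - Tk) / (Ti + Tj + Tk),
        RDTTI = 1 / Ti - 1 / Tj - 1 / Tk,
        RATTI = 1 / Ti + 1 / Tj + 1 / Tk)
    v[!is.finite(v)] <- NA_real_
    v
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation and the two-sided p-value of the t
#' statistic `r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return A list with elements `r`, `p` and `n`.
#' @export
pearsonWithP <- function(x, y) {
    stopifnot(length(x) == length(y))
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3L) stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: zero variance")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Screen candidate predictors by correlation significance
#'
#' Computes the Pearson correlation of every feature column with LAI
#' and flags the columns whose two-sided p-value falls below `alpha`
#' (default 0.05) as model inputs. Constant (zero-variance) columns are
#' recorded with `NA` correlation and are never selected. P-values are
#' not adjusted for multiplicity, matching common practice in
#' correlation-screening studies; treat selections accordingly.
#'
#' @param features numeric matrix or data.frame, one row per sample.
#' @param lai numeric vector aligned with the rows.
#' @param alpha significance level.
#' @return A `data.frame` with columns `variable`, `r`, `p`, `n`,
#'   `selected`.
#' @export
screenVariables <- function(features, lai, alpha = 0.05) {
    features <- as.matrix(features)
    stopifnot(nrow(features) == length(lai))
    res <- lapply(colnames(features), function(v) {
        x <- features[, v]
        keep <- is.finite(x) & is.finite(lai)
        if (sum(keep) < 3L || stats::sd(x[keep]) == 0 ||
            stats::sd(lai[keep]) == 0)
            return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                              n = sum(keep), selected = FALSE))
        ct <- pearsonWithP(x[keep], lai[keep])
        data.frame(variable = v, r = ct$r, p = ct$p, n = ct$n,
                   selected = ct$p < alpha)
    })
    do.call(rbind, res)
}

#' Exhaustive correlation search over one index family
#'
#' Evaluates the family at every ordered tuple (repetition allowed) of
#' the feature columns, correlates each resulting index with LAI over
#' the samples where the index is finite, and returns both the full
#' |r| tensor (48 x 48 or 48 x 48 x 48 under the default alphabet) and
#' the best tuple. Tuples retaining fewer than `min_frac` of the
#' samples, or with zero variance, are invalid (`NA` in the tensor).
#' Ties are broken toward the lexicographically first label tuple.
#'
#' @param family family name (see [textureIndexFamilies()]).
#' @param features numeric matrix of texture features (samples x
#'   labeled columns).
#' @param lai numeric vector aligned with the rows.
#' @param min_frac minimum fraction of finite samples per tuple
#'   (default 0.8).
#' @return A list with `family`, `tensor` (|r| array, `NA` = invalid),
#'   `best` (`data.frame`: family, labels, signed `r`, `abs_r`, `p`,
#'   `n_used`).
#' @export
searchFamily <- function(family, features, lai, min_frac = 0.8) {
    info <- family_code(family)
    features <- as.matrix(features)
    n <- nrow(features)
    stopifnot(n == length(lai), n >= 3L)
    labs <- colnames(features)
    if (is.null(labs)) labs <- paste0("F", seq_len(ncol(features)))
    res <- cpp_search_family(features, lai, info$code, info$arity,
                             as.integer(ceiling(min_frac * n)))
    K <- ncol(features)
    tensor <- array(res$tensor, dim = rep(K, info$arity),
                    dimnames = rep(list(labs), info$arity))
    idx <- c(res$i, res$j, if (info$arity == 3L) res$k)
    tuple <- labs[idx]
    col <- if (info$arity == 2L)
        tiValue(family, features[, idx[1]], features[, idx[2]])
    else
        ttiValue(family, features[, idx[1]], features[, idx[2]],
                 features[, idx[3]])
    ct <- pearsonWithP(col, lai)
    best <- data.frame(family = family,
                       labels = paste(tuple, collapse = ", "),
                       r = res$r, abs_r = abs(res$r), p = ct$p,
                       n_used = res$n_used, stringsAsFactors = FALSE)
    list(family = family, tensor = tensor, best = best)
}

#' Best combination per family
#'
#' Runs [searchFamily()] for every family and stacks the best tuples
#' into one table: family, maximum |r|, significance flag and the
#' feature-label combination where the maximum is located.
#'
#' @inheritParams searchFamily
#' @param families family names to search (default: all eleven).
#' @param alpha significance level for the flag column.
#' @return A `data.frame` with one row per family (columns `family`,
#'   `labels`, `r`, `abs_r`, `p`, `significant`, `n_used`).
#' @export
bestCombinationTable <- function(features, lai,
                                 families = textureIndexFamilies()$family,
                                 min_frac = 0.8, alpha = 0.05) {
    rows <- lapply(families, function(f)
        searchFamily(f, features, lai, min_frac)$best)
    out <- do.call(rbind, rows)
    out$significant <- out$p < alpha
    out[, c("family", "labels", "r", "abs_r", "p", "significant",
            "n_used")]
}

#' Heatmap of a search tensor
#'
#' Renders the |r| matrix of a two-feature family search (or one
#' fixed-third-feature slice of a three-feature tensor) as an image
#' with the 48 feature labels on both axes, mirroring the usual
#' correlation-matrix optimization figures.
#'
#' @param tensor the `tensor` element returned by [searchFamily()].
#' @param slice for arity-3 tensors, the label (or index) of the third
#'   feature defining the displayed slice.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plotSearchHeatmap <- function(tensor, slice = NULL, main = NULL, ...) {
    M <- if (length(dim(tensor)) == 3L) {
        if (is.null(slice))
            stop("a 3-d tensor needs a 'slice' (third-feature label)")
        tensor[, , slice]
    } else tensor
    labs <- rownames(M)
    n <- nrow(M)
    graphics::image(seq_len(n), seq_len(n), t(M)[, n:1],
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "Tj", ylab = "Ti",
                    main = main, ...)
    graphics::axis(1, at = seq_len(n), labels = labs, las = 2,
                   cex.axis = 0.4)
    graphics::axis(2, at = seq_len(n), labels = rev(labs), las = 2,
                   cex.axis = 0.4)
    invisible(M)
}
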