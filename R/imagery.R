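#' Vegetation masking
#'
#' Identifies canopy pixels of a plot image, standing in for the manual
#' soil and film-shadow removal applied when delineating plot regions of
#' interest. Two methods are available: thresholding the per-pixel NDVI,
#' `(NIR - R) / (NIR + R) > tau`, or passing through a mask supplied by
#' the scene generator.
#'
#' @param image a [MultispectralImage-class].
#' @param method `"ndvi-threshold"` or `"provided-mask"`.
#' @param tau NDVI threshold (default 0.3), used by `"ndvi-threshold"`.
#' @param mask logical matrix, required by `"provided-mask"`.
#' @return Logical matrix, `TRUE` on vegetation pixels.
#' @examples
#' a <- array(0.1, dim = c(5, 5, 6)); a[, , 6] <- 0.5
#' img <- MultispectralImage(a)
#' all(vegetationMask(img))    # NDVI = 0.667 everywhere
#' @export
vegetationMask <- function(image, method = c("ndvi-threshold",
                                             "provided-mask"),
                           tau = 0.3, mask = NULL) {
    method <- match.arg(method)
    if (method == "provided-mask") {
        if (is.null(mask)) stop("'provided-mask' requires a mask")
        stopifnot(identical(dim(mask), dim(image@data)[1:2]))
        return(mask)
    }
    nir <- image@data[, , 6]
    red <- image@data[, , 3]
    den <- nir + red
    ndvi <- ifelse(den > 0, (nir - red) / den, 0)
    ndvi > tau
}

#' Plot-mean reflectance over the vegetation mask
#'
#' Per-band arithmetic mean reflectance over the masked (vegetation)
#' pixels of a plot — the plot-level spectral signature from which
#' vegetation indices are computed.
#'
#' @param image a [MultispectralImage-class].
#' @param mask logical matrix of vegetation pixels.
#' @return Named numeric vector of length 6 (`R_B`, `R_G`, `R_RED`,
#'   `R_RE1`, `R_RE2`, `R_NIR`).
#' @examples
#' img <- MultispectralImage(array(0.25, dim = c(4, 4, 6)))
#' plotMeanReflectance(img, matrix(TRUE, 4, 4))
#' @export
plotMeanReflectance <- function(image, mask) {
    stopifnot(identical(dim(mask), dim(image@data)[1:2]))
    if (!any(mask))
        stop("empty ROI: no vegetation pixels in mask")
    v <- vapply(seq_len(dim(image@data)[3]),
                function(b) mean(image@data[, , b][mask]), numeric(1))
    names(v) <- c("R_B", "R_G", "R_RED", "R_RE1", "R_RE2", "R_NIR")
    v
}
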