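#' Multispectral camera band metadata
#'
#' Band definitions of the six-channel multispectral camera assumed
#' throughout the package: blue, green, red, two red-edge channels and
#' near-infrared, with their center wavelengths and bandwidths in
#' nanometres.
#'
#' @return A `data.frame` with columns `index`, `name`,
#'   `center_wavelength_nm` and `bandwidth_nm`, one row per band in
#'   spectral order.
#' @examples
#' msBandInfo()
#' @export
msBandInfo <- function() {
    data.frame(
        index = 1:6,
        name = c("B", "G", "R", "RE1", "RE2", "NIR"),
        center_wavelength_nm = c(450, 555, 660, 720, 750, 840),
        bandwidth_nm = c(35, 25, 20, 10, 15, 35),
        stringsAsFactors = FALSE
    )
}

#' Six-band reflectance image
#'
#' S4 container for a single-plot multispectral reflectance raster:
#' a rows x cols x 6 numeric array of surface reflectance in \[0, 1\]
#' together with the band metadata of [msBandInfo()].
#'
#' @slot data numeric array, rows x cols x 6, reflectance in \[0, 1\].
#' @slot bands `data.frame` of band metadata (see [msBandInfo()]).
#' @seealso [MultispectralImage()], [readMSImage()], [writeMSImage()]
#' @aliases MultispectralImage-class
#' @exportClass MultispectralImage
setClass("MultispectralImage",
    representation(data = "array", bands = "data.frame"))

setValidity("MultispectralImage", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("image data must be a 3-d array")
    if (d[3] != nrow(object@bands))
        return("number of array planes must match band metadata rows")
    if (d[3] != 6L) return("expected exactly 6 spectral bands")
    if (anyNA(object@data) || any(!is.finite(object@data)))
        return("reflectance values must be finite")
    if (min(object@data) < 0 || max(object@data) > 1)
        return("reflectance values must lie in [0, 1]")
    TRUE
})

#' Construct a MultispectralImage
#'
#' @param data numeric array rows x cols x 6 of reflectance in \[0, 1\].
#' @param bands band metadata `data.frame`; defaults to [msBandInfo()].
#' @return A [MultispectralImage-class] object.
#' @examples
#' img <- MultispectralImage(array(0.3, dim = c(8, 8, 6)))
#' dim(img)
#' @export
MultispectralImage <- function(data, bands = msBandInfo()) {
    methods::new("MultispectralImage", data = data, bands = bands)
}

#' One experimental plot sample
#'
#' S4 container tying together a plot's treatment labels, its rendered
#' (or acquired) multispectral image, the vegetation mask and the
#' ground-truth leaf area index.
#'
#' @slot plot_id character plot identifier.
#' @slot season integer season (growing-year) index.
#' @slot mulching character mulching label (e.g. `"NM"`, `"SM"`, `"FM"`).
#' @slot nitrogen numeric nitrogen application rate in kg per hectare.
#' @slot true_lai numeric leaf area index, strictly positive.
#' @slot image a [MultispectralImage-class].
#' @slot mask logical matrix of vegetation pixels, same rows/cols as the
#'   image.
#' @aliases PlotSample-class
#' @exportClass PlotSample
setClass("PlotSample",
    representation(plot_id = "character", season = "integer",
                   mulching = "character", nitrogen = "numeric",
                   true_lai = "numeric", image = "MultispectralImage",
                   mask = "matrix"))

setValidity("PlotSample", function(object) {
    d <- dim(object@image@data)
    if (!identical(dim(object@mask), d[1:2]))
        return("mask shape must equal image shape")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(object@true_lai) != 1L || object@true_lai <= 0)
        return("true_lai must be a single positive value")
    TRUE
})

#' @describeIn PlotSample-class constructor
#' @param plot_id,season,mulching,nitrogen,true_lai,image,mask see slots.
#' @export
PlotSample <- function(plot_id, season, mulching, nitrogen, true_lai,
                       image, mask) {
    methods::new("PlotSample", plot_id = as.character(plot_id),
                 season = as.integer(season),
                 mulching = as.character(mulching),
                 nitrogen = as.numeric(nitrogen),
                 true_lai = as.numeric(true_lai),
                 image = image, mask = mask)
}

#' Gray-level co-occurrence matrix
#'
#' S4 container for one normalized co-occurrence matrix over `G` gray
#' levels. `P[i, j]` is the probability of observing gray level `i - 1`
#' at a pixel and `j - 1` at its offset partner (levels are the integers
#' `0 .. G-1`).
#'
#' @slot P numeric G x G matrix of co-occurrence probabilities, summing
#'   to 1.
#' @slot levels integer, number of gray levels G.
#' @slot symmetric logical, whether reversed pairs were counted.
#' @aliases GLCM-class
#' @exportClass GLCM
setClass("GLCM",
    representation(P = "matrix", levels = "integer", symmetric = "logical"))

setValidity("GLCM", function(object) {
    if (!identical(dim(object@P), rep(object@levels, 2L)))
        return("P must be a G x G matrix")
    if (any(object@P < 0)) return("co-occurrence probabilities must be >= 0")
    if (abs(sum(object@P) - 1) > 1e-12)
        return("co-occurrence probabilities must sum to 1")
    if (object@symmetric && max(abs(object@P - t(object@P))) > 1e-12)
        return("symmetric GLCM must have a symmetric P")
    TRUE
})
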