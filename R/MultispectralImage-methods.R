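#' @describeIn MultispectralImage-class pixel array accessor
#' @param object,x a `MultispectralImage`
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname MultispectralImage-class
#' @export
setMethod("imageData", "MultispectralImage", function(object) object@data)

#' @describeIn MultispectralImage-class band metadata accessor
#' @export
setGeneric("bandInfo", function(object) standardGeneric("bandInfo"))

#' @rdname MultispectralImage-class
#' @export
setMethod("bandInfo", "MultispectralImage", function(object) object@bands)

#' @rdname MultispectralImage-class
#' @export
setMethod("dim", "MultispectralImage", function(x) dim(x@data))

setMethod("show", "MultispectralImage", function(object) {
    d <- dim(object@data)
    cat(sprintf("MultispectralImage: %d x %d pixels, %d bands (%s)\n",
                d[1], d[2], d[3],
                paste(object@bands$name, collapse = ", ")))
    cat(sprintf("  reflectance range [%.3f, %.3f]\n",
                min(object@data), max(object@data)))
})

setMethod("show", "PlotSample", function(object) {
    cat(sprintf(
        "PlotSample %s: season %d, %s + %g kg/ha N, LAI = %.3f\n",
        object@plot_id, object@season, object@mulching, object@nitrogen,
        object@true_lai))
    cat(sprintf("  image %d x %d px, vegetation cover %.1f%%\n",
                nrow(object@mask), ncol(object@mask),
                100 * mean(object@mask)))
})

#' @describeIn PlotSample-class ground-truth LAI accessor
#' @param object a `PlotSample`
#' @export
setGeneric("trueLAI", function(object) standardGeneric("trueLAI"))

#' @rdname PlotSample-class
#' @export
setMethod("trueLAI", "PlotSample", function(object) object@true_lai)

#' @describeIn PlotSample-class vegetation mask accessor
#' @export
setGeneric("vegMask", function(object) standardGeneric("vegMask"))

#' @rdname PlotSample-class
#' @export
setMethod("vegMask", "PlotSample", function(object) object@mask)

#' @describeIn PlotSample-class image accessor
#' @export
setGeneric("msImage", function(object) standardGeneric("msImage"))

#' @rdname PlotSample-class
#' @export
setMethod("msImage", "PlotSample", function(object) object@image)

#' Read and write six-band reflectance images
#'
#' Images are stored as multi-page 32-bit float TIFF files, one page per
#' band in spectral order, with a JSON sidecar (`<path>.json`) carrying
#' the band descriptions. Reading restores values to float32 precision
#' and band order; a file whose page count differs from six is rejected.
#'
#' @param path file path of the TIFF image.
#' @return `readMSImage` returns a [MultispectralImage-class];
#'   `writeMSImage` returns `path` invisibly.
#' @examples
#' img <- MultispectralImage(array(runif(8 * 8 * 6), dim = c(8, 8, 6)))
#' f <- tempfile(fileext = ".tif")
#' writeMSImage(img, f)
#' img2 <- readMSImage(f)
#' max(abs(imageData(img) - imageData(img2))) < 1e-6
#' @export
readMSImage <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 6L)
        stop("format error: expected a 6-band image, found ",
             length(pages), " band(s)")
    bands <- msBandInfo()
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        if (!is.null(meta$bands)) bands <- as.data.frame(meta$bands)
    }
    arr <- array(0, dim = c(dim(pages[[1]]), 6L))
    for (b in seq_len(6L)) arr[, , b] <- pages[[b]]
    MultispectralImage(arr, bands = bands)
}

#' @rdname readMSImage
#' @param image a [MultispectralImage-class] to write.
#' @export
writeMSImage <- function(image, path) {
    stopifnot(methods::is(image, "MultispectralImage"))
    pages <- lapply(seq_len(dim(image@data)[3]),
                    function(b) image@data[, , b])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(bands = image@bands), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read and write vegetation masks
#'
#' Masks are single-page 8-bit TIFF rasters with 1 marking vegetation.
#'
#' @param path file path of the mask TIFF.
#' @return `readMask` returns a logical matrix; `writeMask` returns
#'   `path` invisibly.
#' @export
readMask <- function(path) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0.5
}

#' @rdname readMask
#' @param mask logical matrix to write.
#' @export
writeMask <- function(mask, path) {
    tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L)
    invisible(path)
}
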