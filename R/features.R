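#' Extract plot-level features from an experiment
#'
#' Computes, for each plot sample, the plot-mean band reflectances, the
#' ten vegetation indices and the 48 GLCM texture features, and returns
#' them as a `SummarizedExperiment`: one assay `"features"` with
#' features in rows (rowData column `block` distinguishing
#' `"reflectance"`, `"VI"` and `"TF"`) and plots in columns, with the
#' treatment labels and ground-truth LAI in `colData`.
#'
#' @param samples list of [PlotSample-class] objects (e.g. from
#'   [generateExperiment()]).
#' @param config a [glcmConfig()] used for texture extraction.
#' @param mask_method `"provided-mask"` (use each sample's generator
#'   mask; default) or `"ndvi-threshold"`.
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @export
extractFeatures <- function(samples, config = glcmConfig(),
                            mask_method = c("provided-mask",
                                            "ndvi-threshold")) {
    mask_method <- match.arg(mask_method)
    cols <- lapply(samples, function(s) {
        mask <- if (mask_method == "provided-mask") s@mask else
            vegetationMask(s@image, "ndvi-threshold")
        refl <- plotMeanReflectance(s@image, mask)
        vis <- computeVIs(refl)
        tfs <- plotTextureFeatures(s@image, mask, config)
        c(refl, vis, tfs)
    })
    M <- do.call(cbind, cols)
    colnames(M) <- vapply(samples, function(s) s@plot_id, character(1))
    block <- c(rep("reflectance", 6), rep("VI", 10), rep("TF", 48))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = M),
        rowData = S4Vectors::DataFrame(block = block),
        colData = S4Vectors::DataFrame(
            plot_id = colnames(M),
            season = vapply(samples, function(s) s@season, integer(1)),
            mulching = vapply(samples, function(s) s@mulching,
                              character(1)),
            nitrogen_kg_hm2 = vapply(samples, function(s) s@nitrogen,
                                     numeric(1)),
            true_lai = vapply(samples, function(s) s@true_lai,
                              numeric(1))))
    se
}

#' Pull a feature block as a samples-by-features matrix
#'
#' @param se a `SummarizedExperiment` from [extractFeatures()].
#' @param block one of `"reflectance"`, `"VI"`, `"TF"`, or `"all"`.
#' @return Numeric matrix, one row per plot.
#' @export
featureBlock <- function(se, block = c("TF", "VI", "reflectance", "all")) {
    block <- match.arg(block)
    M <- SummarizedExperiment::assay(se, "features")
    if (block != "all") {
        keep <- SummarizedExperiment::rowData(se)$block == block
        M <- M[keep, , drop = FALSE]
    }
    t(M)
}

#' @rdname featureBlock
#' @return `sampleLAI` returns the ground-truth LAI vector.
#' @export
sampleLAI <- function(se) {
    SummarizedExperiment::colData(se)$true_lai
}
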