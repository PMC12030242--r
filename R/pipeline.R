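#' Pipeline run configuration
#'
#' Collects every setting of an end-to-end run — experiment design,
#' treatment effects, radiative model, GLCM configuration, screening
#' level, model specifications and the generator/split seeds — so that
#' a run is a pure function of its configuration. A configuration can
#' be serialized to JSON/YAML and read back with
#' [readPipelineConfig()].
#'
#' @param design an [experimentDesign()].
#' @param effects a [treatmentEffects()] model.
#' @param radiative a [canopyRadiativeModel()].
#' @param glcm a [glcmConfig()].
#' @param alpha screening significance level.
#' @param min_frac minimum finite-sample fraction in the index search.
#' @param seed generator seed.
#' @param split_seed modeling/validation split seed.
#' @param map_combination input blocks of the inversion map model.
#' @param map_model estimator of the inversion map (name).
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(design = experimentDesign(),
                           effects = treatmentEffects(),
                           radiative = canopyRadiativeModel(),
                           glcm = glcmConfig(), alpha = 0.05,
                           min_frac = 0.8, seed = 42L, split_seed = 7L,
                           map_combination = c("VIs", "TFs", "TTIs"),
                           map_model = "XGBoost") {
    structure(list(design = design, effects = effects,
                   radiative = radiative, glcm = glcm, alpha = alpha,
                   min_frac = min_frac, seed = as.integer(seed),
                   split_seed = as.integer(split_seed),
                   map_combination = map_combination,
                   map_model = map_model),
              class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path JSON or YAML file of (partial) configuration overrides;
#'   unknown keys are an error.
#' @export
readPipelineConfig <- function(path) {
    raw <- if (grepl("\\.ya?ml$", path)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("the 'yaml' package is required for YAML configs")
        yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- pipelineConfig()
    build <- list(design = experimentDesign, effects = treatmentEffects,
                  radiative = canopyRadiativeModel, glcm = glcmConfig)
    for (key in names(raw)) {
        if (!key %in% names(cfg))
            stop("unknown configuration key: ", key)
        cfg[[key]] <- if (key %in% names(build))
            do.call(build[[key]], as.list(raw[[key]])) else raw[[key]]
    }
    cfg
}

stage_log <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Pipeline stages
#'
#' File-based orchestration of the four analysis stages. Each stage
#' reads the previous stage's CSV artifacts from `outdir` and writes
#' its own; `runPipeline` chains all four. All CSV outputs are
#' byte-reproducible for a fixed configuration.
#'
#' * `runSimulate`: renders the synthetic experiment; writes per-plot
#'   image and mask TIFFs and `ground_truth.csv`.
#' * `runExtract`: computes plot-mean reflectance, vegetation indices
#'   and GLCM texture features; writes `reflectance.csv`, `vis.csv`
#'   and `tfs.csv`.
#' * `runSearch`: screens VIs and TFs and runs the exhaustive
#'   texture-index search; writes `screen_vis.csv`, `screen_tfs.csv`,
#'   `best_combinations.csv` and per-family |r| tensors
#'   (`tensor_<family>.csv`, long format).
#' * `runModel`: fits the 15 x 3 estimation grid and the inversion
#'   map; writes `grid.csv`, `scatter.csv` (validation predictions of
#'   the map model) and `lai_map.tif` for the first plot.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory.
#' @param write_tensors whether `runSearch` writes the full tensors
#'   (default `FALSE`; they are ~110k rows per three-feature family).
#' @return Each stage invisibly returns its main in-memory artifact.
#' @export
runSimulate <- function(config = pipelineConfig(), outdir) {
    ex <- generateExperiment(config$design, config$effects,
                             config$radiative, seed = config$seed,
                             dir = outdir)
    stage_log("simulate", "%d plots written to %s", nrow(ex$truth),
              outdir)
    invisible(ex)
}

#' @rdname runSimulate
#' @export
runExtract <- function(config = pipelineConfig(), outdir) {
    truth <- data.table::fread(file.path(outdir, "ground_truth.csv"),
                               data.table = FALSE)
    paths <- file.path(outdir, paste0(truth$plot_id, ".tif"))
    missing <- !file.exists(paths)
    if (any(missing))
        stop("missing scene file(s): ",
             paste(truth$plot_id[missing], collapse = ", "))
    samples <- lapply(seq_len(nrow(truth)), function(p) {
        img <- readMSImage(paths[p])
        mask <- readMask(file.path(outdir,
                                   paste0(truth$plot_id[p], "_mask.tif")))
        PlotSample(truth$plot_id[p], truth$season[p], truth$mulching[p],
                   truth$nitrogen_kg_hm2[p], truth$true_lai[p], img, mask)
    })
    se <- extractFeatures(samples, config$glcm)
    refl <- featureBlock(se, "reflectance")
    vis <- featureBlock(se, "VI")
    tfs <- featureBlock(se, "TF")
    wr <- function(M, f) data.table::fwrite(
        data.frame(plot_id = rownames(M), M, check.names = FALSE),
        file.path(outdir, f))
    wr(refl, "reflectance.csv"); wr(vis, "vis.csv"); wr(tfs, "tfs.csv")
    stage_log("extract", "%d plots x (%d VI, %d TF) columns",
              nrow(vis), ncol(vis), ncol(tfs))
    invisible(se)
}

#' @rdname runSimulate
#' @export
runSearch <- function(config = pipelineConfig(), outdir,
                      write_tensors = FALSE) {
    truth <- data.table::fread(file.path(outdir, "ground_truth.csv"),
                               data.table = FALSE)
    vis <- as.matrix(data.table::fread(file.path(outdir, "vis.csv"),
                                       data.table = FALSE)[, -1])
    tfs <- as.matrix(data.table::fread(file.path(outdir, "tfs.csv"),
                                       data.table = FALSE)[, -1])
    lai <- truth$true_lai
    data.table::fwrite(screenVariables(vis, lai, config$alpha),
                       file.path(outdir, "screen_vis.csv"))
    data.table::fwrite(screenVariables(tfs, lai, config$alpha),
                       file.path(outdir, "screen_tfs.csv"))
    best <- bestCombinationTable(tfs, lai, min_frac = config$min_frac,
                                 alpha = config$alpha)
    data.table::fwrite(best, file.path(outdir, "best_combinations.csv"))
    if (write_tensors) {
        for (f in textureIndexFamilies()$family) {
            sr <- searchFamily(f, tfs, lai, config$min_frac)
            tensor <- sr$tensor
            long <- data.frame(which(!is.na(tensor), arr.ind = TRUE),
                               abs_r = tensor[!is.na(tensor)])
            data.table::fwrite(long,
                               file.path(outdir,
                                         paste0("tensor_", f, ".csv")))
        }
    }
    stage_log("search", "11 families searched; best |r| = %.3f (%s)",
              max(best$abs_r), best$family[which.max(best$abs_r)])
    invisible(best)
}

#' @rdname runSimulate
#' @export
runModel <- function(config = pipelineConfig(), outdir) {
    truth <- data.table::fread(file.path(outdir, "ground_truth.csv"),
                               data.table = FALSE)
    vis <- as.matrix(data.table::fread(file.path(outdir, "vis.csv"),
                                       data.table = FALSE)[, -1])
    tfs <- as.matrix(data.table::fread(file.path(outdir, "tfs.csv"),
                                       data.table = FALSE)[, -1])
    rownames(vis) <- rownames(tfs) <- truth$plot_id
    lai <- truth$true_lai
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = t(cbind(vis, tfs))),
        rowData = S4Vectors::DataFrame(
            block = c(rep("VI", ncol(vis)), rep("TF", ncol(tfs)))),
        colData = S4Vectors::DataFrame(plot_id = truth$plot_id,
                                       true_lai = lai))
    inputs <- buildModelInputs(se, config$alpha, config$min_frac)
    split <- splitDataset(length(lai), seed = config$split_seed)
    grid <- runGrid(inputs, lai, split)
    data.table::fwrite(grid, file.path(outdir, "grid.csv"))
    model <- trainLAIModel(inputs, lai, config$map_combination,
                           modelSpec(config$map_model),
                           rows = split$modeling, config = config$glcm)
    X <- assemble_X(inputs, config$map_combination)
    scatter <- data.frame(
        plot_id = truth$plot_id[split$validation],
        true_lai = lai[split$validation],
        predicted_lai = predictLAI(model$fit,
                                   X[split$validation, , drop = FALSE]))
    data.table::fwrite(scatter, file.path(outdir, "scatter.csv"))
    first <- truth$plot_id[1]
    img <- readMSImage(file.path(outdir, paste0(first, ".tif")))
    mask <- readMask(file.path(outdir, paste0(first, "_mask.tif")))
    lmap <- predictMap(img, mask, model)
    lmap[is.na(lmap)] <- 0            # no-data encoded as 0
    tiff::writeTIFF(pmin(pmax(lmap / 10, 0), 1),   # store LAI / 10
                    file.path(outdir, "lai_map.tif"),
                    bits.per.sample = 32L)
    stage_log("model", "45-cell grid written; best validation R2 = %.3f",
              max(grid$R2_val, na.rm = TRUE))
    invisible(grid)
}

#' @rdname runSimulate
#' @export
runPipeline <- function(config = pipelineConfig(), outdir) {
    runSimulate(config, outdir)
    runExtract(config, outdir)
    runSearch(config, outdir)
    runModel(config, outdir)
}
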