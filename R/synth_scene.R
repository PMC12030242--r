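# Synthetic split-plot scene generator: treatment-structured LAI with a
# saturating nitrogen dose-response, and per-plot six-band rasters whose
# mean reflectance and local texture are both driven by the latent LAI.

local_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
    force(code)
}

derive_seed <- function(seed, index) {
    ((as.numeric(seed) %% 97651) * 1000003 + as.numeric(index) * 7919) %%
        2147483629
}

#' Split-plot experiment design
#'
#' Describes the factorial layout emulated by the scene generator:
#' mulching methods as main plots, nitrogen application rates as
#' subplots, replicated within each of several growing seasons. The
#' defaults give 3 x 5 x 3 = 45 plots per season over 2 seasons
#' (90 samples).
#'
#' @param mulching_levels ordered character labels; defaults `NM`
#'   (no mulching), `SM` (straw), `FM` (plastic film).
#' @param nitrogen_rates nitrogen application rates in kg per hectare.
#' @param replicates replicate count per treatment per season.
#' @param seasons number of growing seasons.
#' @param plot_shape `c(rows, cols)` of each rendered plot raster in
#'   pixels.
#' @return A list of class `ExperimentDesign`.
#' @export
experimentDesign <- function(mulching_levels = c("NM", "SM", "FM"),
                             nitrogen_rates = c(0, 70, 140, 210, 280),
                             replicates = 3L, seasons = 2L,
                             plot_shape = c(48L, 48L)) {
    if (length(mulching_levels) < 1L || length(nitrogen_rates) < 1L)
        stop("invalid design: empty factor list")
    replicates <- as.integer(replicates)
    seasons <- as.integer(seasons)
    if (replicates < 1L || seasons < 1L)
        stop("invalid design: counts must be >= 1")
    structure(list(mulching_levels = mulching_levels,
                   nitrogen_rates = nitrogen_rates,
                   replicates = replicates, seasons = seasons,
                   plot_shape = as.integer(plot_shape)),
              class = "ExperimentDesign")
}

#' Treatment effect model for the latent LAI
#'
#' Additive LAI model: a baseline, an offset per mulching level, a
#' saturating nitrogen dose-response with a linear decline beyond the
#' optimum rate, a shared per-season offset and independent per-plot
#' noise, truncated below at a small positive floor. The defaults are
#' calibrated so that the expected LAI of the film-mulch + 210 kg/ha
#' treatment (the study optimum) is 2.97, and the treatment means span
#' roughly 0.8-3.0 before noise.
#'
#' @param base_lai baseline LAI of the unmulched, unfertilized plots.
#' @param mulch_effects named additive offsets per mulching level.
#' @param n_max_gain asymptotic LAI gain of the nitrogen response.
#' @param n_half nitrogen rate (kg/ha) at which ~63% of the gain is
#'   reached.
#' @param n_optimum rate beyond which over-fertilization depresses LAI.
#' @param n_decline LAI loss per kg/ha beyond the optimum.
#' @param season_sd standard deviation of the shared season offset.
#' @param plot_sd standard deviation of independent per-plot noise.
#' @param lai_floor truncation floor keeping LAI strictly positive.
#' @return A list of class `TreatmentEffectModel`.
#' @export
treatmentEffects <- function(base_lai = 0.804,
                             mulch_effects = c(NM = 0, SM = 0.35, FM = 0.85),
                             n_max_gain = 1.5, n_half = 100,
                             n_optimum = 210, n_decline = 0.0015,
                             season_sd = 0.2, plot_sd = 0.25,
                             lai_floor = 0.05) {
    structure(list(base_lai = base_lai, mulch_effects = mulch_effects,
                   n_max_gain = n_max_gain, n_half = n_half,
                   n_optimum = n_optimum, n_decline = n_decline,
                   season_sd = season_sd, plot_sd = plot_sd,
                   lai_floor = lai_floor),
              class = "TreatmentEffectModel")
}

#' @rdname treatmentEffects
#' @param nitrogen nitrogen rate(s) in kg/ha.
#' @param effects a `TreatmentEffectModel`.
#' @return `nitrogenResponse` returns the expected LAI gain at the given
#'   rate(s); `expectedLAI` the noise-free expected LAI of a treatment.
#' @export
nitrogenResponse <- function(nitrogen, effects = treatmentEffects()) {
    effects$n_max_gain * (1 - exp(-nitrogen / effects$n_half)) -
        effects$n_decline * pmax(0, nitrogen - effects$n_optimum)
}

#' @rdname treatmentEffects
#' @param mulching mulching level label(s).
#' @export
expectedLAI <- function(mulching, nitrogen, effects = treatmentEffects()) {
    effects$base_lai + unname(effects$mulch_effects[mulching]) +
        nitrogenResponse(nitrogen, effects)
}

#' Canopy radiative model
#'
#' Statistical model of per-band plot reflectance as a function of LAI.
#' The mean canopy reflectance of band b follows a Beer-Lambert-style
#' saturating mixture of soil and leaf reflectance,
#' `mu_b(L) = soil_b + (leaf_b - soil_b) (1 - exp(-k_b L))`, which
#' reproduces the characteristic decrease of red and increase of
#' near-infrared reflectance with canopy development. Local texture is
#' a spatially correlated Gaussian field whose standard deviation grows
#' with LAI, and canopy cover (the vegetation-mask fraction) saturates
#' with LAI. Plot-to-plot nuisance variation enters as a multiplicative
#' per-band jitter of the leaf asymptote and of the texture amplitude.
#'
#' @param soil_reflectance per-band bare soil reflectance.
#' @param leaf_reflectance per-band dense-canopy asymptotic reflectance.
#' @param extinction_k per-band saturation exponents.
#' @param correlation_length Gaussian smoothing sigma in pixels.
#' @param cover_k cover saturation rate: cover = 1 - exp(-cover_k * L).
#' @param tex_sd_base per-band texture SD at vanishing LAI.
#' @param tex_sd_max per-band asymptotic texture SD.
#' @param tex_k texture SD saturation rate in LAI units.
#' @param tex_jitter_sd lognormal SD of the per-plot texture amplitude.
#' @param plot_band_sd lognormal SD of the per-plot, per-band leaf
#'   asymptote jitter (spectral nuisance not explained by LAI).
#' @param soil_sd texture SD of non-canopy (soil) pixels.
#' @return A list of class `CanopyRadiativeModel`.
#' @export
canopyRadiativeModel <- function(
        soil_reflectance = c(0.06, 0.09, 0.12, 0.15, 0.17, 0.20),
        leaf_reflectance = c(0.04, 0.12, 0.05, 0.28, 0.40, 0.55),
        extinction_k = c(0.7, 0.7, 0.8, 0.6, 0.6, 0.75),
        correlation_length = 2, cover_k = 0.8,
        tex_sd_base = rep(0.01, 6),
        tex_sd_max = c(0.03, 0.03, 0.03, 0.05, 0.05, 0.06),
        tex_k = 0.7, tex_jitter_sd = 0.15, plot_band_sd = 0.10,
        soil_sd = 0.01) {
    stopifnot(length(soil_reflectance) == 6, length(leaf_reflectance) == 6,
              length(extinction_k) == 6,
              all(soil_reflectance >= 0 & soil_reflectance <= 1),
              all(leaf_reflectance >= 0 & leaf_reflectance <= 1))
    structure(list(soil_reflectance = soil_reflectance,
                   leaf_reflectance = leaf_reflectance,
                   extinction_k = extinction_k,
                   correlation_length = correlation_length,
                   cover_k = cover_k,
                   tex_sd_base = rep_len(tex_sd_base, 6),
                   tex_sd_max = rep_len(tex_sd_max, 6),
                   tex_k = tex_k, tex_jitter_sd = tex_jitter_sd,
                   plot_band_sd = plot_band_sd, soil_sd = soil_sd),
              class = "CanopyRadiativeModel")
}

#' @rdname canopyRadiativeModel
#' @param radiative a `CanopyRadiativeModel`.
#' @param lai leaf area index value(s).
#' @return `bandMeanReflectance` returns the 6 mean canopy reflectances
#'   `mu_b(lai)` (a matrix for vector `lai`); `coverFraction` the canopy
#'   cover fraction; `textureSD` the per-band local reflectance SD.
#' @export
bandMeanReflectance <- function(radiative, lai) {
    s <- radiative$soil_reflectance
    l <- radiative$leaf_reflectance
    k <- radiative$extinction_k
    out <- t(vapply(lai, function(L) s + (l - s) * (1 - exp(-k * L)),
                    numeric(6)))
    colnames(out) <- msBandInfo()$name
    if (length(lai) == 1L) out[1, ] else out
}

#' @rdname canopyRadiativeModel
#' @export
coverFraction <- function(radiative, lai) {
    pmin(1, 1 - exp(-radiative$cover_k * lai))
}

#' @rdname canopyRadiativeModel
#' @export
textureSD <- function(radiative, lai) {
    radiative$tex_sd_base +
        (radiative$tex_sd_max - radiative$tex_sd_base) *
        (1 - exp(-radiative$tex_k * lai))
}

#' Enumerate plot specifications of a design
#'
#' Expands the factorial design into one specification per
#' (season, mulching, nitrogen, replicate) in deterministic order.
#'
#' @param design an [experimentDesign()].
#' @return A `data.frame` with columns `plot_id`, `season`, `mulching`,
#'   `nitrogen_kg_hm2`, `replicate`; `prod(design factors)` rows (90
#'   under defaults).
#' @examples
#' nrow(buildDesign(experimentDesign()))   # 90
#' @export
buildDesign <- function(design = experimentDesign()) {
    stopifnot(inherits(design, "ExperimentDesign"))
    g <- expand.grid(replicate = seq_len(design$replicates),
                     nitrogen_kg_hm2 = design$nitrogen_rates,
                     mulching = design$mulching_levels,
                     season = seq_len(design$seasons),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("season", "mulching", "nitrogen_kg_hm2", "replicate")]
    g$plot_id <- sprintf("S%d_%s_N%03d_R%d", g$season, g$mulching,
                         g$nitrogen_kg_hm2, g$replicate)
    g[, c("plot_id", "season", "mulching", "nitrogen_kg_hm2", "replicate")]
}

#' Draw a ground-truth LAI for one plot
#'
#' LAI = baseline + mulch effect + nitrogen response + season offset +
#' plot noise, truncated below at the model floor. Reproducible under
#' `seed`; when `season_offset` is `NULL` the season term is drawn from
#' a seed derived from (`seed`, season) so that plots of the same season
#' share it.
#'
#' @param spec one row of [buildDesign()] (or a list with `mulching`,
#'   `nitrogen_kg_hm2`, `season`).
#' @param effects a [treatmentEffects()] model.
#' @param seed integer seed.
#' @param season_offset optional pre-drawn season offset.
#' @return A single positive LAI value.
#' @export
drawLAI <- function(spec, effects = treatmentEffects(), seed = 1L,
                    season_offset = NULL) {
    mu <- expectedLAI(spec$mulching, spec$nitrogen_kg_hm2, effects)
    if (is.null(season_offset)) {
        season_offset <- local_seed(derive_seed(seed, 500000 + spec$season),
                                    rnorm(1, 0, effects$season_sd))
    }
    noise <- local_seed(seed, rnorm(1, 0, effects$plot_sd))
    max(effects$lai_floor, mu + season_offset + noise)
}

# Correlated standard-normal field: Gaussian-smoothed white noise,
# empirically re-standardized to zero mean and unit SD.
smooth_field <- function(nr, nc, sigma) {
    z <- matrix(rnorm(nr * nc), nr, nc)
    if (sigma <= 0) return(z)
    kern <- function(n) {
        K <- outer(seq_len(n), seq_len(n),
                   function(i, j) stats::dnorm(i - j, sd = sigma))
        K / rowSums(K)
    }
    s <- kern(nr) %*% z %*% t(kern(nc))
    sd_s <- stats::sd(as.vector(s))
    if (sd_s < 1e-12) return(matrix(0, nr, nc))
    (s - mean(s)) / sd_s
}

#' Render one plot scene
#'
#' Draws a six-band reflectance raster for a plot of known LAI. Canopy
#' pixels follow a spatially correlated Gaussian field around the mean
#' canopy reflectance `mu_b(LAI)` with the model's LAI-dependent texture
#' SD; non-canopy pixels are soil. The canopy/soil assignment is a
#' thresholded correlated field realizing the model's cover fraction.
#' All values are clipped to \[0, 1\]. Bit-reproducible under `seed`.
#'
#' @param true_lai positive LAI.
#' @param radiative a [canopyRadiativeModel()].
#' @param shape `c(rows, cols)` in pixels.
#' @param seed integer seed.
#' @param min_window smallest texture window the scene must support
#'   (default 7); smaller shapes are an error.
#' @return A list with elements `image` ([MultispectralImage-class]) and
#'   `mask` (logical matrix of canopy pixels).
#' @export
renderScene <- function(true_lai, radiative = canopyRadiativeModel(),
                        shape = c(48L, 48L), seed = 1L, min_window = 7L) {
    stopifnot(true_lai > 0)
    nr <- shape[1]; nc <- shape[2]
    if (nr < min_window || nc < min_window)
        stop("scene too small for the texture window")
    local_seed(seed, {
        cover <- coverFraction(radiative, true_lai)
        cov_field <- smooth_field(nr, nc, radiative$correlation_length)
        mask <- if (cover >= 1) matrix(TRUE, nr, nc) else
            cov_field >= stats::quantile(cov_field, 1 - cover)
        mu <- bandMeanReflectance(radiative, true_lai)
        leaf_jit <- exp(rnorm(6, 0, radiative$plot_band_sd))
        mu_jit <- radiative$soil_reflectance +
            (mu - radiative$soil_reflectance) * leaf_jit
        sd_b <- textureSD(radiative, true_lai) *
            exp(rnorm(1, 0, radiative$tex_jitter_sd))
        arr <- array(0, dim = c(nr, nc, 6))
        for (b in 1:6) {
            z <- smooth_field(nr, nc, radiative$correlation_length)
            canopy <- mu_jit[b] + sd_b[b] * z
            soil <- radiative$soil_reflectance[b] + radiative$soil_sd * z
            plane <- ifelse(mask, canopy, soil)
            arr[, , b] <- pmin(1, pmax(0, plane))
        }
        list(image = MultispectralImage(arr), mask = mask)
    })
}

#' Generate a full synthetic experiment
#'
#' Runs the generator over every plot of the design: draws each plot's
#' ground-truth LAI from the treatment model and renders its scene.
#' Optionally writes one multiband TIFF and one mask TIFF per plot plus
#' a ground-truth CSV to `dir`.
#'
#' @param design an [experimentDesign()].
#' @param effects a [treatmentEffects()] model.
#' @param radiative a [canopyRadiativeModel()].
#' @param seed integer seed; the run is a pure function of
#'   (configuration, seed).
#' @param dir optional output directory; created if missing.
#' @return A list with `samples` (list of [PlotSample-class]) and
#'   `truth` (`data.frame`: `plot_id`, `season`, `mulching`,
#'   `nitrogen_kg_hm2`, `true_lai`).
#' @examples
#' \donttest{
#' ex <- generateExperiment(seed = 42)
#' nrow(ex$truth)   # 90
#' }
#' @export
generateExperiment <- function(design = experimentDesign(),
                               effects = treatmentEffects(),
                               radiative = canopyRadiativeModel(),
                               seed = 42L, dir = NULL) {
    specs <- buildDesign(design)
    n <- nrow(specs)
    season_offsets <- vapply(seq_len(design$seasons), function(s)
        local_seed(derive_seed(seed, 500000 + s),
                   rnorm(1, 0, effects$season_sd)), numeric(1))
    samples <- vector("list", n)
    lai <- numeric(n)
    for (p in seq_len(n)) {
        spec <- specs[p, ]
        lai[p] <- drawLAI(spec, effects, seed = derive_seed(seed, p),
                          season_offset = season_offsets[spec$season])
        sc <- renderScene(lai[p], radiative, design$plot_shape,
                          seed = derive_seed(seed, 100000 + p))
        samples[[p]] <- PlotSample(spec$plot_id, spec$season,
                                   spec$mulching, spec$nitrogen_kg_hm2,
                                   lai[p], sc$image, sc$mask)
    }
    truth <- data.frame(plot_id = specs$plot_id, season = specs$season,
                        mulching = specs$mulching,
                        nitrogen_kg_hm2 = specs$nitrogen_kg_hm2,
                        true_lai = lai, stringsAsFactors = FALSE)
    if (!is.null(dir)) {
        if (!dir.exists(dir) &&
            !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
            stop("cannot create output directory: ", dir)
        for (p in seq_len(n)) {
            s <- samples[[p]]
            writeMSImage(s@image, file.path(dir, paste0(s@plot_id, ".tif")))
            writeMask(s@mask, file.path(dir, paste0(s@plot_id, "_mask.tif")))
        }
        data.table::fwrite(truth, file.path(dir, "ground_truth.csv"))
    }
    list(samples = samples, truth = truth)
}
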