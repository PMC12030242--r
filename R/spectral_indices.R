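#' Vegetation index names
#'
#' @return Character vector of the ten vegetation index abbreviations.
#' @export
vegetationIndexNames <- function() {
    c("SAVI", "EVI", "MSR", "DVI", "CIgreen", "RDVI", "TVI", "GNDVI",
      "VDVI", "CVI")
}

#' Compute the ten vegetation indices
#'
#' Evaluates the classical vegetation indices from plot-mean band
#' reflectance:
#' \deqn{SAVI = 1.5 (NIR - R) / (NIR + R + 0.5)}
#' \deqn{EVI = 2.5 (NIR - R) / (NIR + 6R - 7.5B + 1)}
#' \deqn{MSR = (NIR/R - 1) / \sqrt{NIR/R + 1}}
#' \deqn{DVI = NIR - R, \quad CIgreen = NIR/G - 1}
#' \deqn{RDVI = (NIR - R) / \sqrt{NIR + R}}
#' \deqn{TVI = \sqrt{(NIR - R)/(NIR + R) + 0.5}}
#' \deqn{GNDVI = (NIR - G)/(NIR + G)}
#' \deqn{VDVI = (2G - R - B)/(2G + R + B)}
#' \deqn{CVI = (2NIR - R - G)/(2NIR + R + G)}
#'
#' Indices whose denominator vanishes for a given record are returned
#' as `NA` (undefined for that index only).
#'
#' @param record named numeric vector as returned by
#'   [plotMeanReflectance()] (`R_B`, `R_G`, `R_RED`, `R_RE1`, `R_RE2`,
#'   `R_NIR`), or a data.frame/matrix of such rows.
#' @return Named numeric vector of the 10 indices (or a matrix with one
#'   row per input row).
#' @examples
#' computeVIs(c(R_B = 0.05, R_G = 0.1, R_RED = 0.1, R_RE1 = 0.3,
#'              R_RE2 = 0.4, R_NIR = 0.5))
#' @export
computeVIs <- function(record) {
    if (is.data.frame(record) || is.matrix(record)) {
        out <- t(apply(record, 1, computeVIs))
        rownames(out) <- rownames(record)
        return(out)
    }
    B <- record[["R_B"]]; G <- record[["R_G"]]; R <- record[["R_RED"]]
    NIR <- record[["R_NIR"]]
    safe <- function(num, den) if (abs(den) < 1e-12) NA_real_ else num / den
    savi <- safe(1.5 * (NIR - R), NIR + R + 0.5)
    evi <- safe(2.5 * (NIR - R), NIR + 6 * R - 7.5 * B + 1)
    msr <- if (R < 1e-12) NA_real_ else (NIR / R - 1) / sqrt(NIR / R + 1)
    dvi <- NIR - R
    cig <- if (G < 1e-12) NA_real_ else NIR / G - 1
    rdvi <- if (NIR + R < 1e-12) NA_real_ else (NIR - R) / sqrt(NIR + R)
    ndvi <- safe(NIR - R, NIR + R)
    tvi <- if (is.na(ndvi) || ndvi + 0.5 < 0) NA_real_ else sqrt(ndvi + 0.5)
    gndvi <- safe(NIR - G, NIR + G)
    vdvi <- safe(2 * G - R - B, 2 * G + R + B)
    cvi <- safe(2 * NIR - R - G, 2 * NIR + R + G)
    c(SAVI = savi, EVI = evi, MSR = msr, DVI = dvi, CIgreen = cig,
      RDVI = rdvi, TVI = tvi, GNDVI = gndvi, VDVI = vdvi, CVI = cvi)
}
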