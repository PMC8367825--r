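#' Optical properties of the two-chromophore tissue model
#'
#' Diffuse reflectance at the three reflectance bands is modelled with a
#' modified Beer-Lambert law over the two hemoglobin chromophores:
#'
#'   R(band) = k(band) * exp(-d * (eps(band, HbO2) * C_HbO2 +
#'                                 eps(band, Hb)  * C_Hb))
#'
#' where `eps` are extinction coefficients (cm^-1 mM^-1), `d` is a single
#' effective mean photon path length (cm) shared by all bands, and `k(band)`
#' is the dimensionless reflectance of bloodless tissue. Absolute
#' concentrations in mM are meaningful only relative to the configured
#' `k` and `d`; ratio-based statistics are independent of a common `k`
#' scale.
#'
#' Default extinction values are rounded compiled hemoglobin coefficients.
#' They satisfy the physiological ordering used throughout: 545 nm is a
#' strong, nearly isosbestic absorption band, while at 610 nm Hb absorbs
#' 7 to 8 times more strongly than HbO2, making R610 an HbO2-insensitive
#' reference.
#'
#' @param extinction Numeric matrix with rows `R545`, `R575`, `R610` and
#'   columns `HbO2`, `Hb`, in cm^-1 mM^-1.
#' @param baseline Named numeric vector `k(band)` in `(0, 1]` for the three
#'   reflectance bands.
#' @param path_length Effective photon path length `d` in cm.
#' @return An object of class `optical_properties`.
#' @export
#' @examples
#' optical_properties()
optical_properties <- function(extinction = default_extinction(),
                               baseline = c(R545 = 0.9, R575 = 0.9, R610 = 0.9),
                               path_length = 0.1) {
  bands <- reflectance_bands()
  extinction <- as.matrix(extinction)
  if (!all(bands %in% rownames(extinction)) ||
      !all(c("HbO2", "Hb") %in% colnames(extinction))) {
    stop("extinction needs rows R545/R575/R610 and columns HbO2/Hb",
         call. = FALSE)
  }
  extinction <- extinction[bands, c("HbO2", "Hb")]
  if (any(extinction < 0)) stop("extinction coefficients must be >= 0",
                                call. = FALSE)
  if (extinction["R545", "HbO2"] <= extinction["R610", "HbO2"]) {
    stop("HbO2 extinction must be larger at 545 nm than at 610 nm",
         call. = FALSE)
  }
  hb_ratio <- extinction["R610", "Hb"] / extinction["R610", "HbO2"]
  if (hb_ratio < 7 || hb_ratio > 8) {
    stop("Hb/HbO2 extinction ratio at 610 nm must lie in [7, 8]; got ",
         signif(hb_ratio, 4), call. = FALSE)
  }
  baseline <- baseline[bands]
  if (anyNA(baseline) || any(baseline <= 0 | baseline > 1)) {
    stop("baseline k(band) must lie in (0, 1] for every reflectance band",
         call. = FALSE)
  }
  if (path_length <= 0) stop("path_length must be > 0", call. = FALSE)
  structure(
    list(extinction = extinction, baseline = baseline,
         path_length = path_length),
    class = "optical_properties"
  )
}

#' @rdname optical_properties
#' @export
default_extinction <- function() {
  matrix(
    c(52.0, 48.0,
      60.0, 34.0,
      1.3, 9.8),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("R545", "R575", "R610"), c("HbO2", "Hb"))
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("<optical_properties> d =", x$path_length, "cm\n")
  cat("  baseline k:", paste(names(x$baseline), x$baseline, sep = "=",
                             collapse = " "), "\n")
  print(x$extinction)
  invisible(x)
}

# oxygenation-weighted extinction g(band) = eps_HbO2 * StO2 + eps_Hb * (1 - StO2)
weighted_extinction <- function(props, band, sto2) {
  props$extinction[band, "HbO2"] * sto2 +
    props$extinction[band, "Hb"] * (1 - sto2)
}
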