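#' Spectral bands of the four-band intraoral imager
#'
#' The imaging head illuminates tissue with four narrowband LEDs and captures
#' one monochrome frame per band: violet fluorescence excitation at 405 nm
#' (`F405`) and diffuse reflectance at 545, 575 and 610 nm (`R545`, `R575`,
#' `R610`). 545 nm sits on a strong oxyhemoglobin absorption band, 575 nm on
#' the second HbO2 band (used for the inflammation ratio), and 610 nm is an
#' HbO2-insensitive reference wavelength where deoxyhemoglobin dominates
#' absorption.
#'
#' @return A tibble with columns `band`, `center_wavelength` (nm) and
#'   `modality` (`"fluorescence"` or `"reflectance"`).
#' @export
#' @examples
#' spectral_bands()
spectral_bands <- function() {
  tibble::tribble(
    ~band,  ~center_wavelength, ~modality,
    "F405", 405, "fluorescence",
    "R545", 545, "reflectance",
    "R575", 575, "reflectance",
    "R610", 610, "reflectance"
  )
}

band_names <- function() spectral_bands()$band

reflectance_bands <- function() {
  b <- spectral_bands()
  b$band[b$modality == "reflectance"]
}

#' Oral anatomical sites and their keratinization grouping
#'
#' Oral mucosa is grouped by surface keratin layer: keratinized sites
#' (gingiva, vermillion border, dorsal tongue, hard palate, alveolus) and
#' non-keratinized sites (buccal mucosa, lateral/ventral tongue, floor of
#' mouth, inner lip, sulcus). Optical properties differ between the two
#' groups, so classifiers are trained per group (or per site region, e.g.
#' pooled left/right buccal mucosa).
#'
#' @return A tibble with columns `site` (controlled vocabulary term),
#'   `region` (site with laterality stripped) and `group`
#'   (`"keratinized"` or `"non_keratinized"`).
#' @export
#' @examples
#' oral_sites()
#' site_group("buccal_mucosa_left")
oral_sites <- function() {
  tibble::tribble(
    ~site,                ~region,           ~group,
    "gingiva",            "gingiva",         "keratinized",
    "vermillion_border",  "vermillion_border", "keratinized",
    "dorsal_tongue",      "dorsal_tongue",   "keratinized",
    "hard_palate",        "hard_palate",     "keratinized",
    "alveolus",           "alveolus",        "keratinized",
    "buccal_mucosa_left", "buccal_mucosa",   "non_keratinized",
    "buccal_mucosa_right", "buccal_mucosa",  "non_keratinized",
    "lateral_tongue",     "lateral_tongue",  "non_keratinized",
    "ventral_tongue",     "ventral_tongue",  "non_keratinized",
    "floor_of_mouth",     "floor_of_mouth",  "non_keratinized",
    "inner_lip",          "inner_lip",       "non_keratinized",
    "sulcus",             "sulcus",          "non_keratinized"
  )
}

#' @rdname oral_sites
#' @param site Character vector of anatomical-site vocabulary terms.
#' @export
site_group <- function(site) {
  tab <- oral_sites()
  idx <- match(site, tab$site)
  if (anyNA(idx)) {
    stop("unknown anatomical site(s): ",
         paste(unique(site[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tab$group[idx]
}

#' @rdname oral_sites
#' @export
site_region <- function(site) {
  tab <- oral_sites()
  idx <- match(site, tab$site)
  if (anyNA(idx)) {
    stop("unknown anatomical site(s): ",
         paste(unique(site[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tab$region[idx]
}
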