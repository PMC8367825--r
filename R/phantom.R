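#' Describe a synthetic oral-mucosa scene
#'
#' The phantom stands in for clinical captures: a homogeneous mucosal
#' background with known hemoglobin concentrations, elliptical lesions whose
#' hotspot R610/R545 ratio and oxygen saturation are prescribed,
#' inflammation patches with elevated deoxyhemoglobin, circular specular
#' spots (saturated pixels), and a fluorescence channel with lesion
#' autofluorescence loss plus a protoporphyrin-IX gain term. Every generated
#' capture comes with per-pixel ground truth for parameter-recovery tests.
#'
#' Lesion concentration profiles are flat inside the ellipse with a 2-pixel
#' raised-cosine taper at the edge, so the hotspot statistic is well defined.
#'
#' @param width,height Image size in pixels.
#' @param background Named vector `c(HbO2 = , Hb = )` in mM. Default `NULL`
#'   derives the background from a target R610/R545 ratio of 1.41 (the
#'   healthy class median) at StO2 0.98.
#' @param lesions List of lesions, each
#'   `list(center = c(x, y), axes = c(a, b), grade, target_ratio, sto2)`;
#'   `grade` is `"OPML"` or `"SCC"`; `sto2` defaults to 0.85 (OPML) or
#'   0.70 (SCC), reflecting tumor hypoxia.
#' @param inflammation_patches List of
#'   `list(center, axes, hb_multiplier)` entries scaling `C_Hb`.
#' @param specular_spots List of `list(center, radius)` circles rendered as
#'   saturated white in all reflectance bands.
#' @param fluorescence `list(base_level, lesion_loss_fraction, ppix_gain)`
#'   controlling the F405 channel.
#' @param noise_sigma Additive Gaussian noise std on normalized intensity.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param anatomical_site Site term attached to generated captures.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(width = 64, height = 64,
                          background = NULL,
                          lesions = list(),
                          inflammation_patches = list(),
                          specular_spots = list(),
                          fluorescence = list(base_level = 0.6,
                                              lesion_loss_fraction = 0.4,
                                              ppix_gain = 0.15),
                          noise_sigma = 0.005,
                          seed = 1L,
                          anatomical_site = "buccal_mucosa_left") {
  stopifnot(width >= 1, height >= 1, noise_sigma >= 0)
  fl <- modifyList(list(base_level = 0.6, lesion_loss_fraction = 0.4,
                        ppix_gain = 0.15), fluorescence)
  stopifnot(fl$base_level > 0, fl$base_level <= 1,
            fl$lesion_loss_fraction >= 0, fl$lesion_loss_fraction <= 1,
            fl$ppix_gain >= 0)
  default_sto2 <- c(normal = 0.98, OPML = 0.85, SCC = 0.70)
  lesions <- lapply(lesions, function(l) {
    stopifnot(l$grade %in% c("OPML", "SCC"), l$target_ratio > 0)
    if (is.null(l$sto2)) l$sto2 <- default_sto2[[l$grade]]
    stopifnot(l$sto2 >= 0, l$sto2 <= 1)
    check_ellipse(l$center, l$axes, width, height)
    l
  })
  inflammation_patches <- lapply(inflammation_patches, function(p) {
    if (is.null(p$hb_multiplier)) p$hb_multiplier <- 2
    stopifnot(p$hb_multiplier >= 0)
    check_ellipse(p$center, p$axes, width, height)
    p
  })
  structure(
    list(width = width, height = height, background = background,
         lesions = lesions, inflammation_patches = inflammation_patches,
         specular_spots = specular_spots, fluorescence = fl,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         anatomical_site = anatomical_site),
    class = "phantom_scene"
  )
}

check_ellipse <- function(center, axes, width, height) {
  stopifnot(length(center) == 2, length(axes) == 2, all(axes > 0))
  if (center[1] - axes[1] < 0 || center[1] + axes[1] > width - 1 ||
      center[2] - axes[2] < 0 || center[2] + axes[2] > height - 1) {
    stop("ellipse extends outside image bounds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Invert a target band ratio into chromophore concentrations
#'
#' Solves the forward model analytically for the total hemoglobin
#' concentration that produces a requested noise-free R610/R545 ratio at a
#' fixed oxygen saturation, then splits it into the two chromophores:
#' `tHb = ln(ratio * k545 / k610) / (d * (g545 - g610))` with
#' `g(b) = eps(b, HbO2) * StO2 + eps(b, Hb) * (1 - StO2)`,
#' `C_HbO2 = StO2 * tHb`, `C_Hb = (1 - StO2) * tHb`.
#'
#' @param target_ratio Desired R610/R545 ratio; must exceed the bloodless
#'   baseline ratio `k610/k545`.
#' @param sto2 Oxygen saturation fraction in `[0, 1]`.
#' @param props An [optical_properties()].
#' @return Named numeric vector `c(C_HbO2, C_Hb)` in mM.
#' @export
#' @examples
#' props <- optical_properties()
#' cc <- target_ratio_to_concentrations(3.0, 0.85, props)
#' sum(cc)  # total hemoglobin, mM
target_ratio_to_concentrations <- function(target_ratio, sto2, props) {
  stopifnot(inherits(props, "optical_properties"),
            sto2 >= 0, sto2 <= 1)
  base_ratio <- props$baseline["R610"] / props$baseline["R545"]
  if (target_ratio <= base_ratio) {
    stop("target_ratio ", target_ratio,
         " is not achievable: it must exceed the bloodless baseline ratio ",
         signif(base_ratio, 6), call. = FALSE)
  }
  g545 <- weighted_extinction(props, "R545", sto2)
  g610 <- weighted_extinction(props, "R610", sto2)
  if (g545 <= g610) {
    stop("weighted extinction at 545 nm must exceed that at 610 nm",
         call. = FALSE)
  }
  thb <- log(target_ratio * props$baseline["R545"] / props$baseline["R610"]) /
    (props$path_length * (g545 - g610))
  c(C_HbO2 = unname(sto2 * thb), C_Hb = unname((1 - sto2) * thb))
}

# flat-top ellipse weight with a 2-px raised-cosine edge taper
ellipse_weight <- function(width, height, center, axes, taper = 2) {
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  rho <- sqrt(((px - center[1]) / axes[1])^2 + ((py - center[2]) / axes[2])^2)
  t_px <- (1 - rho) * min(axes)  # approx. pixel distance inside the boundary
  w <- ifelse(t_px >= taper, 1,
              ifelse(t_px <= 0, 0, 0.5 * (1 - cos(pi * t_px / taper))))
  matrix(w, nrow = height, ncol = width)
}

disk_mask <- function(width, height, center, radius) {
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  matrix((px - center[1])^2 + (py - center[2])^2 <= radius^2,
         nrow = height, ncol = width)
}

#' Render a phantom scene through the forward reflectance model
#'
#' Builds per-pixel chromophore concentration maps from the scene (lesion
#' concentrations via [target_ratio_to_concentrations()], inflammation
#' patches scaling `C_Hb`), evaluates
#' `R(band) = k(band) * exp(-d * (eps_HbO2 * C_HbO2 + eps_Hb * C_Hb))`
#' for the three reflectance bands, renders F405 from the fluorescence
#' parameters, adds clipped Gaussian noise, and paints specular spots as
#' saturated white. Ground truth (noise-free concentration maps, per-pixel
#' grade labels, and the noise-free R610/R545 map) is returned alongside.
#'
#' @param scene A [phantom_scene()].
#' @param props An [optical_properties()].
#' @return `list(capture = capture_set, truth = ground_truth)`.
#' @export
forward_reflectance <- function(scene, props = optical_properties()) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(props, "optical_properties"))
  w <- scene$width; h <- scene$height
  bg <- scene$background
  if (is.null(bg)) {
    cc <- target_ratio_to_concentrations(1.41, 0.98, props)
    bg <- c(HbO2 = unname(cc["C_HbO2"]), Hb = unname(cc["C_Hb"]))
  }
  stopifnot(all(bg >= 0))
  c_hbo2 <- matrix(bg[["HbO2"]], h, w)
  c_hb <- matrix(bg[["Hb"]], h, w)
  grade_map <- matrix("normal", h, w)
  lesion_weight <- matrix(0, h, w)

  for (l in scene$lesions) {
    cc <- target_ratio_to_concentrations(l$target_ratio, l$sto2, props)
    wgt <- ellipse_weight(w, h, l$center, l$axes)
    c_hbo2 <- c_hbo2 + wgt * (cc[["C_HbO2"]] - bg[["HbO2"]])
    c_hb <- c_hb + wgt * (cc[["C_Hb"]] - bg[["Hb"]])
    inside <- ellipse_weight(w, h, l$center, l$axes, taper = 1e-9) > 0
    grade_map[inside] <- l$grade
    lesion_weight <- pmax(lesion_weight, wgt)
  }
  for (p in scene$inflammation_patches) {
    wgt <- ellipse_weight(w, h, p$center, p$axes)
    c_hb <- c_hb * (1 + wgt * (p$hb_multiplier - 1))
  }

  band_image <- function(band) {
    props$baseline[[band]] *
      exp(-props$path_length * (props$extinction[band, "HbO2"] * c_hbo2 +
                                  props$extinction[band, "Hb"] * c_hb))
  }
  clean <- list(
    R545 = band_image("R545"),
    R575 = band_image("R575"),
    R610 = band_image("R610")
  )
  fl <- scene$fluorescence
  clean$F405 <- fl$base_level * (1 - fl$lesion_loss_fraction * lesion_weight) +
    fl$ppix_gain * lesion_weight

  truth <- structure(
    list(C_HbO2 = c_hbo2, C_Hb = c_hb, grade_map = grade_map,
         expected_ratio_map = clean$R610 / clean$R545),
    class = "ground_truth"
  )

  noisy <- withr::with_seed(scene$seed, {
    lapply(clean, function(img) {
      if (scene$noise_sigma > 0) {
        img <- img + rnorm(length(img), sd = scene$noise_sigma)
      }
      pmin(pmax(img, 0), 1)
    })
  })

  sat <- matrix(FALSE, h, w)
  for (s in scene$specular_spots) {
    m <- disk_mask(w, h, s$center, s$radius)
    sat <- sat | m
    for (b in reflectance_bands()) noisy[[b]][m] <- 1
  }

  capture <- capture_set(
    images = noisy[band_names()],
    exposure = c(F405 = 1, R545 = 1, R575 = 1, R610 = 1),
    site_id = paste0("phantom-", scene$seed),
    anatomical_site = scene$anatomical_site,
    saturation_mask = sat,
    bit_depth = 16L,
    extra = list(generator = "phantom", seed = scene$seed)
  )
  list(capture = capture, truth = truth)
}
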