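#' Construct a multispectral capture set
#'
#' A capture set holds the four co-registered monochrome frames of one
#' imaging site (fluorescence `F405` plus reflectance `R545`, `R575`,
#' `R610`), per-band exposure multipliers, site metadata, and a saturation
#' mask flagging specular or clipped pixels. Intensities are stored as
#' real values in `[0, 1]`; the camera bit depth is metadata only, so all
#' downstream math is independent of it.
#'
#' Images are numeric matrices indexed `[y + 1, x + 1]` for the 0-based
#' pixel `(x, y)`: x runs rightward (columns), y downward (rows).
#'
#' @param images Named list of four numeric matrices (names `F405`, `R545`,
#'   `R575`, `R610`), identical dimensions, values in `[0, 1]`.
#' @param exposure Named numeric vector of positive per-band exposure
#'   multipliers (same band names).
#' @param site_id Character scalar identifying the imaging site.
#' @param anatomical_site Term from [oral_sites()].
#' @param saturation_mask Logical matrix, same dimensions as the images;
#'   `TRUE` marks saturated/specular pixels. Defaults to all `FALSE`.
#' @param bit_depth Integer bit depth of the originating camera (metadata).
#' @param extra Named list of additional sidecar fields preserved on
#'   round-trip.
#'
#' @return An object of class `capture_set`.
#' @export
capture_set <- function(images, exposure, site_id, anatomical_site,
                        saturation_mask = NULL, bit_depth = 16L,
                        extra = list()) {
  missing_bands <- setdiff(band_names(), names(images))
  if (length(missing_bands) > 0) {
    stop("missing band image(s): ", paste(missing_bands, collapse = ", "),
         call. = FALSE)
  }
  images <- images[band_names()]
  dims <- lapply(images, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1)))) {
    stop("dimension mismatch between band images", call. = FALSE)
  }
  for (b in band_names()) {
    v <- images[[b]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1)) {
      stop("band ", b, " has intensities outside [0, 1]", call. = FALSE)
    }
  }
  if (is.null(saturation_mask)) {
    saturation_mask <- matrix(FALSE, nrow(images[[1]]), ncol(images[[1]]))
  }
  stopifnot(is.logical(saturation_mask),
            identical(dim(saturation_mask), dim(images[[1]])))
  exposure <- exposure[band_names()]
  if (anyNA(exposure) || any(exposure <= 0)) {
    stop("exposure must be a positive scalar for every band", call. = FALSE)
  }
  group <- site_group(anatomical_site)  # validates the vocabulary term
  structure(
    list(
      images = images,
      exposure = exposure,
      site_id = as.character(site_id),
      anatomical_site = anatomical_site,
      site_group = group,
      saturation_mask = saturation_mask,
      bit_depth = as.integer(bit_depth),
      extra = extra
    ),
    class = "capture_set"
  )
}

#' @export
print.capture_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("<capture_set> site ", x$site_id, " (", x$anatomical_site, ", ",
      x$site_group, ")\n", sep = "")
  cat("  ", d[2], "x", d[1], " px, ", x$bit_depth, "-bit origin, ",
      sum(x$saturation_mask), " saturated px\n", sep = "")
  cat("  exposures:",
      paste(names(x$exposure), round(x$exposure, 4), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.capture_set <- function(x) dim(x$images[[1]])

band_file <- function(directory, band) {
  for (ext in c("tiff", "tif", "png")) {
    p <- file.path(directory, paste0(band, ".", ext))
    if (file.exists(p)) return(p)
  }
  NA_character_
}

read_gray_image <- function(path) {
  # returns raw integer sample values plus their bit depth
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 16L
    raw <- round(img * (2^bits - 1))
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
    raw <- img
  }
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  list(raw = raw, bits = as.integer(bits))
}

#' Read and write capture-set directories
#'
#' A capture-set directory contains one grayscale TIFF or PNG per band
#' (`F405.tiff`, `R545.tiff`, ... or `.png`) and a JSON sidecar
#' `capture.json` with keys `bands`, `exposures`, `site_id`,
#' `anatomical_site` and `bit_depth`; unknown sidecar keys are preserved.
#' Integer pixel values are normalized by the bit-depth maximum into
#' `[0, 1]`, and pixels at the maximum raw value are flagged in the
#' saturation mask.
#'
#' @param directory_path Directory holding the four band images plus sidecar.
#' @return [read_capture_set()] returns a validated [capture_set()];
#'   [write_capture_set()] invisibly returns `directory_path`.
#' @export
read_capture_set <- function(directory_path) {
  sidecar_path <- file.path(directory_path, "capture.json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  }
  sidecar <- tryCatch(
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE),
    error = function(e) stop("malformed sidecar ", sidecar_path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  needed <- c("exposures", "site_id", "anatomical_site", "bit_depth")
  if (!all(needed %in% names(sidecar))) {
    stop("sidecar missing key(s): ",
         paste(setdiff(needed, names(sidecar)), collapse = ", "),
         call. = FALSE)
  }
  bit_depth <- as.integer(sidecar$bit_depth)
  maxval <- 2^bit_depth - 1

  images <- list()
  sat <- NULL
  for (b in band_names()) {
    p <- band_file(directory_path, b)
    if (is.na(p)) stop("missing band file for ", b, " in ", directory_path,
                       call. = FALSE)
    g <- read_gray_image(p)
    images[[b]] <- g$raw / maxval
    band_sat <- g$raw >= maxval
    sat <- if (is.null(sat)) band_sat else {
      if (!identical(dim(band_sat), dim(sat))) {
        stop("dimension mismatch between band images", call. = FALSE)
      }
      sat | band_sat
    }
  }
  exposures <- unlist(sidecar$exposures)[band_names()]
  extra <- sidecar[setdiff(names(sidecar), c(needed, "bands"))]
  capture_set(images, exposures, sidecar$site_id, sidecar$anatomical_site,
              saturation_mask = sat, bit_depth = bit_depth, extra = extra)
}

#' @rdname read_capture_set
#' @param capture A [capture_set()].
#' @param format `"tiff"` or `"png"`.
#' @export
write_capture_set <- function(capture, directory_path, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(capture, "capture_set"))
  if (format == "png" && capture$bit_depth != 8L) {
    stop("PNG band files are written at 8 bits; use TIFF for ",
         capture$bit_depth, "-bit captures", call. = FALSE)
  }
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  maxval <- 2^capture$bit_depth - 1
  for (b in band_names()) {
    img <- capture$images[[b]]
    # force saturated pixels to full scale so the flag round-trips
    img[capture$saturation_mask] <- 1
    quant <- round(img * maxval) / maxval
    path <- file.path(directory_path, paste0(b, ".", format))
    if (format == "tiff") {
      tiff::writeTIFF(quant, path, bits.per.sample = capture$bit_depth)
    } else {
      png::writePNG(quant, path)
    }
  }
  sidecar <- c(
    list(
      bands = band_names(),
      exposures = as.list(capture$exposure),
      site_id = capture$site_id,
      anatomical_site = capture$anatomical_site,
      bit_depth = capture$bit_depth
    ),
    capture$extra
  )
  jsonlite::write_json(sidecar, file.path(directory_path, "capture.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory_path)
}
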