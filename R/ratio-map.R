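#' Pixel-wise diffuse-reflectance band ratio
#'
#' Divides two reflectance band images pixel by pixel. The diagnostic
#' ratios are R610/R545 (oxyhemoglobin absorption contrast, rising with
#' malignant transformation), R610/R575 (tissue inflammation), and
#' R545/R575. Pixels are invalid where the denominator falls below
#' `min_denominator` (default one 8-bit count, suppressing dark-end
#' blow-ups) or where the capture's saturation mask is set; invalid pixels
#' carry value 0 and are excluded from all downstream statistics.
#'
#' @param capture A [capture_set()].
#' @param num_band,den_band Reflectance band names (`R545`, `R575`, `R610`).
#' @param min_denominator Smallest usable denominator intensity.
#' @return An object of class `ratio_map`: list with `numerator_band`,
#'   `denominator_band`, `values` (matrix), `valid_mask` (logical matrix).
#' @export
compute_ratio_map <- function(capture, num_band = "R610", den_band = "R545",
                              min_denominator = 1 / 255) {
  stopifnot(inherits(capture, "capture_set"), min_denominator > 0)
  rb <- reflectance_bands()
  if (!(num_band %in% rb) || !(den_band %in% rb)) {
    stop("ratio maps are defined on reflectance bands only (",
         paste(rb, collapse = ", "), "); got ", num_band, "/", den_band,
         call. = FALSE)
  }
  num <- capture$images[[num_band]]
  den <- capture$images[[den_band]]
  valid <- den >= min_denominator & !capture$saturation_mask
  values <- matrix(0, nrow(num), ncol(num))
  values[valid] <- num[valid] / den[valid]
  structure(
    list(numerator_band = num_band, denominator_band = den_band,
         values = values, valid_mask = valid),
    class = "ratio_map"
  )
}

#' @export
print.ratio_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat("<ratio_map> ", x$numerator_band, "/", x$denominator_band, ", ",
      ncol(x$values), "x", nrow(x$values), " px, ",
      sum(!x$valid_mask), " invalid\n", sep = "")
  if (length(v) > 0) {
    cat("  valid range [", signif(min(v), 4), ", ", signif(max(v), 4),
        "], mean ", signif(mean(v), 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.ratio_map <- function(x) dim(x$values)

#' Tidy a ratio map into a pixel tibble
#'
#' @param x A `ratio_map`.
#' @param ... Unused.
#' @return Tibble with 0-based `x`, `y`, `value`, `valid` per pixel.
#' @export
tidy.ratio_map <- function(x, ...) {
  h <- nrow(x$values); w <- ncol(x$values)
  value <- as.vector(x$values)
  valid <- as.vector(x$valid_mask)
  tibble::tibble(
    x = rep(seq_len(w) - 1, each = h),
    y = rep(seq_len(h) - 1, times = w),
    value = value,
    valid = valid
  )
}

#' Pseudo-color rendering of a scalar image
#'
#' Values are clamped to `[display_min, display_max]`, mapped through a
#' monotone sequential palette, and invalid pixels are rendered in a
#' reserved neutral gray — mirroring the on-screen pseudo-color map whose
#' display range the operator adjusts interactively.
#'
#' @param map A `ratio_map` or a plain numeric matrix.
#' @param display_min,display_max Display range (`min < max`).
#' @param colormap_name Palette name passed to [grDevices::hcl.colors()]
#'   (monotone sequential palettes such as `"Viridis"` or `"Inferno"`).
#' @param n_colors Number of palette levels.
#' @return `height` x `width` x 3 RGB array in `[0, 1]`.
#' @export
pseudo_color <- function(map, display_min = 0, display_max = 5,
                         colormap_name = "Viridis", n_colors = 256L) {
  if (display_min >= display_max) {
    stop("degenerate display range: display_min must be < display_max",
         call. = FALSE)
  }
  if (inherits(map, "ratio_map")) {
    values <- map$values
    valid <- map$valid_mask
  } else {
    values <- as.matrix(map)
    valid <- matrix(TRUE, nrow(values), ncol(values))
  }
  pal <- grDevices::hcl.colors(n_colors, colormap_name)
  frac <- (pmin(pmax(values, display_min), display_max) - display_min) /
    (display_max - display_min)
  idx <- pmin(floor(frac * n_colors) + 1L, n_colors)
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, c(nrow(values), ncol(values), 3))
  neutral <- c(0.5, 0.5, 0.5)
  for (ch in 1:3) {
    plane <- matrix(rgb[ch, ], nrow(values), ncol(values))
    plane[!valid] <- neutral[ch]
    out[, , ch] <- plane
  }
  out
}

#' Plot a ratio map with ggplot2
#'
#' @param object A `ratio_map`.
#' @param display_min,display_max Color scale limits.
#' @param ... Unused.
#' @return A ggplot object (y axis points downward, as in image
#'   coordinates); invalid pixels are gray.
#' @export
autoplot.ratio_map <- function(object, display_min = 0, display_max = 5, ...) {
  df <- tidy.ratio_map(object)
  df$value[!df$valid] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      limits = c(display_min, display_max),
      oob = scales_squish, na.value = "grey50",
      name = paste0(object$numerator_band, "/", object$denominator_band)
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

# clamp out-of-bounds values to the scale limits (avoids a scales dependency
# at build time; scales is always present under ggplot2)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  finite <- if (only.finite) is.finite(x) else rep(TRUE, length(x))
  x[finite & x < range[1]] <- range[1]
  x[finite & x > range[2]] <- range[2]
  x
}
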