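#' Hotspot score of a lesion ROI
#'
#' Locates the valid in-ROI pixel with the maximum ratio value (the
#' presumptive most malignant site) and scores the lesion as the mean of
#' the 5x5 pixel window centered on that hotspot. The window is clipped at
#' image borders, restricted to valid pixels, and deliberately NOT
#' restricted to the ROI — the window surrounds the hotspot, wherever its
#' neighbors fall. Ties in the maximum are broken by the smallest row-major
#' index (y, then x) so scoring is deterministic.
#'
#' @param ratio_map A `ratio_map` (see [compute_ratio_map()]).
#' @param lesion_roi An [roi()] outlining the lesion.
#' @param window Odd window side length (default 5).
#' @return A one-row tibble: `ratio_kind`, `hotspot_x`, `hotspot_y`
#'   (0-based), `score`, `n_window_pixels`.
#' @export
score_lesion <- function(ratio_map, lesion_roi, window = 5L) {
  stopifnot(inherits(ratio_map, "ratio_map"), inherits(lesion_roi, "roi"),
            window >= 1, window %% 2 == 1)
  h <- nrow(ratio_map$values); w <- ncol(ratio_map$values)
  mask <- rasterize_roi(lesion_roi, w, h) & ratio_map$valid_mask
  if (!any(mask)) stop("no valid pixel inside the lesion ROI", call. = FALSE)

  idx <- which(mask)                       # column-major linear indices
  yy <- (idx - 1) %% h                     # 0-based
  xx <- (idx - 1) %/% h
  vals <- ratio_map$values[idx]
  best <- which(vals == max(vals))
  best <- best[which.min(yy[best] * w + xx[best])]  # row-major tie-break
  hx <- xx[best]; hy <- yy[best]

  half <- (window - 1L) / 2L
  rows <- max(hy - half, 0):min(hy + half, h - 1) + 1
  cols <- max(hx - half, 0):min(hx + half, w - 1) + 1
  win_vals <- ratio_map$values[rows, cols, drop = FALSE]
  win_valid <- ratio_map$valid_mask[rows, cols, drop = FALSE]
  tibble::tibble(
    ratio_kind = paste0(ratio_map$numerator_band, "/",
                        ratio_map$denominator_band),
    hotspot_x = hx, hotspot_y = hy,
    score = mean(win_vals[win_valid]),
    n_window_pixels = sum(win_valid)
  )
}

#' Mean ratio over a healthy reference ROI
#'
#' The healthy reference is the arithmetic mean of all valid pixels inside
#' the ROI a clinician marks on apparently healthy mucosa of the same
#' anatomical site.
#'
#' @param ratio_map A `ratio_map`.
#' @param healthy_roi An [roi()].
#' @return Positive scalar mean ratio.
#' @export
healthy_reference <- function(ratio_map, healthy_roi) {
  stopifnot(inherits(ratio_map, "ratio_map"), inherits(healthy_roi, "roi"))
  h <- nrow(ratio_map$values); w <- ncol(ratio_map$values)
  mask <- rasterize_roi(healthy_roi, w, h) & ratio_map$valid_mask
  if (!any(mask)) stop("no valid pixel inside the healthy ROI", call. = FALSE)
  mean(ratio_map$values[mask])
}

#' Suggest an inflammation-free healthy reference region
#'
#' Healthy reference regions should avoid tissue inflammation, which shows
#' as a high R610/R575 ratio. This scans every square window that lies
#' fully outside the lesion ROI with all pixels valid, and returns the one
#' with the minimal mean R610/R575 as a rectangular ROI. Ties go to the
#' smallest row-major window corner.
#'
#' @param inflammation_map A `ratio_map`, normally R610/R575.
#' @param lesion_roi An [roi()] outlining the lesion to avoid.
#' @param window_size Odd window side length >= 3.
#' @return An [roi()] labelled `"healthy"` covering the chosen window.
#' @export
suggest_healthy_roi <- function(inflammation_map, lesion_roi,
                                window_size = 7L) {
  stopifnot(inherits(inflammation_map, "ratio_map"),
            inherits(lesion_roi, "roi"),
            window_size >= 3, window_size %% 2 == 1)
  h <- nrow(inflammation_map$values); w <- ncol(inflammation_map$values)
  if (window_size > w || window_size > h) {
    stop("window_size exceeds image dimensions", call. = FALSE)
  }
  lesion_mask <- rasterize_roi(lesion_roi, w, h)

  # integral images give every window's sum/count in O(1)
  win_sum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    cs <- rbind(0, cbind(0, cs))                 # (w+1) x (h+1), [x+1, y+1]
    k <- window_size
    # corners (x0, y0) with 0 <= x0 <= w-k, 0 <= y0 <= h-k
    xs <- seq_len(w - k + 1); ys <- seq_len(h - k + 1)
    cs[xs + k, ys + k, drop = FALSE] - cs[xs, ys + k, drop = FALSE] -
      cs[xs + k, ys, drop = FALSE] + cs[xs, ys, drop = FALSE]
  }
  sums <- win_sum(inflammation_map$values)
  n_valid <- win_sum(inflammation_map$valid_mask + 0)
  n_lesion <- win_sum(lesion_mask + 0)
  k2 <- window_size^2
  eligible <- n_valid == k2 & n_lesion == 0
  if (!any(eligible)) {
    stop("no fully-valid candidate window outside the lesion ROI",
         call. = FALSE)
  }
  means <- ifelse(eligible, sums / k2, Inf)
  # means is indexed [x0+1, y0+1]; row-major tie-break = min y0, then x0
  nx <- nrow(means)
  best <- which(means == min(means))
  x0 <- (best - 1) %% nx
  y0 <- (best - 1) %/% nx
  pick <- which.min(y0 * w + x0)
  x0 <- x0[pick]; y0 <- y0[pick]
  # rectangle enclosing the window's pixel centers, clamped into bounds
  # (a vertex exactly on 0 still encloses the center at 0 under even-odd)
  xlo <- max(x0 - 0.5, 0); ylo <- max(y0 - 0.5, 0)
  xhi <- x0 + window_size - 0.5; yhi <- y0 + window_size - 0.5
  roi(rbind(c(xlo, ylo), c(xhi, ylo), c(xhi, yhi), c(xlo, yhi)),
      label = "healthy")
}
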