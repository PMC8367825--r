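# Independent scalar-loop oracles. These deliberately avoid the package's
# vectorized code paths: everything here is a plain double loop over pixels
# or pairs, so agreement is meaningful.

# even-odd center-in-polygon test for a single point
oracle_point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- vertices[j, 1]; y1 <- vertices[j, 2]
    x2 <- vertices[i, 1]; y2 <- vertices[i, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(vertices, width, height) {
  out <- matrix(FALSE, height, width)
  for (y in 0:(height - 1)) {
    for (x in 0:(width - 1)) {
      out[y + 1, x + 1] <- oracle_point_in_polygon(x, y, vertices)
    }
  }
  out
}

oracle_ratio <- function(num, den, sat, min_den) {
  h <- nrow(num); w <- ncol(num)
  values <- matrix(0, h, w)
  valid <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!sat[i, j] && den[i, j] >= min_den) {
      valid[i, j] <- TRUE
      values[i, j] <- num[i, j] / den[i, j]
    }
  }
  list(values = values, valid = valid)
}

# hotspot + clipped-window mean, enumerating every candidate
oracle_score <- function(values, valid, roi_mask, window = 5) {
  h <- nrow(values); w <- ncol(values)
  best <- NULL
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {   # row-major scan
    if (roi_mask[y + 1, x + 1] && valid[y + 1, x + 1]) {
      v <- values[y + 1, x + 1]
      if (is.null(best) || v > best$v) best <- list(x = x, y = y, v = v)
    }
  }
  if (is.null(best)) return(NULL)
  half <- (window - 1) / 2
  acc <- c(); n <- 0
  for (yy in (best$y - half):(best$y + half)) {
    for (xx in (best$x - half):(best$x + half)) {
      if (yy >= 0 && yy < h && xx >= 0 && xx < w && valid[yy + 1, xx + 1]) {
        acc <- c(acc, values[yy + 1, xx + 1]); n <- n + 1
      }
    }
  }
  list(x = best$x, y = best$y, score = mean(acc), n = n)
}

oracle_best_window <- function(values, valid, lesion_mask, k) {
  h <- nrow(values); w <- ncol(values)
  best <- NULL
  for (y0 in 0:(h - k)) for (x0 in 0:(w - k)) {
    ok <- TRUE; s <- 0
    for (yy in y0:(y0 + k - 1)) for (xx in x0:(x0 + k - 1)) {
      if (!valid[yy + 1, xx + 1] || lesion_mask[yy + 1, xx + 1]) ok <- FALSE
      s <- s + values[yy + 1, xx + 1]
    }
    if (ok) {
      m <- s / k^2
      if (is.null(best) || m < best$mean) best <- list(x0 = x0, y0 = y0, mean = m)
    }
  }
  best
}

# Mann-Whitney U via stats::wilcox.test for large inputs where the pairwise
# loop is impractical
oracle_auc_fast <- function(pos, neg) {
  w <- stats::wilcox.test(pos, neg, exact = FALSE)$statistic
  unname(w) / (length(pos) * length(neg))
}

oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# star-shaped simple polygon: vertices at sorted angles around a center
random_simple_polygon <- function(width, height, n_min = 3, n_max = 8) {
  n <- sample(n_min:n_max, 1)
  cx <- runif(1, width * 0.3, width * 0.7)
  cy <- runif(1, height * 0.3, height * 0.7)
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, 1, min(width, height) * 0.45)
  x <- pmin(pmax(cx + rad * cos(ang), 0), width - 1e-6)
  y <- pmin(pmax(cy + rad * sin(ang), 0), height - 1e-6)
  cbind(x, y)
}

make_capture <- function(images, sat = NULL, site = "buccal_mucosa_left",
                         bit_depth = 16L) {
  full <- list(
    F405 = images$F405 %||% matrix(0.5, nrow(images[[1]]), ncol(images[[1]])),
    R545 = images$R545,
    R575 = images$R575 %||% images$R545,
    R610 = images$R610
  )
  capture_set(full, c(F405 = 1, R545 = 1, R575 = 1, R610 = 1),
              "test-site", site, saturation_mask = sat,
              bit_depth = bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

linear_camera <- function(gains, response = 0.05) {
  force(gains); force(response)
  function(band, exposure) matrix(gains[[band]] * exposure * response, 8, 8)
}
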