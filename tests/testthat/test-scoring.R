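ratio_from <- function(values, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  structure(list(numerator_band = "R610", denominator_band = "R545",
                 values = values, valid_mask = valid),
            class = "ratio_map")
}

big_roi <- function(w, h) {
  roi(rbind(c(0, 0), c(w - 1e-6, 0), c(w - 1e-6, h - 1e-6), c(0, h - 1e-6)),
      "lesion")
}

test_that("uniform fields score their constant and single peaks average in", {
  rm <- ratio_from(matrix(2.5, 12, 12))
  interior <- roi(rbind(c(3, 3), c(9, 3), c(9, 9), c(3, 9)), "lesion")
  s <- score_lesion(rm, interior)
  expect_equal(s$score, 2.5)
  expect_equal(s$n_window_pixels, 25)

  vals <- matrix(1, 12, 12)
  vals[7, 7] <- 5  # 0-based (6, 6)
  s2 <- score_lesion(ratio_from(vals), interior)
  expect_equal(s2$hotspot_x, 6)
  expect_equal(s2$hotspot_y, 6)
  expect_equal(s2$score, (24 * 1 + 5) / 25)
})

test_that("hotspot scoring matches the exhaustive oracle on random maps", {
  set.seed(81)
  for (i in 1:50) {
    h <- sample(10:20, 1); w <- sample(10:20, 1)
    vals <- matrix(sample(seq(0.5, 5, by = 0.5), h * w, replace = TRUE), h, w)
    valid <- matrix(runif(h * w) > 0.1, h, w)
    v <- random_simple_polygon(w, h, n_min = 4)
    mask <- rasterize_roi(roi(v), w, h)
    if (!any(mask & valid)) next
    got <- score_lesion(ratio_from(vals, valid), roi(v))
    want <- oracle_score(vals, valid, mask)
    expect_equal(got$hotspot_x, want$x)
    expect_equal(got$hotspot_y, want$y)
    expect_equal(got$score, want$score)
    expect_equal(got$n_window_pixels, want$n)
  }
})

test_that("window means are clipped at borders and skip invalid pixels", {
  vals <- matrix(1, 8, 8)
  vals[1, 1] <- 4  # hotspot at the corner (0, 0)
  s <- score_lesion(ratio_from(vals), big_roi(8, 8))
  expect_equal(s$n_window_pixels, 9)  # 3x3 survives clipping
  expect_equal(s$score, (8 + 4) / 9)

  valid <- matrix(TRUE, 8, 8)
  valid[1:3, 2:3] <- FALSE
  s2 <- score_lesion(ratio_from(vals, valid), big_roi(8, 8))
  expect_equal(s2$n_window_pixels, 9 - 6)
})

test_that("score responds monotonically to hotspot raises and bounded windows", {
  set.seed(82)
  vals <- matrix(runif(144, 1, 3), 12, 12)
  lesion <- roi(rbind(c(2, 2), c(9, 2), c(9, 9), c(2, 9)), "lesion")
  base <- score_lesion(ratio_from(vals), lesion)
  for (i in 1:20) {
    # raising the hotspot pixel itself (it stays the max) raises the score
    bumped <- vals
    bumped[base$hotspot_y + 1, base$hotspot_x + 1] <-
      bumped[base$hotspot_y + 1, base$hotspot_x + 1] + runif(1, 0, 3)
    s <- score_lesion(ratio_from(bumped), lesion)
    expect_gte(s$score, base$score)
    expect_equal(c(s$hotspot_x, s$hotspot_y),
                 c(base$hotspot_x, base$hotspot_y))
    # the score is a window mean: bracketed by the window extremes,
    # never above the in-ROI maximum
    expect_lte(s$score, bumped[s$hotspot_y + 1, s$hotspot_x + 1])
    expect_gte(s$score, min(bumped))
  }
})

test_that("shifting map and ROI together translates the hotspot only", {
  set.seed(83)
  vals <- matrix(runif(400, 1, 4), 20, 20)
  lesion <- roi(rbind(c(3, 3), c(9, 3), c(9, 9), c(3, 9)), "lesion")
  s0 <- score_lesion(ratio_from(vals), lesion)
  shifted_vals <- matrix(0, 20, 20)
  shifted_vals[4:20, 4:20] <- vals[1:17, 1:17]
  shifted_roi <- roi(lesion$vertices + 3, "lesion")
  s1 <- score_lesion(ratio_from(shifted_vals), shifted_roi)
  expect_equal(s1$hotspot_x, s0$hotspot_x + 3)
  expect_equal(s1$hotspot_y, s0$hotspot_y + 3)
  expect_equal(s1$score, s0$score)
})

test_that("healthy reference averages exactly the valid in-ROI pixels", {
  vals <- matrix(1, 10, 10)
  vals[, 6:10] <- 2
  half_roi <- roi(rbind(c(0, 0), c(9.9, 0), c(9.9, 9.9), c(0, 9.9)),
                  "healthy")
  expect_equal(healthy_reference(ratio_from(vals), half_roi), 1.5)

  set.seed(84)
  rv <- matrix(runif(100, 0.5, 3), 10, 10)
  valid <- matrix(runif(100) > 0.2, 10, 10)
  v <- random_simple_polygon(10, 10, n_min = 4)
  mask <- rasterize_roi(roi(v), 10, 10) & valid
  expect_true(any(mask))
  expect_equal(healthy_reference(ratio_from(rv, valid), roi(v, "healthy")),
               mean(rv[mask]))
  expect_error(healthy_reference(ratio_from(rv, valid & FALSE),
                                 roi(v, "healthy")),
               "no valid pixel")
})

test_that("healthy-ROI suggestion finds the coolest inflammation window", {
  vals <- matrix(2, 20, 20)
  vals[11:17, 3:9] <- 1  # cool 7x7 patch, corner (2, 10)
  lesion <- roi(rbind(c(12, 2), c(18, 2), c(18, 8), c(12, 8)), "lesion")
  got <- suggest_healthy_roi(ratio_from(vals), lesion, window_size = 7)
  mask <- rasterize_roi(got, 20, 20)
  expect_equal(sum(mask), 49)
  expect_true(all(mask[11:17, 3:9]))
})

test_that("window suggestion matches the exhaustive window-search oracle", {
  set.seed(85)
  for (i in 1:30) {
    vals <- matrix(runif(18 * 18, 1, 3), 18, 18)
    valid <- matrix(runif(18 * 18) > 0.05, 18, 18)
    lesion_v <- random_simple_polygon(18, 18, n_min = 4)
    lesion_mask <- rasterize_roi(roi(lesion_v), 18, 18)
    want <- oracle_best_window(vals, valid, lesion_mask, 5)
    if (is.null(want)) {
      expect_error(suggest_healthy_roi(ratio_from(vals, valid),
                                       roi(lesion_v), 5),
                   "no fully-valid candidate")
      next
    }
    got <- suggest_healthy_roi(ratio_from(vals, valid), roi(lesion_v), 5)
    got_mask <- rasterize_roi(got, 18, 18)
    expect_equal(sum(got_mask), 25)
    expect_equal(mean(vals[got_mask]), want$mean)
  }
})
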