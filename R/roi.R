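#' Construct a region of interest polygon
#'
#' ROIs are clinician-drawn polygons outlining either the lesion border or
#' an adjoining apparently healthy reference region. Vertices are 0-based
#' pixel coordinates (x rightward, y downward); the polygon is closed
#' implicitly. Rasterization uses the even-odd rule on pixel centers, which
#' sit at integer coordinates.
#'
#' @param vertices Numeric matrix (or two-column data frame) of at least
#'   three `(x, y)` vertices.
#' @param label `"lesion"` or `"healthy"`.
#' @return An object of class `roi`.
#' @export
roi <- function(vertices, label = c("lesion", "healthy")) {
  label <- match.arg(label)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("an ROI needs a numeric matrix of >= 3 (x, y) vertices",
         call. = FALSE)
  }
  colnames(vertices) <- c("x", "y")
  structure(list(label = label, vertices = vertices), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat("<roi> ", x$label, ", ", nrow(x$vertices), " vertices\n", sep = "")
  invisible(x)
}

#' Rasterize an ROI polygon onto a pixel grid
#'
#' A pixel is inside when its center (at integer coordinates) falls inside
#' the polygon under the even-odd fill rule; boundary pixels are resolved by
#' the same center-in-polygon test.
#'
#' @param roi An [roi()].
#' @param width,height Grid dimensions in pixels (x spans `[0, width)`).
#' @return Logical `height` x `width` matrix, `TRUE` inside the polygon.
#' @export
#' @examples
#' r <- roi(rbind(c(0.5, 0.5), c(4.5, 0.5), c(4.5, 4.5), c(0.5, 4.5)))
#' sum(rasterize_roi(r, 10, 10))  # 16 pixel centers inside
rasterize_roi <- function(roi, width, height) {
  stopifnot(inherits(roi, "roi"), width >= 1, height >= 1)
  v <- roi$vertices
  if (any(v[, 1] < 0 | v[, 1] >= width | v[, 2] < 0 | v[, 2] >= height)) {
    stop("ROI vertex outside image bounds [0,", width, ") x [0,", height, ")",
         call. = FALSE)
  }
  px <- rep(seq_len(width) - 1, each = height)   # column-major over (y, x)
  py <- rep(seq_len(height) - 1, times = width)
  inside <- rep(FALSE, width * height)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]
    x2 <- v[i, 1]; y2 <- v[i, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Read and write ROI files
#'
#' ROI files are JSON arrays of objects `{label, vertices}` where
#' `vertices` is a list of `[x, y]` pairs.
#'
#' @param rois List of [roi()] objects.
#' @param path File path.
#' @return [read_roi_set()] returns a list of [roi()] objects.
#' @export
write_roi_set <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(label = r$label,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) unname(r$vertices[i, ])))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(item) {
    verts <- do.call(rbind, lapply(item$vertices, unlist))
    roi(verts, label = item$label)
  })
}

#' Pick one ROI by label from a list
#' @param rois List of [roi()] objects.
#' @param label Label to select.
#' @return The first matching [roi()].
#' @export
roi_by_label <- function(rois, label) {
  hit <- Filter(function(r) r$label == label, rois)
  if (length(hit) == 0) stop("no ROI labelled '", label, "'", call. = FALSE)
  hit[[1]]
}
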