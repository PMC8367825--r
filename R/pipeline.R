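#' Run the full screening pipeline on one capture-set directory
#'
#' Reproduces the device workflow for one imaged site: read the four-band
#' capture, compute the three diagnostic ratio maps (R610/R545, R610/R575,
#' R545/R575), score the lesion ROI by its 5x5 hotspot mean on R610/R545,
#' compute the healthy references (mean R610/R545 and mean R610/R575 in
#' the healthy ROI, the latter quantifying inflammation), classify the
#' lesion score against the threshold model, and write a JSON report plus
#' pseudo-color PNG renderings. Reports are byte-reproducible for
#' identical inputs.
#'
#' @param capture_dir Capture-set directory (see [read_capture_set()]).
#' @param roi_file ROI JSON with a `lesion` ROI and optionally a `healthy`
#'   ROI (see [write_roi_set()]); if no healthy ROI is given, one is
#'   suggested automatically from the inflammation map.
#' @param model A `threshold_model` or path to a model JSON.
#' @param out_dir Output directory for `report.json` and PNG overlays;
#'   `NULL` writes nothing.
#' @param min_denominator Passed to [compute_ratio_map()].
#' @param display_range Pseudo-color display range `c(min, max)`.
#' @return The report as a list (invisibly identical to the JSON content).
#' @export
run_pipeline <- function(capture_dir, roi_file, model, out_dir = NULL,
                         min_denominator = 1 / 255,
                         display_range = c(0, 5)) {
  capture <- read_capture_set(capture_dir)
  rois <- read_roi_set(roi_file)
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "threshold_model"))

  maps <- list(
    "R610/R545" = compute_ratio_map(capture, "R610", "R545", min_denominator),
    "R610/R575" = compute_ratio_map(capture, "R610", "R575", min_denominator),
    "R545/R575" = compute_ratio_map(capture, "R545", "R575", min_denominator)
  )
  lesion <- roi_by_label(rois, "lesion")
  healthy <- tryCatch(roi_by_label(rois, "healthy"), error = function(e) NULL)
  if (is.null(healthy)) {
    # prefer a 7x7 reference region; shrink if the lesion leaves no room
    for (win in c(7L, 5L, 3L)) {
      healthy <- tryCatch(
        suggest_healthy_roi(maps[["R610/R575"]], lesion, window_size = win),
        error = function(e) NULL)
      if (!is.null(healthy)) break
    }
    if (is.null(healthy)) {
      stop("no healthy ROI supplied and none could be suggested",
           call. = FALSE)
    }
  }

  scores <- dplyr::bind_rows(lapply(maps, score_lesion, lesion_roi = lesion))
  main <- scores[scores$ratio_kind == "R610/R545", ]
  call <- classify(main$score, model)

  report <- list(
    site_id = capture$site_id,
    anatomical_site = capture$anatomical_site,
    site_group = capture$site_group,
    model = list(group = model$group, version = model$version,
                 t_opml = model$t_opml, t_scc = model$t_scc),
    scores = lapply(seq_len(nrow(scores)), function(i) as.list(scores[i, ])),
    healthy_reference = healthy_reference(maps[["R610/R545"]], healthy),
    inflammation_reference = healthy_reference(maps[["R610/R575"]], healthy),
    classification = list(score = main$score,
                          class = as.character(call$class),
                          color = call$color)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (kind in names(maps)) {
      png::writePNG(
        pseudo_color(maps[[kind]], display_range[1], display_range[2]),
        file.path(out_dir, paste0(gsub("/", "_over_", kind), ".png"))
      )
    }
  }
  invisible(report)
}
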