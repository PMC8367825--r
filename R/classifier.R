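#' Mean-of-means discrimination threshold
#'
#' The decision boundary between two score classes is placed at the
#' midpoint of the two class means: `(mean(A) + mean(B)) / 2`. The result
#' depends only on the class means, not on class sizes, and is symmetric
#' in its arguments.
#'
#' @param scores_a,scores_b Non-empty numeric vectors of positive scores.
#' @return The midpoint threshold.
#' @export
#' @examples
#' learn_threshold(c(1, 1), c(3, 3))  # 2
learn_threshold <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    stop("both score classes must be non-empty", call. = FALSE)
  }
  if (any(scores_a <= 0) || any(scores_b <= 0)) {
    stop("scores must be positive", call. = FALSE)
  }
  (mean(scores_a) + mean(scores_b)) / 2
}

match_group <- function(records, group) {
  if (group == "all_sites") return(records)
  if (group %in% c("keratinized", "non_keratinized")) {
    return(dplyr::filter(records, site_group(.data$anatomical_site) == group))
  }
  if (startsWith(group, "site:")) {
    target <- sub("^site:", "", group)
    return(dplyr::filter(
      records,
      site_region(.data$anatomical_site) == target |
        .data$anatomical_site == target
    ))
  }
  stop("unknown group '", group, "'; use all_sites, keratinized, ",
       "non_keratinized or site:<anatomical_site>", call. = FALSE)
}

#' Fit a two-cutoff threshold model
#'
#' Learns the three-zone classifier for one site group from labelled score
#' records: the normal/suspect boundary `t_opml` is the mean-of-means of
#' normal vs OPML scores and the suspect/critical boundary `t_scc` the
#' mean-of-means of OPML vs SCC scores. Only the lower boundary is pinned
#' by the clinical scatter plots; the upper one is this package's
#' extension so that the three-zone display (green/yellow/red) is fully
#' specified. Normal records may be restricted to patient normals or to
#' healthy-volunteer normals (site-specific models using volunteer data
#' avoid field-cancerization bias in patient "normal" tissue).
#'
#' @param records Score-record tibble (see [read_score_table()]).
#' @param group `"all_sites"`, `"keratinized"`, `"non_keratinized"`, or
#'   `"site:<region>"` (e.g. `"site:buccal_mucosa"`, pooling laterality).
#' @param normal_source `"patient"` or `"healthy_volunteer"`.
#' @param version Model version number (managed by the registry).
#' @return An object of class `threshold_model`.
#' @export
fit_model <- function(records, group = "all_sites",
                      normal_source = c("patient", "healthy_volunteer"),
                      version = 1L) {
  normal_source <- match.arg(normal_source)
  records <- validate_score_records(records)
  records <- match_group(records, group)
  normals <- records$score[records$label == "normal" &
                             records$source == normal_source]
  opml <- records$score[records$label == "OPML"]
  scc <- records$score[records$label == "SCC"]
  counts <- c(normal = length(normals), OPML = length(opml),
              SCC = length(scc))
  if (any(counts == 0)) {
    stop("missing class after filtering (group '", group, "', normals from ",
         normal_source, "): ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  t_opml <- learn_threshold(normals, opml)
  t_scc <- learn_threshold(opml, scc)
  if (t_opml >= t_scc) {
    stop("degenerate training: normal/OPML cutoff (", signif(t_opml, 6),
         ") is not below the OPML/SCC cutoff (", signif(t_scc, 6), ")",
         call. = FALSE)
  }
  structure(
    list(
      group = group,
      t_opml = t_opml,
      t_scc = t_scc,
      provenance = list(
        n = as.list(counts),
        class_means = list(normal = mean(normals), OPML = mean(opml),
                           SCC = mean(scc)),
        normal_source = normal_source
      ),
      version = as.integer(version)
    ),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("<threshold_model> v", x$version, " (", x$group, ", normals from ",
      x$provenance$normal_source, ")\n", sep = "")
  cat("  cutoffs: normal/suspect ", signif(x$t_opml, 6),
      ", suspect/critical ", signif(x$t_scc, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy and glance methods for threshold models
#'
#' @param x,object A `threshold_model`.
#' @param ... Unused.
#' @return `tidy()` gives one row per decision boundary with the class
#'   means it averages; `glance()` gives a one-row model summary.
#' @export
tidy.threshold_model <- function(x, ...) {
  m <- x$provenance$class_means
  tibble::tibble(
    boundary = c("normal/suspect", "suspect/critical"),
    cutoff = c(x$t_opml, x$t_scc),
    lower_class_mean = c(m$normal, m$OPML),
    upper_class_mean = c(m$OPML, m$SCC)
  )
}

#' @rdname tidy.threshold_model
#' @export
glance.threshold_model <- function(x, ...) {
  tibble::tibble(
    group = x$group,
    normal_source = x$provenance$normal_source,
    t_opml = x$t_opml,
    t_scc = x$t_scc,
    n_normal = x$provenance$n$normal,
    n_opml = x$provenance$n$OPML,
    n_scc = x$provenance$n$SCC,
    version = x$version
  )
}

#' Classify lesion scores into the three-zone display
#'
#' Scores below `t_opml` read normal (green), scores in
#' `[t_opml, t_scc)` suspect (yellow, the potentially malignant zone), and
#' scores at or above `t_scc` critical (red, the malignant zone). Boundary
#' values are assigned to the higher-risk class, favoring sensitivity.
#'
#' @param score Positive numeric vector of lesion scores.
#' @param model A `threshold_model`.
#' @return Tibble with `score`, `class` (factor normal < suspect <
#'   critical) and `color` (green/yellow/red).
#' @export
#' @examples
#' m <- fit_model(generate_cohort(c(normal = 30, OPML = 30, SCC = 30),
#'                                seed = 1))
#' classify(c(1.2, 2.6, 4.5), m)
classify <- function(score, model) {
  stopifnot(inherits(model, "threshold_model"))
  if (any(score <= 0)) stop("scores must be positive", call. = FALSE)
  cls <- ifelse(score < model$t_opml, "normal",
                ifelse(score < model$t_scc, "suspect", "critical"))
  tibble::tibble(
    score = score,
    class = factor(cls, levels = c("normal", "suspect", "critical"),
                   ordered = TRUE),
    color = c(normal = "green", suspect = "yellow",
              critical = "red")[cls]
  )
}

#' Serialize threshold models to JSON
#'
#' @param model A `threshold_model`.
#' @param path JSON file path.
#' @return [read_model()] returns the `threshold_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  # digits = I(17): cutoffs must survive the JSON round-trip bit for bit
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(group = m$group, t_opml = m$t_opml, t_scc = m$t_scc,
         provenance = m$provenance, version = as.integer(m$version)),
    class = "threshold_model"
  )
}

#' Plot class scores against a fitted threshold model
#'
#' Scatter of scores by class with the model's two decision boundaries,
#' mirroring the clinical scatter-plot presentation of the discrimination
#' lines.
#'
#' @param object A `threshold_model`.
#' @param records Optional score-record tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_model <- function(object, records = NULL, ...) {
  cuts <- tidy.threshold_model(object)
  p <- ggplot2::ggplot()
  if (!is.null(records)) {
    records <- validate_score_records(records)
    records$index <- seq_len(nrow(records))
    p <- p + ggplot2::geom_point(
      data = records,
      ggplot2::aes(x = .data$index, y = .data$score, color = .data$label)
    ) +
      ggplot2::scale_color_manual(
        values = c(normal = "#2e7d32", OPML = "#f9a825", SCC = "#c62828")
      )
  }
  p +
    ggplot2::geom_hline(data = cuts,
                        ggplot2::aes(yintercept = .data$cutoff,
                                     linetype = .data$boundary)) +
    ggplot2::labs(x = "record", y = "R610/R545 score",
                  title = paste0("threshold model v", object$version,
                                 " (", object$group, ")")) +
    ggplot2::theme_minimal()
}
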