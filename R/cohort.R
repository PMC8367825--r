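#' Class score-distribution targets for cohort simulation
#'
#' Simulated cohorts draw R610/R545 lesion scores per histopathology class
#' from log-normal distributions calibrated analytically so that the
#' population median and interquartile range hit configured targets. For a
#' log-normal, `median = exp(mu)` and
#' `IQR = median * 2 * sinh(z * sigma)` with `z = qnorm(0.75)`, so
#' `mu = log(median)` and `sigma = asinh(IQR / (2 * median)) / z` — the
#' calibration is exact in distribution, not fitted.
#'
#' Default targets are the observed clinical class summaries: healthy
#' median 1.41 / IQR 0.55, potentially malignant 3.04 / 0.98, malignant
#' 3.59 / 1.07. Healthy-volunteer normals (median 1.30 / IQR 0.50, a
#' simulator convention) sit slightly below patient normals, emulating the
#' field-cancerization shift.
#'
#' @param n_per_class Named integer vector with counts for `normal`,
#'   `OPML`, `SCC`.
#' @param targets Tibble with columns `label`, `median`, `iqr` overriding
#'   the class targets.
#' @param n_volunteer_normals Number of additional healthy-volunteer
#'   normal records.
#' @param volunteer_median,volunteer_iqr Volunteer normal distribution
#'   targets.
#' @param seed Integer seed; cohorts are deterministic given the seed.
#' @return A tibble of score records (see [read_score_table()]).
#' @export
#' @examples
#' cohort <- generate_cohort(c(normal = 50, OPML = 30, SCC = 20), seed = 7)
#' dplyr::count(cohort, label)
generate_cohort <- function(n_per_class = c(normal = 40, OPML = 40, SCC = 49),
                            targets = default_cohort_targets(),
                            n_volunteer_normals = 0,
                            volunteer_median = 1.30, volunteer_iqr = 0.50,
                            seed = 1L) {
  n_per_class <- n_per_class[c("normal", "OPML", "SCC")]
  n_per_class[is.na(n_per_class)] <- 0
  names(n_per_class) <- c("normal", "OPML", "SCC")
  if (any(n_per_class < 0) || n_volunteer_normals < 0) {
    stop("class counts must be >= 0", call. = FALSE)
  }
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("label", "median", "iqr") %in% names(targets)))
  if (any(targets$median <= 0) || any(targets$iqr < 0) ||
      volunteer_median <= 0 || volunteer_iqr < 0) {
    stop("class medians must be positive and IQRs non-negative",
         call. = FALSE)
  }

  sites <- oral_sites()$site
  draw <- function(n, med, iqr, label, source, offset) {
    if (n == 0) {
      return(tibble::tibble(site_id = character(), anatomical_site = character(),
                            score = numeric(), label = character(),
                            source = character()))
    }
    pars <- lognormal_params(med, iqr)
    tibble::tibble(
      site_id = sprintf("S%05d", offset + seq_len(n)),
      anatomical_site = sample(sites, n, replace = TRUE),
      score = rlnorm(n, meanlog = pars$mu, sdlog = pars$sigma),
      label = label,
      source = source
    )
  }

  withr::with_seed(seed, {
    offset <- 0
    out <- list()
    for (lab in c("normal", "OPML", "SCC")) {
      trg <- targets[targets$label == lab, ]
      if (nrow(trg) != 1) stop("missing target row for class ", lab,
                               call. = FALSE)
      out[[lab]] <- draw(n_per_class[[lab]], trg$median, trg$iqr,
                         lab, "patient", offset)
      offset <- offset + n_per_class[[lab]]
    }
    out$volunteer <- draw(n_volunteer_normals, volunteer_median,
                          volunteer_iqr, "normal", "healthy_volunteer",
                          offset)
    validate_score_records(dplyr::bind_rows(out))
  })
}

#' @rdname generate_cohort
#' @export
default_cohort_targets <- function() {
  tibble::tribble(
    ~label,   ~median, ~iqr,
    "normal", 1.41, 0.55,
    "OPML",   3.04, 0.98,
    "SCC",    3.59, 1.07
  )
}

lognormal_params <- function(med, iqr) {
  list(mu = log(med), sigma = asinh(iqr / (2 * med)) / qnorm(0.75))
}
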