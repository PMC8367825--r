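#' Local versioned model registry
#'
#' Emulates the cloud feedback loop with a local, append-only store:
#' confirmed score records (biopsy-labelled R610/R545 values) accumulate in
#' a JSON-lines file, and every retraining writes an immutable, versioned
#' model snapshot per site group. Rebuilding any version from the log
#' reproduces its cutoffs exactly, so the registry is fully replayable.
#'
#' @param dir Registry directory (created if absent).
#' @return An object of class `model_registry`.
#' @export
#' @examples
#' reg <- model_registry(tempfile("registry"))
#' cohort <- generate_cohort(c(normal = 20, OPML = 20, SCC = 20), seed = 3)
#' m1 <- update_model(reg, cohort)
#' m1$version
model_registry <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "models"), showWarnings = FALSE)
  structure(list(dir = dir), class = "model_registry")
}

records_path <- function(registry) file.path(registry$dir, "records.jsonl")

#' @export
print.model_registry <- function(x, ...) {
  n <- nrow(registry_records(x))
  cat("<model_registry> ", x$dir, "\n  ", n, " stored record",
      if (n == 1) "" else "s", "\n", sep = "")
  invisible(x)
}

#' Read the accumulated training records of a registry
#'
#' @param registry A [model_registry()].
#' @return Score-record tibble (possibly empty).
#' @export
registry_records <- function(registry) {
  p <- records_path(registry)
  if (!file.exists(p)) {
    return(tibble::tibble(site_id = character(), anatomical_site = character(),
                          score = numeric(), label = character(),
                          source = character()))
  }
  lines <- readLines(p)
  dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}

append_records <- function(registry, records) {
  records <- validate_score_records(records)
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                     digits = I(17))
  }, character(1))
  cat(lines, file = records_path(registry), sep = "\n", append = TRUE)
  invisible(registry)
}

model_path <- function(registry, group, version) {
  file.path(registry$dir, "models",
            paste0(gsub(":", "_", group), "_v", version, ".json"))
}

#' List stored model versions for a group
#'
#' @param registry A [model_registry()].
#' @param group Site group label (see [fit_model()]).
#' @return Integer vector of stored versions (sorted).
#' @export
registry_versions <- function(registry, group) {
  pattern <- paste0("^", gsub(":", "_", group), "_v([0-9]+)\\.json$")
  files <- list.files(file.path(registry$dir, "models"))
  hits <- regmatches(files, regexec(pattern, files))
  sort(as.integer(vapply(hits[lengths(hits) == 2],
                         function(h) h[2], character(1))))
}

#' Retrieve a stored model version
#'
#' @param registry A [model_registry()].
#' @param group Site group label.
#' @param version Version to fetch; `NULL` for the latest.
#' @return A `threshold_model`.
#' @export
get_model <- function(registry, group = "all_sites", version = NULL) {
  versions <- registry_versions(registry, group)
  if (length(versions) == 0) {
    stop("no model stored for group '", group, "'", call. = FALSE)
  }
  if (is.null(version)) version <- max(versions)
  if (!(version %in% versions)) {
    stop("version ", version, " not stored for group '", group, "'",
         call. = FALSE)
  }
  read_model(model_path(registry, group, version))
}

#' Append new records and retrain a group's model
#'
#' Appends confirmed records to the registry's append-only store, refits
#' the threshold model on the full accumulated data, and stores it under
#' the next version number. Historical versions are never modified.
#'
#' @param registry A [model_registry()].
#' @param new_records Score-record tibble to append (may be empty).
#' @param group Site group label (see [fit_model()]).
#' @param normal_source `"patient"` or `"healthy_volunteer"`.
#' @return The newly stored `threshold_model`.
#' @export
update_model <- function(registry, new_records, group = "all_sites",
                         normal_source = "patient") {
  stopifnot(inherits(registry, "model_registry"))
  if (nrow(new_records) > 0) append_records(registry, new_records)
  all_records <- registry_records(registry)
  versions <- registry_versions(registry, group)
  next_version <- if (length(versions) == 0) 1L else max(versions) + 1L
  model <- fit_model(all_records, group = group,
                     normal_source = normal_source, version = next_version)
  write_model(model, model_path(registry, group, next_version))
  model
}
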