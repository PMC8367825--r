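#' Read and write lesion score tables
#'
#' A score table records, per imaged site, the scalar R610/R545 lesion
#' statistic together with its histopathology label. The CSV header is
#' `site_id,anatomical_site,score,label,source` where `label` is one of
#' `normal`, `OPML`, `SCC` and `source` is `patient` or `healthy_volunteer`
#' (healthy-volunteer normals can replace patient normals in site-specific
#' classifiers to sidestep field-cancerization bias).
#'
#' @param records Tibble/data frame with the five score-table columns.
#' @param path CSV file path.
#' @return [read_score_table()] returns a validated tibble;
#'   [write_score_table()] invisibly returns `path`.
#' @export
write_score_table <- function(records, path) {
  records <- validate_score_records(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(site_id = "character"))
  validate_score_records(df)
}

score_labels <- c("normal", "OPML", "SCC")
score_sources <- c("patient", "healthy_volunteer")

#' Validate a table of lesion score records
#'
#' @param records Data frame with columns `site_id`, `anatomical_site`,
#'   `score`, `label`, `source`.
#' @return The records as a tibble, or an error naming the offending row.
#' @export
validate_score_records <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("site_id", "anatomical_site", "score", "label", "source")
  if (!all(needed %in% names(records))) {
    stop("score table missing column(s): ",
         paste(setdiff(needed, names(records)), collapse = ", "),
         call. = FALSE)
  }
  records <- records[needed]
  if (nrow(records) == 0) return(records)
  bad <- which(!(records$label %in% score_labels))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": unknown label '", records$label[bad[1]], "'",
         call. = FALSE)
  }
  bad <- which(!(records$source %in% score_sources))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": unknown source '", records$source[bad[1]], "'",
         call. = FALSE)
  }
  bad <- which(!is.finite(records$score) | records$score <= 0)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": score must be a positive real", call. = FALSE)
  }
  site_group(records$anatomical_site)  # errors on unknown vocabulary
  records
}
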