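.study_levels <- list(height_m = c("40", "50"),
                      angle_deg = c("-45", "-90"),
                      speed_m_s = c("2", "4", "6"))

.check_levels <- function(data, factor_levels) {
  for (col in names(factor_levels)) {
    if (!col %in% names(data)) next
    bad <- setdiff(unique(as.character(data[[col]])),
                   as.character(factor_levels[[col]]))
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "),
                   paste(factor_levels[[col]], collapse = ", ")))
  }
  invisible(data)
}

.check_counts <- function(data, col = "count") {
  v <- data[[col]]
  bad <- which(is.na(v) | v < 0 | v != round(v))
  if (length(bad))
    stop(sprintf("column '%s' must hold non-negative integers; offending row(s): %s",
                 col, paste(utils::head(bad, 10), collapse = ", ")))
  data[[col]] <- as.integer(v)
  data
}

.apply_column_map <- function(data, column_map) {
  if (is.null(column_map)) return(data)
  for (canonical in names(column_map)) {
    src <- column_map[[canonical]]
    if (!src %in% names(data))
      stop(sprintf("column mapping names '%s' which is not in the file", src))
    names(data)[names(data) == src] <- canonical
  }
  data
}

#' Read a per-video count table from CSV
#'
#' Expects the canonical columns `video_id`, `flight_id`, `site_id`,
#' `height_m`, `angle_deg`, `speed_m_s`, `count`; a `column_map`
#' (`canonical = "file header"`) adapts differently-named deposits. Counts
#' must be non-negative integers and factor columns must use the allowed
#' levels (pass `factor_levels = NULL` to skip the level check).
#'
#' @param path CSV file path.
#' @param column_map optional named character vector/list mapping canonical
#'   column names to the file's headers.
#' @param factor_levels named list of allowed levels per factor column;
#'   defaults to the study design levels.
#' @return a validated data.frame.
#' @export
read_count_table <- function(path, column_map = NULL,
                             factor_levels = .study_levels) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  data <- .apply_column_map(data, column_map)
  need <- c("video_id", "flight_id", "site_id", "height_m", "angle_deg",
            "speed_m_s", "count")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- .check_counts(data)
  if (!is.null(factor_levels)) .check_levels(data, factor_levels)
  data[, need]
}

#' Read a per-video, per-coder rating table from CSV
#'
#' Canonical columns `video_id`, `coder_id`, `zone`, `count`; `zone` must be
#' `"high"` or `"low"`.
#'
#' @inheritParams read_count_table
#' @return a validated data.frame.
#' @export
read_coder_table <- function(path, column_map = NULL) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  data <- .apply_column_map(data, column_map)
  need <- c("video_id", "coder_id", "zone", "count")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- .check_counts(data)
  .check_levels(data, list(zone = c("high", "low")))
  data[, need]
}

#' Write a table as canonical CSV
#'
#' UTF-8, comma-separated, "." decimal, headers, no row names, no quoting of
#' numerics — byte-identical across platforms for identical input.
#'
#' @param data a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Sections: `camera` ([camera_model()] fields), `design` (sites, flights,
#' factor lists), `simulation` ([sim_config()] fields), `inference`
#' (`predictors`, `n_quad`, `reduced_filter`), `agreement`, plus a
#' mandatory top-level `seed`. Missing fields fall back to the study
#' defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' Build a pipeline configuration from a list
#'
#' @param cfg a (possibly partial) nested list with the sections of
#'   [read_pipeline_config()]. A `seed` is mandatory.
#' @return a validated `pipeline_config`.
#' @export
as_pipeline_config <- function(cfg = list()) {
  if (is.null(cfg$seed)) stop("config must set a seed")
  defaults <- list(
    camera = list(image_width_px = 640, image_height_px = 512,
                  focal_length_mm = 9, pixel_pitch_um = 12,
                  frame_rate_fps = 30),
    design = list(n_sites = 5, flights_per_site = 8,
                  heights = c(40, 50), angles = c(-45, -90),
                  speeds = c(2, 4, 6), transect_length_m = 220,
                  canopy_height_m = 25),
    simulation = list(mode = "glmm"),
    inference = list(predictors = c("speed_m_s", "height_m", "angle_deg"),
                     n_quad = 25, reduced_filter = TRUE),
    agreement = list(),
    seed = NULL)
  merged <- utils::modifyList(defaults, cfg)
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "pipeline_config")
}
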