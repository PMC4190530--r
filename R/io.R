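# Plain-text readers/writers for the package's tabular formats.

#' Read and write phase-solubility datasets
#'
#' CSV schema: `cd_total_M`, `s_total_M`, and optionally `replicate` and
#' `temperature_K`. Extra columns are ignored with a warning. The writer
#' emits a JSON metadata sidecar (`<path>.json`) carrying any generating
#' parameters attached to the dataset.
#'
#' @param path CSV file path.
#' @param data A phase-solubility tibble (see [sim_phase_solubility()]).
#' @return `read_phase_solubility()` returns a tibble;
#'   `write_phase_solubility()` returns `path` invisibly.
#' @name phase_solubility_io
NULL

#' @rdname phase_solubility_io
#' @export
read_phase_solubility <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  .require_columns(data, c("cd_total_M", "s_total_M"), sprintf("`%s`", path))
  extra <- setdiff(names(data), c("cd_total_M", "s_total_M", "replicate",
                                  "temperature_K"))
  if (length(extra) > 0) {
    warn(sprintf("Ignoring extra column%s in %s: %s.",
                 if (length(extra) > 1) "s" else "", path,
                 paste(extra, collapse = ", ")))
    data <- data[, setdiff(names(data), extra)]
  }
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    attr(data, "params") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  data
}

#' @rdname phase_solubility_io
#' @export
write_phase_solubility <- function(data, path) {
  .require_columns(data, c("cd_total_M", "s_total_M"), "`data`")
  readr::write_csv(data, path)
  params <- attr(data, "params")
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read and write pulling work ensembles
#'
#' CSV schema: a `lambda_A` column followed by one work column per repeat
#' (`work_1`, `work_2`, ...), in kcal/mol. The reader returns the long
#' format used by the PMF estimators and attaches `temperature_K`.
#'
#' @param path CSV file path.
#' @param work A long work-ensemble tibble (`lambda_A`, `repeat_id`,
#'   `work_kcal_mol`).
#' @param temperature Temperature in K to attach on read; defaults to the
#'   value stored by [write_work_ensemble()]'s JSON sidecar, if present.
#' @return `read_work_ensemble()` returns a long tibble;
#'   `write_work_ensemble()` returns `path` invisibly.
#' @name work_ensemble_io
NULL

#' @rdname work_ensemble_io
#' @export
read_work_ensemble <- function(path, temperature = NULL) {
  wide <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  .require_columns(wide, "lambda_A", sprintf("`%s`", path))
  work_cols <- setdiff(names(wide), "lambda_A")
  if (length(work_cols) == 0) {
    abort(sprintf("`%s` has no work columns.", path))
  }
  long <- tidyr::pivot_longer(wide, -"lambda_A", names_to = "repeat_id",
                              values_to = "work_kcal_mol")
  long$repeat_id <- match(long$repeat_id, work_cols)
  long <- dplyr::arrange(long, .data$repeat_id, .data$lambda_A)
  meta_path <- paste0(path, ".json")
  if (is.null(temperature) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    temperature <- meta$temperature_K
  }
  attr(long, "temperature_K") <- temperature
  long
}

#' @rdname work_ensemble_io
#' @export
write_work_ensemble <- function(work, path, temperature = NULL) {
  .require_columns(work, c("lambda_A", "repeat_id", "work_kcal_mol"),
                   "`work`")
  temperature <- temperature %||% attr(work, "temperature_K")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(work[, c("lambda_A", "repeat_id", "work_kcal_mol")],
                  repeat_id = paste0("work_", .data$repeat_id)),
    names_from = "repeat_id", values_from = "work_kcal_mol"
  )
  readr::write_csv(dplyr::arrange(wide, .data$lambda_A), path)
  if (!is.null(temperature)) {
    jsonlite::write_json(list(temperature_K = temperature),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and write PMF profiles and distance series
#'
#' PMF profiles are written as CSV (`lambda_A`, `pmf_kcal_mol`,
#' `sd_kcal_mol`); distance series as CSV (`time_ns`, `distance_A`).
#'
#' @param profile A `pmf_profile` tibble.
#' @param series A `distance_series` tibble.
#' @param path CSV file path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name series_io
NULL

#' @rdname series_io
#' @export
write_pmf_profile <- function(profile, path) {
  .require_columns(profile, c("lambda_A", "pmf_kcal_mol", "sd_kcal_mol"),
                   "`profile`")
  readr::write_csv(as_tibble(profile), path)
  invisible(path)
}

#' @rdname series_io
#' @export
read_distance_series <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    time_ns = readr::col_double(),
    distance_A = readr::col_double(),
    .default = readr::col_guess()
  ))
  .require_columns(data, c("time_ns", "distance_A"), sprintf("`%s`", path))
  class(data) <- c("distance_series", class(data))
  data
}

#' @rdname series_io
#' @export
write_distance_series <- function(series, path) {
  .require_columns(series, c("time_ns", "distance_A"), "`series`")
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}

#' Read a multi-frame XYZ coordinate trajectory
#'
#' Parses the plain multi-frame XYZ format: for each frame an atom-count
#' line, a comment line, then `element x y z` rows. The frame time in ns is
#' taken from the first number found in the comment line (e.g. `t = 0.25
#' ns`); if a comment carries none, frames are numbered from 0 with
#' `dt_fallback` spacing.
#'
#' @param path XYZ file path.
#' @param dt_fallback Frame spacing in ns used when comments carry no time
#'   (default 1).
#' @return A tibble: `time_ns`, `atom`, `element`, `x`, `y`, `z`.
#' @export
read_xyz_trajectory <- function(path, dt_fallback = 1) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      abort(sprintf("Malformed XYZ at line %d: expected an atom count.", i))
    }
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    tm <- regmatches(comment, regexpr("-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?", comment))
    time_ns <- if (length(tm) == 1) as.numeric(tm) else frame * dt_fallback
    rows <- lines[(i + 2L):(i + 1L + n)]
    if (length(rows) < n || anyNA(rows)) {
      abort(sprintf("Truncated XYZ frame starting at line %d.", i))
    }
    parts <- strsplit(trimws(rows), "\\s+")
    out[[length(out) + 1L]] <- tibble(
      time_ns = time_ns,
      atom = seq_len(n),
      element = vapply(parts, `[`, character(1), 1L),
      x = as.numeric(vapply(parts, `[`, character(1), 2L)),
      y = as.numeric(vapply(parts, `[`, character(1), 3L)),
      z = as.numeric(vapply(parts, `[`, character(1), 4L))
    )
    i <- i + 2L + n
    frame <- frame + 1L
  }
  if (length(out) == 0) abort(sprintf("`%s` contains no XYZ frames.", path))
  dplyr::bind_rows(out)
}
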