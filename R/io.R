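# Delimited-text I/O. All tables are CSV with a header, UTF-8, "." decimal;
# units are encoded in column names (time_hr, cfu_per_ml) so numbers are
# never ambiguous.

require_columns <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("'", path, "' is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

check_numeric_column <- function(df, col, path) {
  raw <- df[[col]]
  parsed <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(parsed) & !is.na(raw) & raw != "")
  if (length(bad)) {
    abort(paste0("'", path, "' column '", col, "': non-numeric value '",
                 raw[bad[1]], "' at data row ", bad[1]))
  }
  parsed
}

#' Read culture trajectories from a CSV file
#'
#' Expects header columns `strain`, `density_label`, `time_hr`,
#' `cfu_per_ml`. Rows are grouped by (strain, density_label) and sorted by
#' time; duplicated (culture, time) rows — replicate measurements — are
#' averaged and the number of collapsed rows is reported as a message.
#'
#' @param path CSV file path.
#' @return A tibble with columns `strain`, `density_label`, `n0`,
#'   `time_hr`, `cfu_per_ml`; `n0` is each culture's earliest value.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  require_columns(df, c("strain", "density_label", "time_hr", "cfu_per_ml"), path)
  df$time_hr <- check_numeric_column(df, "time_hr", path)
  df$cfu_per_ml <- check_numeric_column(df, "cfu_per_ml", path)
  incomplete <- !stats::complete.cases(df[, c("strain", "density_label", "time_hr", "cfu_per_ml")])
  if (any(incomplete)) {
    abort(paste0("'", path, "' has ", sum(incomplete),
                 " malformed row(s); first at data row ", which(incomplete)[1]))
  }
  n_in <- nrow(df)
  out <- df |>
    dplyr::group_by(.data$strain, .data$density_label, .data$time_hr) |>
    dplyr::summarise(cfu_per_ml = mean(.data$cfu_per_ml), .groups = "drop_last") |>
    dplyr::arrange(.data$time_hr, .by_group = TRUE) |>
    dplyr::mutate(n0 = .data$cfu_per_ml[1], .after = "density_label") |>
    dplyr::ungroup()
  if (nrow(out) < n_in) {
    message(n_in - nrow(out), " duplicated (culture, time) row(s) averaged.")
  }
  out
}

#' Write culture trajectories to CSV
#'
#' @param trajectories Tibble as produced by [generate_dataset()] or
#'   [read_trajectories()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  require_columns(trajectories, c("strain", "density_label", "time_hr", "cfu_per_ml"),
                  "trajectories")
  readr::write_csv(trajectories, path, progress = FALSE)
  invisible(path)
}

#' Read replicate-level plate counts from CSV
#'
#' Expects the trajectory columns plus `replicate`, `colonies`,
#' `dilution_factor` (and optionally `lod`). `cfu_per_ml` consistency with
#' `colonies * dilution_factor / plated_volume_ml` is the generator's
#' responsibility and is not rescaled here.
#'
#' @param path CSV file path.
#' @return A tibble of replicate-level records.
#' @export
read_plate_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  require_columns(df, c("strain", "density_label", "time_hr", "replicate",
                        "colonies", "dilution_factor", "cfu_per_ml"), path)
  for (col in c("time_hr", "replicate", "colonies", "dilution_factor", "cfu_per_ml")) {
    df[[col]] <- check_numeric_column(df, col, path)
  }
  if ("lod" %in% names(df)) df$lod <- as.logical(df$lod)
  as_tibble(df)
}

#' Write replicate-level plate counts to CSV
#'
#' @param counts Replicate-level tibble (`generate_dataset()$counts`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_counts <- function(counts, path) {
  require_columns(counts, c("strain", "density_label", "time_hr", "replicate",
                            "colonies", "dilution_factor", "cfu_per_ml"), "counts")
  readr::write_csv(counts, path, progress = FALSE)
  invisible(path)
}
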