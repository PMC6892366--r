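#' Read a measurement CSV of raw peak areas
#'
#' Expects a delimited text file with header columns `replicate`,
#' `metabolite`, `mass_shift`, `peak_area` (comment lines starting with
#' `#` are ignored). Rows are validated: metabolites must be one of
#' citrate, glutamate, alpha_ketoglutarate, succinate, malate; peak areas
#' non-negative; (replicate, metabolite, mass_shift) unique; mass shifts
#' within each metabolite's carbon count. Violations are rejected with the
#' offending row cited.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the four columns above.
#' @export
read_measurement_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  m <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  validate_measurements(m, source = path)
}

#' Write a measurement table (or any tidy result) as stamped CSV
#'
#' Output files begin with comment lines recording the package version
#' and, when available, the checksum of the transition table behind the
#' numbers, so a result can always be traced to its model.
#'
#' @param measurements A tibble of measurements (columns `replicate`,
#'   `metabolite`, `mass_shift`, `peak_area`).
#' @param path Output path.
#' @param table_checksum Optional transition-table checksum to embed.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(measurements, path, table_checksum = NULL) {
  validate_measurements(measurements)
  write_stamped_csv(measurements, path, table_checksum)
}

write_stamped_csv <- function(df, path, table_checksum = NULL) {
  header <- c(
    sprintf("# tcatrace %s", as.character(packageVersion("tcatrace"))),
    if (!is.null(table_checksum)) {
      sprintf("# transition_table_checksum: %s", table_checksum)
    }
  )
  writeLines(header, path)
  # plain formatting keeps files byte-stable across locales
  readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
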