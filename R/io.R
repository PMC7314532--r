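# Plain-text I/O for diffusion curves and calibration tables. Curves travel
# as CSV (time_s, conc_uM) with a commented header block carrying the
# metadata; calibration tables as two-column CSV (conc_mM, voltage_mV).

#' Write a diffusion curve to CSV
#'
#' Metadata (`distance_um`, `depth_um`, `medium`, `animal_id`, `group`) is
#' stored in `# key: value` header lines above the `time_s,conc_uM` table.
#'
#' @param curve A [diffusion_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "diffusion_curve"))
  hdr <- c(sprintf("# distance_um: %.10g", curve$distance),
           sprintf("# depth_um: %s", format(curve$depth, digits = 10)),
           sprintf("# medium: %s", curve$medium),
           sprintf("# animal_id: %s", curve$animal_id),
           sprintf("# group: %s", curve$group))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(time_s = curve$times, conc_uM = curve$concentration),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a diffusion curve written by [write_curve_csv()]
#'
#' @param path CSV file path.
#' @return A [diffusion_curve()].
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  na_chr <- function(x) if (is.null(x) || x == "NA") NA_character_ else x
  diffusion_curve(df$time_s, df$conc_uM,
                  distance = as.numeric(meta$distance_um),
                  depth = suppressWarnings(as.numeric(meta$depth_um)),
                  medium = meta$medium,
                  animal_id = na_chr(meta$animal_id),
                  group = na_chr(meta$group))
}

#' Write a calibration table to CSV
#' @param table A [calibration_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  utils::write.csv(data.frame(conc_mM = table$concentrations,
                              voltage_mV = table$voltages),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration table from CSV
#' @param path CSV with columns `conc_mM`, `voltage_mV`.
#' @return A [calibration_table()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  calibration_table(df$conc_mM, df$voltage_mV)
}
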