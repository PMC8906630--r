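# Skin-dose tables from nanoDot OSLD readings.
#
# On the first treatment fraction, three OSLD chips are read per
# measurement site (upper/lower/inner/outer of the nipple, irradiated
# breast) and averaged into one site dose in cGy; the four site doses are
# averaged again into the patient mean.

#' Average an OSLD triplet into a site dose
#'
#' @param readings Exactly three positive dose readings in cGy.
#' @return Arithmetic mean dose (cGy).
#' @examples
#' average_triplet(c(221.0, 222.0, 222.4))
#' @export
average_triplet <- function(readings) {
  if (length(readings) != 3L)
    stop("an OSLD group holds exactly 3 readings, got ", length(readings))
  if (!all(is.finite(readings)) || any(readings <= 0))
    stop("OSLD readings must be positive dose values in cGy")
  mean(readings)
}

#' Per-patient mean skin dose
#'
#' @param doses The four site doses (upper, lower, inner, outer) in cGy,
#'   as a length-4 vector.
#' @return Arithmetic mean (cGy). Printed tables round this to 0.1 cGy.
#' @export
patient_mean <- function(doses) {
  if (length(doses) != 4L || any(!is.finite(doses)))
    stop("all four site doses (upper, lower, inner, outer) are required")
  mean(doses)
}

#' Construct and validate a dose table
#'
#' One row per patient with the four site doses in cGy. A `mean` column is
#' recomputed if absent; if present it must agree with the arithmetic mean
#' of the sites to within 0.05 cGy (printed-table rounding).
#'
#' @param df Data frame with columns `patient_id`, `upper`, `lower`,
#'   `inner`, `outer` and optionally `mean`.
#' @return A tibble of class `dose_table`.
#' @export
dose_table <- function(df) {
  need <- c("patient_id", .site_levels)
  if (!all(need %in% names(df)))
    stop("dose table needs columns: ", paste(need, collapse = ", "))
  tbl <- tibble::as_tibble(df[, c(need, intersect("mean", names(df)))])
  recomputed <- rowMeans(as.matrix(tbl[, .site_levels]))
  if ("mean" %in% names(tbl)) {
    off <- abs(tbl$mean - recomputed) > 0.05 + 1e-9
    if (any(off))
      stop("printed mean disagrees with site doses beyond 0.05 cGy for patient(s): ",
           paste(tbl$patient_id[off], collapse = ", "))
  } else {
    tbl$mean <- recomputed
  }
  class(tbl) <- c("dose_table", class(tbl))
  tbl
}

#' Read / write a dose table as CSV
#'
#' Dialect: header `patient_id,upper,lower,inner,outer[,mean]`, doses in
#' cGy, UTF-8, '.' decimal separator.
#' @param path CSV path.
#' @return [read_dose_table()] returns a `dose_table`;
#'   [write_dose_table()] returns `path` invisibly.
#' @export
read_dose_table <- function(path) {
  dose_table(utils::read.csv(path, colClasses = c(patient_id = "character")))
}

#' @rdname read_dose_table
#' @param table A `dose_table`.
#' @export
write_dose_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' The packaged 20-patient OSLD skin-dose table
#'
#' Skin doses (cGy) measured with nanoDot OSLDs on the first fraction of
#' whole-breast radiotherapy for a published 20-patient cohort; shipped as
#' a plain CSV so the dosimetry summaries are reproducible without any
#' external data.
#' @return A `dose_table` with 20 rows.
#' @export
osld_dose_table <- function() {
  read_dose_table(system.file("extdata", "osld_skin_doses.csv",
                              package = "dermachroma", mustWork = TRUE))
}

#' Which sites carry the row minima and maxima
#'
#' Counts, over patients, how often each site is the lowest and the highest
#' dose in its row. Ties increment every tied site, so counts can exceed
#' the number of rows. Also reports how often the row maximum falls on the
#' upper or lower site (the tangential-field entrance/exit regions).
#'
#' @param table A `dose_table`.
#' @return List with named count vectors `min_counts`, `max_counts`, the
#'   scalar `max_upper_or_lower`, and `n_rows`.
#' @export
site_extremes <- function(table) {
  m <- as.matrix(table[, .site_levels])
  mins <- sweep(m, 1L, apply(m, 1L, min), `==`)
  maxs <- sweep(m, 1L, apply(m, 1L, max), `==`)
  list(min_counts = colSums(mins),
       max_counts = colSums(maxs),
       max_upper_or_lower = sum(maxs[, "upper"] | maxs[, "lower"]),
       n_rows = nrow(m))
}

#' Extreme of the per-patient mean doses
#'
#' @param table A `dose_table`.
#' @param which `"min"` (default) for the lowest patient mean dose in the
#'   cohort, `"max"` for the highest.
#' @return Dose in cGy.
#' @export
cohort_min_mean <- function(table, which = c("min", "max")) {
  which <- match.arg(which)
  if (which == "min") min(table$mean) else max(table$mean)
}
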