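# Biosorter time-of-flight (TOF) to fragment-size calibration.
#
# The standard curve regresses TOF on the diameter of standard-sized beads
# (TOF = slope * size + intercept); fragment sizes are obtained by
# inverting the fitted line. The regression direction follows the assay
# (TOF on size), which differs from size-on-TOF under noisy calibration.

#' Fit the bead standard curve
#'
#' Ordinary least squares of TOF readings on bead diameter. Multiple
#' readings per bead size enter as individual points (no pre-averaging),
#' preserving least-squares weighting.
#'
#' @param bead_sizes Bead diameters in micrometres (one per reading).
#' @param tof_readings Matching TOF readings in sorter units.
#' @return A `BeadCalibration`: list with `slope` (units/um), `intercept`
#'   (units), `r_squared`, and the input points.
#' @export
fit_calibration <- function(bead_sizes, tof_readings) {
  if (length(bead_sizes) != length(tof_readings))
    stop("fit_calibration: sizes and readings differ in length")
  if (length(unique(bead_sizes)) < 2)
    stop("fit_calibration: degenerate design, need >= 2 distinct bead sizes")
  fit <- stats::lm(tof_readings ~ bead_sizes)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("fit_calibration: zero slope")
  r2 <- if (stats::var(tof_readings) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)  # exact fits are valid input
  structure(list(bead_sizes = bead_sizes, tof_readings = tof_readings,
                 slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "BeadCalibration")
}

#' @export
print.BeadCalibration <- function(x, ...) {
  cat(sprintf("BeadCalibration: TOF = %.4g * size + %.4g (R^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, length(x$bead_sizes)))
  invisible(x)
}

#' Persist / restore a calibration as JSON
#' @param cal A `BeadCalibration`.
#' @param path File path.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "BeadCalibration")
}

#' Estimate fragment sizes from TOF
#'
#' Inverts the standard curve: size = (TOF - intercept) / slope. Negative
#' predicted sizes are flagged in a `size_flag` column, never silently
#' clamped.
#'
#' @param cal A fitted `BeadCalibration`.
#' @param table Fragment table with `tof` set.
#' @return The table with `size` (um) filled in.
#' @export
size_from_tof <- function(cal, table) {
  if (!inherits(cal, "BeadCalibration") || is.null(cal$slope))
    stop("size_from_tof: unfitted calibration")
  if (cal$slope == 0) stop("size_from_tof: zero slope")
  table$size <- (table$tof - cal$intercept) / cal$slope
  table$size_flag <- ifelse(!is.na(table$size) & table$size <= 0,
                            "nonpositive", "")
  if (any(table$size_flag == "nonpositive"))
    warning("size_from_tof: ", sum(table$size_flag == "nonpositive"),
            " fragment(s) with non-positive predicted size")
  table
}

#' Predict the TOF gate for a size window
#'
#' Maps a diameter window through the forward model; bounds are returned in
#' ascending order regardless of slope sign.
#'
#' @param cal A fitted `BeadCalibration`.
#' @param size_lo,size_hi Window in micrometres, `size_lo < size_hi`.
#' @return Numeric `c(tof_lo, tof_hi)`.
#' @export
predict_gate <- function(cal, size_lo, size_hi) {
  if (!inherits(cal, "BeadCalibration") || is.null(cal$slope))
    stop("predict_gate: unfitted calibration")
  if (size_lo > size_hi) stop("predict_gate: size_lo must be <= size_hi")
  sort(cal$slope * c(size_lo, size_hi) + cal$intercept)
}

#' Filter fragments to a closed size interval
#'
#' Closed on both ends, matching printed gate ranges (e.g. 211-325 and
#' 326-457 um tile without overlap).
#'
#' @param table Fragment table with `size` set.
#' @param size_lo,size_hi Interval bounds in micrometres.
#' @return Subset of the table; attribute `n_removed` counts the dropped
#'   rows.
#' @export
gate_fragments <- function(table, size_lo, size_hi) {
  keep <- !is.na(table$size) & table$size >= size_lo & table$size <= size_hi
  out <- table[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
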