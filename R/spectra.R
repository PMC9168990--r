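# Spectrum ingest, top-hat baseline subtraction, peak picking, m/z
# windowing, and internal affine mass calibration.

new_spectrum <- function(mz, intensity, sample_id = NA_character_,
                         replicate_index = NA_integer_) {
  structure(
    list(mz = as.numeric(mz), intensity = as.numeric(intensity),
         sample_id = sample_id, replicate_index = replicate_index),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, m/z %.1f-%.1f, max intensity %.3g mV\n",
              length(x$mz), min(x$mz), max(x$mz), max(x$intensity)))
  invisible(x)
}

#' Read a mass spectrum
#'
#' Text dialect: whitespace- or comma-separated `m/z intensity` rows,
#' `#` comment lines ignored; rows are sorted by m/z on read.  A minimal
#' mzML reader (first spectrum, 32/64-bit float arrays, no compression or
#' zlib) is available when the `xml2` package is installed.
#'
#' @param path File path.
#' @param format `"text"` (default, inferred) or `"mzml"`.
#' @param sample_id,replicate_index Optional metadata carried on the
#'   returned object.
#' @return A `spectrum` object: parallel numeric vectors `mz` (strictly
#'   increasing, Da) and `intensity` (mV).
#' @export
read_spectrum <- function(path, format = c("text", "mzml"),
                          sample_id = NA_character_,
                          replicate_index = NA_integer_) {
  format <- match.arg(format)
  if (format == "mzml" || grepl("\\.mzml$", tolower(path)))
    return(read_mzml(path, sample_id, replicate_index))
  if (!file.exists(path))
    glyco_stop(sprintf("spectrum file '%s' not found", path),
               "glycomig_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 3L)
    glyco_stop(sprintf("'%s': need at least 3 data rows, found %d",
                       path, length(lines)), "glycomig_format_error")
  fields <- strsplit(lines, "[,[:space:]]+")
  n_ok <- vapply(fields, length, integer(1))
  if (any(n_ok < 2L))
    glyco_stop(sprintf("'%s': malformed row '%s'", path,
                       lines[which(n_ok < 2L)[1]]), "glycomig_format_error")
  mz <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(mz) || anyNA(it))
    glyco_stop(sprintf("'%s': non-numeric values", path), "glycomig_format_error")
  o <- order(mz)
  mz <- mz[o]; it <- it[o]
  if (any(diff(mz) <= 0))
    glyco_stop(sprintf("'%s': duplicated m/z values", path),
               "glycomig_format_error")
  new_spectrum(mz, it, sample_id, replicate_index)
}

# Minimal mzML reader: first <spectrum>, profile mode, using xml2 and
# base64 decoding; supports 64/32-bit floats, no compression or zlib.
read_mzml <- function(path, sample_id = NA_character_,
                      replicate_index = NA_integer_) {
  if (!requireNamespace("xml2", quietly = TRUE))
    glyco_stop("reading mzML requires the 'xml2' package",
               "glycomig_format_error")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spec <- xml2::xml_find_first(doc, ".//spectrum")
  if (inherits(spec, "xml_missing"))
    glyco_stop(sprintf("'%s': no <spectrum> element", path),
               "glycomig_format_error")
  arrays <- xml2::xml_find_all(spec, ".//binaryDataArray")
  decode <- function(arr) {
    accs <- xml2::xml_attr(xml2::xml_find_all(arr, ".//cvParam"), "accession")
    raw <- jsonlite::base64_dec(xml2::xml_text(xml2::xml_find_first(arr, ".//binary")))
    if ("MS:1000574" %in% accs) raw <- memDecompress(raw, type = "gzip")
    size <- if ("MS:1000521" %in% accs) 4L else 8L
    vals <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                    endian = "little")
    kind <- if ("MS:1000514" %in% accs) "mz"
            else if ("MS:1000515" %in% accs) "intensity" else "other"
    list(kind = kind, vals = vals)
  }
  got <- lapply(arrays, decode)
  kinds <- vapply(got, `[[`, character(1), "kind")
  if (!all(c("mz", "intensity") %in% kinds))
    glyco_stop(sprintf("'%s': missing m/z or intensity array", path),
               "glycomig_format_error")
  mz <- got[[which(kinds == "mz")[1]]]$vals
  it <- got[[which(kinds == "intensity")[1]]]$vals
  if (length(mz) != length(it) || length(mz) < 3L)
    glyco_stop(sprintf("'%s': array length mismatch", path),
               "glycomig_format_error")
  o <- order(mz)
  new_spectrum(mz[o], it[o], sample_id, replicate_index)
}

#' Top-hat baseline subtraction
#'
#' Subtracts the morphological opening (moving minimum followed by moving
#' maximum over a window of `window_da` in m/z units) from the intensity
#' trace.  Peaks narrower than the window survive with their height; any
#' baseline feature wider than the window is removed.  The operation is
#' idempotent.
#'
#' @param spectrum A `spectrum`.
#' @param window_da Structuring-element full width in Da. Default 20: wide
#'   versus a linear-mode peak (FWHM ~2.5 Da), narrow versus baseline drift.
#' @return The baseline-subtracted `spectrum` (all intensities >= 0).
#' @export
tophat_baseline <- function(spectrum, window_da = 20) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (!is.numeric(window_da) || window_da <= 0)
    glyco_stop("window_da must be positive", "glycomig_parameter_error")
  spacing <- median(diff(spectrum$mz))
  if (window_da < spacing)
    glyco_stop(sprintf(
      "top-hat window (%.3g Da) is below the median point spacing (%.3g Da)",
      window_da, spacing), "glycomig_parameter_error")
  half <- window_da / 2
  ero <- c_roll_extreme(spectrum$mz, spectrum$intensity, half, FALSE)
  opening <- c_roll_extreme(spectrum$mz, ero, half, TRUE)
  out <- spectrum
  out$intensity <- spectrum$intensity - opening
  out
}

#' Threshold peak picking
#'
#' Local maxima (strictly greater than both neighbouring distinct values;
#' plateaus resolve to their midpoint) with baseline-subtracted height at
#' or above the threshold.  The apex m/z is refined by a least-squares
#' parabola over the points within `interp_halfwidth` of the apex (a
#' noise-robust generalization of 3-point parabolic interpolation; with
#' fewer than three points in the window it degrades to the 3-point
#' form, and to the grid position at array edges).
#'
#' @param spectrum A baseline-subtracted `spectrum`.
#' @param threshold_mv Minimum peak height in mV (default 0.050).
#' @param interp_halfwidth Half-width in Da of the apex-interpolation
#'   window (default 0.7, about two thirds of the default peak sigma;
#'   keeps noise-induced apex jitter well below 0.05 Da for minor peaks).
#' @return A `peak_list` data frame with columns `mz` and `height`,
#'   possibly empty.
#' @export
pick_peaks <- function(spectrum, threshold_mv = 0.050,
                       interp_halfwidth = 0.7) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (threshold_mv < 0)
    glyco_stop("threshold_mv must be >= 0", "glycomig_parameter_error")
  y <- spectrum$intensity
  x <- spectrum$mz
  runs <- rle(y)
  k <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out_mz <- numeric(0); out_h <- numeric(0)
  if (k >= 3L) {
    is_peak <- c(FALSE,
                 runs$values[2:(k - 1)] > runs$values[1:(k - 2)] &
                 runs$values[2:(k - 1)] > runs$values[3:k],
                 FALSE)
    idx <- which(is_peak)
    if (length(idx)) {
      apex <- (starts[idx] + ends[idx]) %/% 2L
      h <- y[apex]
      keep <- h >= threshold_mv
      apex <- apex[keep]; h <- h[keep]
      if (length(apex)) {
        out_mz <- vapply(apex, function(i)
          ls_parabola_apex(x, y, i, interp_halfwidth), numeric(1))
        out_h <- h
      }
    }
  }
  structure(data.frame(mz = out_mz, height = out_h),
            class = c("peak_list", "data.frame"))
}

# Least-squares parabola vertex over points within `half` Da of index i.
# Falls back to the exact 3-point parabola (then the grid position) when
# the window holds fewer than 4 points or the fit is not concave.
ls_parabola_apex <- function(x, y, i, half) {
  idx <- which(x >= x[i] - half & x <= x[i] + half)
  if (length(idx) >= 4L) {
    u <- x[idx] - x[i]
    fit <- stats::lm.fit(cbind(1, u, u * u), y[idx])
    b <- fit$coefficients
    if (is.finite(b[3]) && b[3] < 0) {
      v <- x[i] - b[2] / (2 * b[3])
      if (v >= x[i] - half && v <= x[i] + half) return(unname(v))
    }
  }
  parabolic_apex(x, y, i)
}

# Vertex of the parabola through (x,y) at indices i-1, i, i+1.  Falls back
# to the grid position for flat or degenerate neighbourhoods.
parabolic_apex <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  x1 <- x[i - 1L]; x2 <- x[i]; x3 <- x[i + 1L]
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  d1 <- (y2 - y1) / (x2 - x1)
  d2 <- (y3 - y2) / (x3 - x2)
  a <- (d2 - d1) / (x3 - x1)
  if (!is.finite(a) || a >= 0) return(x2)
  v <- (x1 + x2) / 2 - d1 / (2 * a)
  # keep the vertex inside the bracket
  if (v < x1 || v > x3) x2 else v
}

#' Restrict peaks to an m/z export window
#'
#' @param peaks A `peak_list`.
#' @param lo,hi Window bounds in Da (inclusive); peaks with
#'   `lo <= mz <= hi` are kept in order.
#' @return The filtered `peak_list`.
#' @export
window_filter <- function(peaks, lo, hi) {
  if (lo >= hi)
    glyco_stop("window requires lo < hi", "glycomig_parameter_error")
  out <- peaks[peaks$mz >= lo & peaks$mz <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Internal affine mass calibration
#'
#' For each theoretical calibrant mass the highest picked peak within
#' `match_tol` is taken as its observed partner; a least-squares affine
#' map observed -> theoretical is fitted (exact with two calibrants,
#' over-determined with more) and applied to every peak m/z.
#'
#' @param peaks A `peak_list`.
#' @param calibrant_mzs Theoretical calibrant m/z values
#'   (default [calibrant_masses()]).
#' @param match_tol Match tolerance in Da (default 1.5).
#' @return A list with `peaks` (calibrated `peak_list`) and `fit`, a
#'   `calibration_fit` with fields `slope`, `offset`,
#'   `n_calibrants_used`, `residuals` (theoretical minus fitted, Da) and
#'   `matched` (observed m/z, NA where unmatched).
#' @export
internal_calibrate <- function(peaks, calibrant_mzs = calibrant_masses(),
                               match_tol = 1.5) {
  observed <- rep(NA_real_, length(calibrant_mzs))
  for (j in seq_along(calibrant_mzs)) {
    cand <- which(abs(peaks$mz - calibrant_mzs[j]) <= match_tol)
    if (length(cand))
      observed[j] <- peaks$mz[cand[which.max(peaks$height[cand])]]
  }
  ok <- !is.na(observed)
  if (sum(ok) < 2L)
    glyco_stop(sprintf("only %d of %d calibrants matched within %.2f Da",
                       sum(ok), length(calibrant_mzs), match_tol),
               "glycomig_calibration_error")
  fit <- lm(theo ~ obs, data = data.frame(theo = calibrant_mzs[ok],
                                          obs = observed[ok]))
  slope <- unname(coef(fit)[2]); offset <- unname(coef(fit)[1])
  res <- rep(NA_real_, length(calibrant_mzs))
  res[ok] <- calibrant_mzs[ok] - (offset + slope * observed[ok])
  out <- peaks
  out$mz <- offset + slope * peaks$mz
  cal <- structure(
    list(slope = slope, offset = offset, n_calibrants_used = sum(ok),
         residuals = res, matched = observed),
    class = "calibration_fit")
  list(peaks = out, fit = cal)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope %.6f, offset %+.4f Da, %d calibrants, max |residual| %.4f Da\n",
              x$slope, x$offset, x$n_calibrants_used,
              max(abs(x$residuals), na.rm = TRUE)))
  invisible(x)
}
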