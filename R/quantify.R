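# Peak-to-library assignment, relative quantification, replicate
# averaging, and RSD repeatability QC.

new_glyco_profile <- function(subclass, glycoform, abundance,
                              sample_id = NA_character_, n_replicates = 1L) {
  structure(
    data.frame(subclass = subclass, glycoform = glycoform,
               abundance = abundance, stringsAsFactors = FALSE),
    sample_id = sample_id, n_replicates = n_replicates,
    class = c("glyco_profile", "data.frame"))
}

#' @export
print.glyco_profile <- function(x, ...) {
  cat(sprintf("<glyco_profile> %s: %d glycopeptides, sum %.6f (%d replicate%s)\n",
              attr(x, "sample_id"), nrow(x), sum(x$abundance),
              attr(x, "n_replicates"),
              if (identical(attr(x, "n_replicates"), 1L)) "" else "s"))
  invisible(x)
}

#' Assign calibrated peaks to library glycopeptides
#'
#' Greedy nearest-match assignment: candidate (entry, peak) pairs within
#' `assign_tol` are ranked by distance (ties broken towards the higher
#' peak, then the lower-m/z entry) and assigned one-to-one.  Overlap-
#' flagged IgG3/4 entries are excluded; unmatched entries get height 0
#' (the missing-value rule).
#'
#' @param peaks A calibrated `peak_list`.
#' @param library A `glyco_library`.
#' @param assign_tol Match tolerance in Da (default 1.0).
#' @return Data frame with one row per non-overlapped library entry:
#'   `subclass`, `glycoform`, `mz` (theoretical) and assigned `height`
#'   (mV, 0 if unmatched).
#' @export
assign_peaks <- function(peaks, library, assign_tol = 1.0) {
  lib <- library[!library$overlapped, , drop = FALSE]
  heights <- numeric(nrow(lib))
  if (nrow(peaks) > 0 && nrow(lib) > 0) {
    cand <- expand.grid(entry = seq_len(nrow(lib)), peak = seq_len(nrow(peaks)))
    cand$dist <- abs(lib$mz[cand$entry] - peaks$mz[cand$peak])
    cand <- cand[cand$dist <= assign_tol, , drop = FALSE]
    cand <- cand[order(cand$dist, -peaks$height[cand$peak],
                       lib$mz[cand$entry]), , drop = FALSE]
    entry_free <- rep(TRUE, nrow(lib))
    peak_free <- rep(TRUE, nrow(peaks))
    for (r in seq_len(nrow(cand))) {
      e <- cand$entry[r]; p <- cand$peak[r]
      if (entry_free[e] && peak_free[p]) {
        heights[e] <- peaks$height[p]
        entry_free[e] <- FALSE
        peak_free[p] <- FALSE
      }
    }
  }
  data.frame(subclass = lib$subclass, glycoform = lib$glycoform,
             mz = lib$mz, height = heights, stringsAsFactors = FALSE)
}

#' Relative intensity normalization
#'
#' Each glycopeptide height divided by the summed heights of all (non-
#' overlapped) Fc glycopeptides in the same profile, so abundances sum
#' to 1 and are invariant to uniform intensity scaling.
#'
#' @param heights Data frame from [assign_peaks()] (columns `subclass`,
#'   `glycoform`, `height`).
#' @param sample_id,replicate_index Optional metadata.
#' @return A `glyco_profile`.
#' @export
relative_intensity <- function(heights, sample_id = NA_character_,
                               replicate_index = NA_integer_) {
  total <- sum(heights$height)
  if (total <= 0)
    glyco_stop("all glycopeptide heights are zero; cannot normalize",
               "glycomig_quantification_error")
  new_glyco_profile(heights$subclass, heights$glycoform,
                    heights$height / total, sample_id = sample_id)
}

#' Average technical replicate profiles
#'
#' Element-wise arithmetic mean of 1-4 replicate relative-intensity
#' profiles of one sample; the average of simplex profiles stays on the
#' simplex.  Fewer than 4 replicates trigger a warning, not an error.
#'
#' @param profiles List of `glyco_profile`s over identical glycopeptides.
#' @param n_expected Expected replicate count (default 4).
#' @return The averaged `glyco_profile` with `n_replicates` recorded.
#' @export
average_replicates <- function(profiles, n_expected = 4L) {
  if (length(profiles) == 0L)
    glyco_stop("no replicate profiles to average", "glycomig_quantification_error")
  if (length(profiles) < n_expected)
    warning(sprintf("averaging %d replicate(s); expected %d",
                    length(profiles), n_expected))
  key <- paste(profiles[[1]]$subclass, profiles[[1]]$glycoform)
  abund <- vapply(profiles, function(p) {
    if (!identical(paste(p$subclass, p$glycoform), key))
      glyco_stop("replicate profiles cover different glycopeptides",
                 "glycomig_quantification_error")
    p$abundance
  }, numeric(length(key)))
  new_glyco_profile(profiles[[1]]$subclass, profiles[[1]]$glycoform,
                    rowMeans(as.matrix(abund)),
                    sample_id = attr(profiles[[1]], "sample_id"),
                    n_replicates = length(profiles))
}

#' Replicate repeatability (RSD) quality control
#'
#' Relative standard deviation (100 * SD / mean) of the heights at target
#' m/z values across replicate spectra; by default the six minor-component
#' QC masses.  Passes when every target RSD is below the threshold.
#'
#' @param replicate_heights List (one element per replicate) of height
#'   tables from [assign_peaks()].
#' @param targets Target theoretical m/z values (default [qc_masses()]).
#' @param threshold_pct RSD pass threshold in percent (default 15).
#' @param match_tol Da tolerance for locating a target among library
#'   entries (default 0.15).
#' @return An `rsd_report`: data frame of `target_mz` and `rsd_pct`
#'   (NA where the mean height is zero, counted as failure), with
#'   attribute `pass`.
#' @export
rsd_qc <- function(replicate_heights, targets = qc_masses(),
                   threshold_pct = 15, match_tol = 0.15) {
  if (length(replicate_heights) < 2L)
    glyco_stop("RSD QC needs at least 2 replicates", "glycomig_parameter_error")
  mzs <- replicate_heights[[1]]$mz
  rsd <- vapply(targets, function(t) {
    i <- which.min(abs(mzs - t))
    if (abs(mzs[i] - t) > match_tol) return(NA_real_)
    h <- vapply(replicate_heights, function(x) x$height[i], numeric(1))
    m <- mean(h)
    if (m <= 0) return(NA_real_)
    100 * sd(h) / m
  }, numeric(1))
  out <- data.frame(target_mz = unname(targets), rsd_pct = unname(rsd))
  attr(out, "pass") <- all(!is.na(rsd) & rsd < threshold_pct)
  attr(out, "threshold_pct") <- threshold_pct
  class(out) <- c("rsd_report", "data.frame")
  out
}

#' @export
print.rsd_report <- function(x, ...) {
  cat(sprintf("<rsd_report> %s (threshold %.1f%%)\n",
              if (attr(x, "pass")) "PASS" else "FAIL",
              attr(x, "threshold_pct")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Process one spectrum through the quantification chain
#'
#' Top-hat baseline subtraction, threshold peak picking, internal affine
#' calibration (falling back to uncalibrated m/z with a warning when
#' fewer than two calibrants are found), export-window filtering, and
#' library assignment.
#'
#' @param spectrum A raw `spectrum`.
#' @param library A `glyco_library`.
#' @param config A [pipeline_config()].
#' @return List with `heights` (assignment table), `profile`
#'   (`glyco_profile`), `peaks`, and the calibration `fit` (NULL if
#'   calibration failed).
#' @export
process_spectrum <- function(spectrum, library, config = pipeline_config()) {
  sp <- tophat_baseline(spectrum, config$tophat_width)
  pk <- pick_peaks(sp, config$threshold_mv)
  cal <- tryCatch(
    internal_calibrate(pk, calibrant_masses(library), config$cal_tol),
    glycomig_calibration_error = function(e) {
      warning(sprintf("calibration failed (%s); using uncalibrated m/z",
                      conditionMessage(e)))
      list(peaks = pk, fit = NULL)
    })
  pk <- window_filter(cal$peaks, config$window[1], config$window[2])
  heights <- assign_peaks(pk, library, config$assign_tol)
  profile <- relative_intensity(heights, sample_id = spectrum$sample_id,
                                replicate_index = spectrum$replicate_index)
  list(heights = heights, profile = profile, peaks = pk, fit = cal$fit)
}

#' Estimate one sample's profile from its replicate spectra
#'
#' Runs [process_spectrum()] on each replicate and averages the replicate
#' relative-intensity profiles.
#'
#' @param spectra List of raw `spectrum` objects (technical replicates).
#' @param library A `glyco_library`.
#' @param config A [pipeline_config()].
#' @param sample_id Sample identifier for the result.
#' @return List with the averaged `profile`, per-replicate `heights`, and
#'   the `rsd` report (NULL if fewer than 2 replicates).
#' @export
estimate_profile <- function(spectra, library, config = pipeline_config(),
                             sample_id = NA_character_) {
  runs <- lapply(spectra, process_spectrum, library = library, config = config)
  prof <- average_replicates(lapply(runs, `[[`, "profile"),
                             n_expected = length(spectra))
  attr(prof, "sample_id") <- sample_id
  rsd <- if (length(runs) >= 2L)
    rsd_qc(lapply(runs, `[[`, "heights"), qc_masses(library),
           config$rsd_threshold)
  else NULL
  list(profile = prof, heights = lapply(runs, `[[`, "heights"), rsd = rsd)
}
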