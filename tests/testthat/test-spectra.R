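test_that("text spectra parse, sort on read, and reject malformed input", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "2600 0.1", "2601 0.2", "2602 0.1"), p)
  sp <- read_spectrum(p)
  expect_s3_class(sp, "spectrum")
  expect_length(sp$mz, 3)
  expect_equal(sp$intensity, c(0.1, 0.2, 0.1))

  shuffled <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2602,0.1", "2600,0.1", "2601,0.2"), shuffled)
  expect_equal(read_spectrum(shuffled)$mz, sp$mz)
  expect_equal(read_spectrum(shuffled)$intensity, sp$intensity)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_spectrum(empty), class = "glycomig_format_error")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2600 0.1", "oops", "2602 0.1"), bad)
  expect_error(read_spectrum(bad), class = "glycomig_format_error")

  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2600 0.1", "2600 0.2", "2602 0.1"), dup)
  expect_error(read_spectrum(dup), "duplicated",
               class = "glycomig_format_error")
})

test_that("a minimal mzML round-trips through the reader", {
  skip_if_not_installed("xml2")
  mz <- seq(2500, 2600, by = 0.5)
  it <- exp(-(mz - 2550)^2 / 8) + 0.01
  enc <- function(x, size) jsonlite::base64_enc(writeBin(x, raw(), size = size,
                                                         endian = "little"))
  tpl <- '<?xml version="1.0"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml">
 <run><spectrumList count="1">
  <spectrum index="0" defaultArrayLength="%d">
   <binaryDataArrayList count="2">
    <binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/>
     <cvParam accession="MS:1000514" name="m/z array"/>
     <binary>%s</binary></binaryDataArray>
    <binaryDataArray><cvParam accession="MS:1000521" name="32-bit float"/>
     <cvParam accession="MS:1000515" name="intensity array"/>
     <binary>%s</binary></binaryDataArray>
   </binaryDataArrayList>
  </spectrum>
 </spectrumList></run>
</mzML>'
  p <- withr::local_tempfile(fileext = ".mzML")
  writeLines(sprintf(tpl, length(mz), enc(mz, 8), enc(it, 4)), p)
  sp <- read_spectrum(p, format = "mzml")
  expect_equal(sp$mz, mz)
  expect_equal(sp$intensity, it, tolerance = 1e-6)  # 32-bit storage
})

test_that("top-hat of a constant trace is zero and the op is idempotent", {
  x <- seq(2400, 2600, by = 0.1)
  sp <- glycomig:::new_spectrum(x, rep(3.7, length(x)))
  out <- tophat_baseline(sp, 20)
  expect_true(all(out$intensity == 0))

  set.seed(42)
  noisy <- glycomig:::new_spectrum(x, abs(rnorm(length(x))) +
                                     0.01 * (x - 2400))
  once <- tophat_baseline(noisy, 20)
  twice <- tophat_baseline(once, 20)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-12)
})

test_that("top-hat matches the brute-force min/max filter oracle", {
  set.seed(7)
  x <- seq(2500, 2540, by = 0.1)
  y <- abs(rnorm(length(x), 0.1, 0.05)) + 0.02 * (x - 2500)
  sp <- glycomig:::new_spectrum(x, y)
  expect_equal(tophat_baseline(sp, 8)$intensity, oracle_tophat(x, y, 8),
               tolerance = 1e-12)
  # and on an irregular axis
  xr <- sort(2500 + cumsum(runif(200, 0.05, 0.3)))
  yr <- abs(rnorm(length(xr), 0.2, 0.1))
  spr <- glycomig:::new_spectrum(xr, yr)
  expect_equal(tophat_baseline(spr, 5)$intensity, oracle_tophat(xr, yr, 5),
               tolerance = 1e-12)
})

test_that("top-hat preserves narrow peaks on flat and ramped baselines", {
  peak <- make_gaussian_spectrum(2500, 1.0, fwhm = 2.5, range = c(2400, 2600))
  flat <- tophat_baseline(peak, 20)
  expect_equal(max(flat$intensity), 1.0, tolerance = 0.01)

  ramped <- make_gaussian_spectrum(2500, 1.0, fwhm = 2.5, range = c(2400, 2600),
                                   baseline = function(x) 0.002 * (x - 2400))
  deramped <- tophat_baseline(ramped, 20)
  expect_equal(max(deramped$intensity), max(flat$intensity), tolerance = 0.02)
})

test_that("top-hat rejects degenerate windows", {
  sp <- make_gaussian_spectrum(2500, 1.0)
  expect_error(tophat_baseline(sp, -1), class = "glycomig_parameter_error")
  expect_error(tophat_baseline(sp, 0.01), "spacing",
               class = "glycomig_parameter_error")
})

test_that("peak picking applies the threshold and finds isolated apices", {
  quiet <- make_gaussian_spectrum(2500, 0.04)
  expect_equal(nrow(pick_peaks(quiet, 0.05)), 0)

  one <- make_gaussian_spectrum(2602.1, 1.0)
  pk <- pick_peaks(one, 0.05)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 2602.1), 0.05)

  two <- make_gaussian_spectrum(c(2600, 2606), c(1.0, 0.8), fwhm = 2.5)
  pk2 <- pick_peaks(two, 0.05)
  expect_equal(nrow(pk2), 2)
  # against the brute-force local-maximum scan
  idx <- oracle_local_maxima(two$mz, two$intensity, 0.05)
  expect_equal(nrow(pk2), length(idx))
  expect_equal(pk2$height, two$intensity[idx], tolerance = 1e-12)
})

test_that("plateaus resolve to their midpoint", {
  x <- seq(1, 21, by = 1)
  y <- c(0, 0, 0, 1, 2, 3, 3, 3, 2, 1, rep(0, 11))
  pk <- pick_peaks(glycomig:::new_spectrum(x, y), 0.5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mz, 7)  # run of 3s spans indices 6:8
  expect_equal(pk$height, 3)
})

test_that("peak heights respect the threshold and counts are monotone", {
  set.seed(11)
  sp <- make_gaussian_spectrum(seq(2450, 3450, by = 25),
                               runif(41, 0.02, 1.2))
  thresholds <- c(0, 0.05, 0.2, 0.5, 1)
  counts <- vapply(thresholds, function(t) {
    pk <- pick_peaks(sp, t)
    expect_true(all(pk$height >= t))
    nrow(pk)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("window_filter keeps closed-interval membership in order", {
  pk <- structure(data.frame(mz = c(2400, 2600, 3600),
                             height = c(1, 2, 3)),
                  class = c("peak_list", "data.frame"))
  expect_equal(window_filter(pk, 2450, 3500)$mz, 2600)
  expect_equal(nrow(window_filter(pk[0, ], 2450, 3500)), 0)
  expect_equal(window_filter(pk, 0, Inf)$mz, pk$mz)
  expect_error(window_filter(pk, 3500, 2450), class = "glycomig_parameter_error")
})

test_that("internal calibration recovers identity, shift and affine maps", {
  cal <- calibrant_masses()
  exact <- structure(data.frame(mz = unname(cal), height = rep(1, 4)),
                     class = c("peak_list", "data.frame"))
  fit <- internal_calibrate(exact, cal)$fit
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$offset, 0, tolerance = 1e-6)
  expect_true(all(abs(fit$residuals) < 1e-9))

  shifted <- exact; shifted$mz <- shifted$mz + 0.5
  fs <- internal_calibrate(shifted, cal)
  expect_equal(fs$fit$offset, -0.5, tolerance = 1e-9)
  expect_equal(fs$fit$slope, 1, tolerance = 1e-12)
  expect_equal(fs$peaks$mz, unname(cal), tolerance = 1e-9)

  warped <- exact; warped$mz <- 1.0002 * warped$mz - 0.3
  fw <- internal_calibrate(warped, cal)
  # closed-form least-squares oracle on the same pairs
  ora <- oracle_lsq_line(warped$mz, unname(cal))
  expect_equal(fw$fit$slope, unname(ora["slope"]), tolerance = 1e-12)
  expect_equal(fw$fit$offset, unname(ora["intercept"]), tolerance = 1e-9)
  expect_equal(fw$peaks$mz, unname(cal), tolerance = 1e-6)

  # calibrating already-calibrated peaks is a no-op
  again <- internal_calibrate(fw$peaks, cal)
  expect_equal(again$peaks$mz, fw$peaks$mz, tolerance = 1e-9)
})

test_that("calibration fails cleanly with fewer than two matched calibrants", {
  lone <- structure(data.frame(mz = 2602.06, height = 1),
                    class = c("peak_list", "data.frame"))
  expect_error(internal_calibrate(lone, calibrant_masses()),
               class = "glycomig_calibration_error")
})

test_that("full chain recovers seeded peaks within 0.3 Da at high SNR", {
  lib <- build_library(subclasses = c("IgG1", "IgG2"))
  prof <- template_profile(lib)
  inst <- instrument_params(noise_sd = 0.001)
  sp <- synthesize_spectrum(prof, lib, inst, seed = 5)
  res <- process_spectrum(sp, lib, synth_config())
  heights <- res$heights
  seeded <- paste(prof$subclass, prof$glycoform)
  for (i in seq_len(nrow(heights))) {
    key <- paste(heights$subclass[i], heights$glycoform[i])
    truth <- prof$abundance[match(key, seeded)]
    if (truth * inst$total_signal < 2 * synth_config()$threshold_mv) next
    if (heights$mz[i] < 2400 || heights$mz[i] > 3500) next
    expect_gt(heights$height[i], 0)
    matched <- res$peaks$mz[which.min(abs(res$peaks$mz - heights$mz[i]))]
    expect_lt(abs(matched - heights$mz[i]), 0.3)
  }
})
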