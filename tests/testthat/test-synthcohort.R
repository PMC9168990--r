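test_that("cohorts are deterministic per seed with the stated design", {
  c1 <- generate_cohort(seed = 7)
  c2 <- generate_cohort(seed = 7)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$manifest, c2$manifest)
  c3 <- generate_cohort(seed = 8)
  expect_false(identical(c1$profiles, c3$profiles))

  m <- c1$manifest
  expect_equal(sum(m$group == "case"), 20)
  expect_equal(sum(m$group == "control"), 20)
  expect_equal(sum(m$aura), 5)
  expect_equal(sum(m$phase == "ictal"), 7)
  expect_equal(sum(m$family_history), 11)
  expect_true(all(abs(rowSums(c1$profiles) - 1) < 1e-12))
})

test_that("zero effects and zero noise reproduce the template exactly", {
  eff <- effect_spec(log_sd = 0)
  cohort <- generate_cohort(n_case = 3, n_control = 3, effects = eff,
                            seed = 1, n_aura = 1, n_ictal = 1, n_famhist = 1)
  tpl <- template_profile()
  for (i in 1:6)
    expect_equal(as.numeric(cohort$profiles[i, ]), tpl$abundance,
                 tolerance = 1e-12)
})

test_that("a case fold change shifts the targeted glycopeptide upward", {
  cohort <- generate_cohort(effects = migraine_effects(g0nf_fold = 1.5),
                            seed = 99)
  g <- cohort$manifest$group
  x <- cohort$profiles[["IgG1 G0-NF"]]
  expect_gt(mean(x[g == "case"]), mean(x[g == "control"]))
})

test_that("effects on unknown glycopeptides are rejected", {
  bad <- effect_spec(case = c("IgG1 G9F" = 2))
  expect_error(generate_cohort(effects = bad), class = "glycomig_parameter_error")
  expect_error(effect_spec(case = c("IgG1 G0F" = -1)),
               class = "glycomig_parameter_error")
})

test_that("noiseless synthesis puts apex heights proportional to abundances", {
  lib <- build_library(subclasses = c("IgG1", "IgG2"))
  prof <- template_profile(lib)
  inst <- instrument_params(noise_sd = 0, baseline_amp = 0,
                            mass_slope = 1, mass_offset = 0,
                            total_signal = 1)
  sp <- synthesize_spectrum(prof, lib, inst, seed = 1)
  # parabolic vertex height around the grid maximum, to remove the
  # <= grid/2 sampling offset from the comparison
  vertex_height <- function(x, y, i) {
    h <- x[i + 1] - x[i]
    a <- (y[i - 1] - 2 * y[i] + y[i + 1]) / (2 * h^2)
    b <- (y[i + 1] - y[i - 1]) / (2 * h)
    if (a >= 0) return(y[i])
    y[i] - b^2 / (4 * a)
  }
  for (i in which(prof$abundance > 0.004)) {
    mz_i <- glycomig:::library_mz(lib, prof$subclass[i], prof$glycoform[i])
    near <- which(abs(sp$mz - mz_i) < 1)
    apex_idx <- near[which.max(sp$intensity[near])]
    apex <- vertex_height(sp$mz, sp$intensity, apex_idx)
    expect_equal(apex, prof$abundance[i], tolerance = 1e-3,
                 label = paste(prof$subclass[i], prof$glycoform[i]))
  }
  expect_error(synthesize_spectrum(prof, lib, instrument_params(grid_step = 3)),
               class = "glycomig_parameter_error")
})

test_that("affine mass distortion is undone by the calibration chain", {
  lib <- build_library(subclasses = c("IgG1", "IgG2"))
  prof <- template_profile(lib)
  inst <- instrument_params(mass_slope = 1.0003, mass_offset = -0.4,
                            noise_sd = 0.001)
  sp <- synthesize_spectrum(prof, lib, inst, seed = 2)
  res <- process_spectrum(sp, lib, synth_config())
  expect_false(is.null(res$fit))
  expect_true(abs(res$fit$slope - 1 / 1.0003) < 1e-3)
  for (i in which(prof$abundance > 0.01)) {
    mz_i <- glycomig:::library_mz(lib, prof$subclass[i], prof$glycoform[i])
    expect_lt(min(abs(res$peaks$mz - mz_i)), 0.05)
  }
})

test_that("replicate jitter behaves like the requested CV", {
  prof <- template_profile(build_library(subclasses = c("IgG1", "IgG2")))
  lib <- build_library(subclasses = c("IgG1", "IgG2"))
  reps0 <- generate_qc_replicates(prof, n = 3, cv_pct = 0, seed = 5,
                                  library = lib,
                                  instrument = instrument_params(noise_sd = 0))
  # zero CV and zero noise: replicates are identical up to RNG-free synthesis
  expect_equal(reps0[[1]]$intensity, reps0[[2]]$intensity, tolerance = 1e-12)
  hts <- lapply(reps0, function(s)
    process_spectrum(s, lib, synth_config())$heights)
  rep0 <- rsd_qc(hts, qc_masses(lib))
  expect_true(all(rep0$rsd_pct < 1e-6))
  expect_true(attr(rep0, "pass"))

  expect_error(generate_qc_replicates(prof, n = 1),
               class = "glycomig_parameter_error")
  expect_error(generate_qc_replicates(prof, cv_pct = -5),
               class = "glycomig_parameter_error")
})

test_that("large replicate CV breaks the repeatability QC", {
  lib <- build_library(subclasses = c("IgG1", "IgG2"))
  prof <- template_profile(lib)
  fails <- vapply(1:5, function(s) {
    reps <- generate_qc_replicates(prof, n = 3, cv_pct = 40, seed = s,
                                   library = lib)
    hts <- lapply(reps, function(sp)
      process_spectrum(sp, lib, synth_config())$heights)
    !attr(rsd_qc(hts, qc_masses(lib)), "pass")
  }, logical(1))
  expect_gte(sum(fails), 4)
})

test_that("write_cohort emits readable spectra, manifest and ground truth", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(n_case = 2, n_control = 2, seed = 12,
                            n_aura = 1, n_ictal = 1, n_famhist = 1)
  manifest <- write_cohort(cohort, dir, n_replicates = 2)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(all(file.exists(manifest$rep1)))
  sp <- read_spectrum(manifest$rep1[1])
  expect_gt(length(sp$mz), 1000)
})
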