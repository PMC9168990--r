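# Synthetic cohorts and spectra with known ground truth, emulating the
# statistical structure the analysis assumes: logistic-normal subject
# variation of a compositional template, targeted case/subgroup fold
# changes, and linear-mode spectra with broad Gaussian peaks, baseline
# drift, affine mass error, and replicate intensity jitter.

#' Effect specification for the cohort generator
#'
#' Fold changes are multiplicative on the (pre-renormalization) template
#' abundance of the targeted glycopeptides.
#'
#' @param case Named numeric vector of case-vs-control fold changes, keyed
#'   by feature id (`"IgG1 G0-NF"` style).
#' @param aura,family_history Named fold-change vectors applied within the
#'   corresponding case subgroup.
#' @param log_sd Between-subject SD on the log abundance scale
#'   (default 0.15).
#' @param replicate_cv_pct Technical replicate coefficient of variation in
#'   percent (default 5, consistent with RSD < 15% repeatability).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(case = c(), aura = c(), family_history = c(),
                        log_sd = 0.15, replicate_cv_pct = 5) {
  if (any(c(case, aura, family_history) <= 0))
    glyco_stop("fold changes must be positive", "glycomig_parameter_error")
  if (replicate_cv_pct < 0 || log_sd < 0)
    glyco_stop("log_sd and replicate_cv_pct must be >= 0",
               "glycomig_parameter_error")
  structure(list(case = case, aura = aura, family_history = family_history,
                 log_sd = log_sd, replicate_cv_pct = replicate_cv_pct),
            class = "effect_spec")
}

#' The default migraine effect preset
#'
#' Emulates the reported cohort findings: IgG1 G0-NF elevated in cases
#' (fold 1.5); within-case subgroup shifts for aura (IgG1 G1 and IgG2 G0
#' up, IgG2 G0N down) and for family history (IgG3/4 G2FS down).  Effect
#' magnitudes are not printed anywhere, so the subgroup folds are package
#' choices (1.4 and 0.7).
#'
#' @inheritParams effect_spec
#' @param g0nf_fold Case fold change on IgG1 G0-NF (default 1.5).
#' @return An `effect_spec`.
#' @export
migraine_effects <- function(g0nf_fold = 1.5, log_sd = 0.15,
                             replicate_cv_pct = 5) {
  effect_spec(
    case = c("IgG1 G0-NF" = g0nf_fold),
    aura = c("IgG1 G1" = 1.4, "IgG2 G0" = 1.4, "IgG2 G0N" = 0.7),
    family_history = c("IgG3/4 G2FS" = 0.7),
    log_sd = log_sd, replicate_cv_pct = replicate_cv_pct)
}

#' Template mean glycoform profile
#'
#' A plausible human serum IgG Fc glycoform distribution (dominated by
#' G0F/G1F/G2F, subclass weights roughly 60/32/8 for IgG1/IgG2/IgG3-4),
#' bundled as a text fixture.  It is a documented synthetic stand-in, not
#' a measured profile.  Overlap-flagged IgG3/4 entries are removed and the
#' remainder renormalized to the simplex.
#'
#' @param library A `glyco_library` (default [build_library()]).
#' @param subclasses Subclasses to retain (default all in the library).
#' @return A `glyco_profile` summing to 1.
#' @export
template_profile <- function(library = build_library(),
                             subclasses = unique(library$subclass)) {
  path <- system.file("extdata", "template_profile_synthetic.csv",
                      package = "glycomig")
  tpl <- read.csv(path, stringsAsFactors = FALSE)
  lib <- library[!library$overlapped & library$subclass %in% subclasses, ,
                 drop = FALSE]
  idx <- match(paste(lib$subclass, lib$glycoform),
               paste(tpl$subclass, tpl$glycoform))
  if (anyNA(idx))
    glyco_stop("library entry missing from template fixture",
               "glycomig_parameter_error")
  w <- tpl$weight[idx]
  new_glyco_profile(lib$subclass, lib$glycoform, w / sum(w),
                    sample_id = "template")
}

#' Generate a synthetic case/control cohort
#'
#' Per subject, the log template abundances are perturbed by iid normal
#' noise (`log_sd`), case and subgroup fold changes are added on the log
#' scale for the targeted glycopeptides, and the result is renormalized
#' to the simplex (logistic-normal variation).  The default design is
#' 20 cases + 20 controls with case subgroup counts 5 aura, 7 ictal and
#' 11 family-history, and sex 7M/13F (cases) vs 9M/11F (controls).
#'
#' @param n_case,n_control Group sizes (default 20 each).
#' @param effects An [effect_spec()] (default [migraine_effects()]).
#' @param template A `glyco_profile` (default [template_profile()]).
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @param n_aura,n_ictal,n_famhist Case subgroup counts.
#' @return A `synthetic_cohort` list: `manifest` (sample_id, group, aura,
#'   phase, family_history, age, sex), `profiles` (sample-by-feature
#'   ground-truth abundance data frame), the `template`, `effects`, and
#'   `seed`.
#' @export
generate_cohort <- function(n_case = 20L, n_control = 20L,
                            effects = migraine_effects(),
                            template = template_profile(), seed = 7L,
                            n_aura = 5L, n_ictal = 7L, n_famhist = 11L) {
  feat <- paste(template$subclass, template$glycoform)
  for (nm in names(c(effects$case, effects$aura, effects$family_history)))
    if (!nm %in% feat)
      glyco_stop(sprintf("effect target '%s' is not in the vocabulary", nm),
                 "glycomig_parameter_error")
  n <- n_case + n_control
  with_seed(seed, {
    manifest <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = rep(c("case", "control"), c(n_case, n_control)),
      aura = FALSE, phase = "none", family_history = FALSE,
      age = round(rnorm(n, mean = 40, sd = 11), 1),
      sex = NA_character_, stringsAsFactors = FALSE)
    manifest$aura[sample(seq_len(n_case), min(n_aura, n_case))] <- TRUE
    manifest$phase[seq_len(n_case)] <- "interictal"
    manifest$phase[sample(seq_len(n_case), min(n_ictal, n_case))] <- "ictal"
    manifest$family_history[sample(seq_len(n_case), min(n_famhist, n_case))] <- TRUE
    nm_case <- round(7 / 20 * n_case)
    nm_ctrl <- round(9 / 20 * n_control)
    manifest$sex[seq_len(n_case)] <-
      sample(c(rep("M", nm_case), rep("F", n_case - nm_case)))
    manifest$sex[n_case + seq_len(n_control)] <-
      sample(c(rep("M", nm_ctrl), rep("F", n_control - nm_ctrl)))
    log_tpl <- log(template$abundance)
    profiles <- matrix(NA_real_, n, length(feat),
                       dimnames = list(manifest$sample_id, feat))
    for (i in seq_len(n)) {
      lg <- log_tpl + rnorm(length(feat), 0, effects$log_sd)
      if (manifest$group[i] == "case") {
        lg <- add_log_folds(lg, feat, effects$case)
        if (manifest$aura[i]) lg <- add_log_folds(lg, feat, effects$aura)
        if (manifest$family_history[i])
          lg <- add_log_folds(lg, feat, effects$family_history)
      }
      p <- exp(lg)
      profiles[i, ] <- p / sum(p)
    }
  })
  structure(list(manifest = manifest,
                 profiles = as.data.frame(profiles, check.names = FALSE),
                 template = template, effects = effects, seed = seed),
            class = "synthetic_cohort")
}

add_log_folds <- function(lg, feat, folds) {
  if (length(folds)) {
    idx <- match(names(folds), feat)
    lg[idx] <- lg[idx] + log(folds)
  }
  lg
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d case + %d control, %d glycopeptides (seed %d)\n",
              sum(x$manifest$group == "case"),
              sum(x$manifest$group == "control"),
              ncol(x$profiles), x$seed))
  invisible(x)
}

#' Instrument model for spectrum synthesis
#'
#' @param fwhm Peak full width at half maximum in Da (default 2.5,
#'   linear-mode TOF resolution near m/z 2600).
#' @param grid_step m/z grid spacing in Da (default 0.1).
#' @param mz_range Acquisition window (default 2300-3600, bracketing the
#'   glycopeptide region).
#' @param baseline_amp,baseline_tau Decaying-exponential baseline:
#'   amplitude in mV at the window start and decay length in Da.
#' @param noise_sd White-noise SD in mV (default 0.002).
#' @param mass_slope,mass_offset Affine mass error applied to theoretical
#'   positions (observed = slope * true + offset).
#' @param total_signal Sum of apex heights in mV (default 50, which keeps
#'   minor glycoforms above the 0.050 mV picking threshold).
#' @param replicate_cv_pct Per-peak multiplicative replicate jitter CV.
#' @return Named list of instrument parameters.
#' @export
instrument_params <- function(fwhm = 2.5, grid_step = 0.1,
                              mz_range = c(2300, 3600),
                              baseline_amp = 0.2, baseline_tau = 500,
                              noise_sd = 0.002,
                              mass_slope = 1.0003, mass_offset = -0.4,
                              total_signal = 50, replicate_cv_pct = 0) {
  if (grid_step >= fwhm)
    glyco_stop("grid_step must be smaller than the peak FWHM",
               "glycomig_parameter_error")
  list(fwhm = fwhm, grid_step = grid_step, mz_range = mz_range,
       baseline_amp = baseline_amp, baseline_tau = baseline_tau,
       noise_sd = noise_sd, mass_slope = mass_slope,
       mass_offset = mass_offset, total_signal = total_signal,
       replicate_cv_pct = replicate_cv_pct)
}

#' Synthesize a linear-mode MALDI spectrum from a profile
#'
#' Sum of Gaussian peaks centred at the (affinely distorted) theoretical
#' m/z of the profile's glycopeptides, apex heights proportional to
#' abundances (total `total_signal` mV, per-peak multiplicative jitter of
#' `replicate_cv_pct`), plus a decaying-exponential baseline and white
#' noise.
#'
#' @param profile A `glyco_profile` on the simplex.
#' @param library A `glyco_library` supplying theoretical m/z.
#' @param instrument [instrument_params()].
#' @param seed Seed for noise and jitter.
#' @param sample_id,replicate_index Metadata for the returned spectrum.
#' @return A `spectrum`.
#' @export
synthesize_spectrum <- function(profile, library = build_library(),
                                instrument = instrument_params(),
                                seed = 1L, sample_id = NA_character_,
                                replicate_index = NA_integer_) {
  mz_theo <- library_mz(library, profile$subclass, profile$glycoform)
  centers <- instrument$mass_slope * mz_theo + instrument$mass_offset
  x <- seq(instrument$mz_range[1], instrument$mz_range[2],
           by = instrument$grid_step)
  sigma <- instrument$fwhm / (2 * sqrt(2 * log(2)))
  with_seed(seed, {
    jitter <- if (instrument$replicate_cv_pct > 0) {
      sdlog <- sqrt(log(1 + (instrument$replicate_cv_pct / 100)^2))
      exp(rnorm(length(centers), -sdlog^2 / 2, sdlog))
    } else rep(1, length(centers))
    heights <- instrument$total_signal * profile$abundance * jitter
    y <- numeric(length(x))
    for (j in seq_along(centers)) {
      if (heights[j] <= 0) next
      lo <- findInterval(centers[j] - 6 * sigma, x) + 1L
      hi <- findInterval(centers[j] + 6 * sigma, x)
      if (lo > hi) next
      idx <- lo:hi
      y[idx] <- y[idx] + heights[j] * exp(-(x[idx] - centers[j])^2 / (2 * sigma^2))
    }
    y <- y + instrument$baseline_amp *
      exp(-(x - instrument$mz_range[1]) / instrument$baseline_tau)
    if (instrument$noise_sd > 0)
      y <- y + rnorm(length(x), 0, instrument$noise_sd)
  })
  new_spectrum(x, y, sample_id, replicate_index)
}

#' Generate replicate QC spectra of one profile
#'
#' Replicate spectra of the same profile with per-peak multiplicative
#' jitter of the given CV, emulating repeated spotting of a standard IVIG
#' digest for repeatability assessment.
#'
#' @param profile A `glyco_profile`.
#' @param n Number of replicates (default 3).
#' @param cv_pct Per-peak replicate CV in percent (default 5).
#' @param seed Seed.
#' @param library,instrument As in [synthesize_spectrum()].
#' @return List of `n` `spectrum` objects.
#' @export
generate_qc_replicates <- function(profile, n = 3L, cv_pct = 5, seed = 1L,
                                   library = build_library(),
                                   instrument = instrument_params()) {
  if (n < 2L)
    glyco_stop("QC needs at least 2 replicates", "glycomig_parameter_error")
  if (cv_pct < 0)
    glyco_stop("cv_pct must be >= 0", "glycomig_parameter_error")
  inst <- modifyList(instrument, list(replicate_cv_pct = cv_pct))
  lapply(seq_len(n), function(r)
    synthesize_spectrum(profile, library, inst, seed = child_seed(seed, r),
                        sample_id = "QC", replicate_index = r))
}

#' Write a cohort's spectra, manifest and ground truth to a directory
#'
#' Spectra are written as two-column text (`<sample>_rep<k>.txt`), the
#' manifest as `cohort.csv` with replicate path columns, and the ground-
#' truth profiles as `ground_truth.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param n_replicates Technical replicates per subject (default 4).
#' @param library,instrument As in [synthesize_spectrum()].
#' @return The manifest data frame (with `rep1..repK` path columns),
#'   invisibly.
#' @export
write_cohort <- function(cohort, dir, n_replicates = 4L,
                         library = build_library(),
                         instrument = instrument_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  inst <- modifyList(instrument, list(
    replicate_cv_pct = cohort$effects$replicate_cv_pct))
  feat <- colnames(cohort$profiles)
  parts <- strsplit(feat, " ", fixed = TRUE)
  subclass <- vapply(parts, `[[`, character(1), 1L)
  glycoform <- vapply(parts, function(p) paste(p[-1], collapse = " "), character(1))
  for (r in seq_len(n_replicates))
    manifest[[paste0("rep", r)]] <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    prof <- new_glyco_profile(subclass, glycoform,
                              as.numeric(cohort$profiles[i, ]),
                              sample_id = manifest$sample_id[i])
    for (r in seq_len(n_replicates)) {
      sp <- synthesize_spectrum(
        prof, library, inst,
        seed = child_seed(cohort$seed, i * 101L + r),
        sample_id = manifest$sample_id[i], replicate_index = r)
      fn <- file.path(dir, sprintf("%s_rep%d.txt", manifest$sample_id[i], r))
      writeLines(c(sprintf("# synthetic spectrum %s replicate %d",
                           manifest$sample_id[i], r),
                   sprintf("%.4f %.6f", sp$mz, sp$intensity)), fn)
      manifest[[paste0("rep", r)]][i] <- fn
    }
  }
  write.csv(manifest, file.path(dir, "cohort.csv"), row.names = FALSE)
  gt <- cbind(sample_id = manifest$sample_id, cohort$profiles)
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(manifest)
}
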