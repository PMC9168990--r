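# Orchestration: resolved configuration, the end-to-end pipeline, and
# config file I/O.

#' Pipeline configuration
#'
#' Defaults follow the reference acquisition and extraction settings
#' where stated: picking threshold 0.050 mV, export window 2450-3500 Da,
#' 4 technical replicates, 7 selected features, 5 CV folds.  For
#' synthetic cohorts use [synth_config()], which widens the window floor
#' to 2400 Da so that IgG1 G0-NF (theoretical m/z ~2431) is retained.
#'
#' @param threshold_mv Peak-picking threshold, mV.
#' @param window Export window `c(lo, hi)` in Da.
#' @param tophat_width Top-hat structuring-element width, Da.
#' @param cal_tol Calibrant match tolerance, Da.
#' @param assign_tol Peak-to-library assignment tolerance, Da.
#' @param overlap_tol IgG3/4 overlap flagging tolerance, Da.
#' @param rsd_threshold Replicate RSD QC threshold, percent.
#' @param n_replicates Expected technical replicates per sample.
#' @param k_features Features selected for the classifier.
#' @param n_folds Cross-validation folds.
#' @param seed Master seed for fold assignment and training inits.
#' @param paper_mode If TRUE, fit scaling and feature selection on the
#'   full dataset before splitting (leaky reference protocol).
#' @param hyper Network hyperparameters ([ffnn_hyper()]).
#' @param glycoforms,subclasses Library vocabulary.
#' @param include Optional character vector of feature ids
#'   (`"IgG1 G0F"`) restricting the library to a detected subset.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold_mv = 0.050, window = c(2450, 3500),
                            tophat_width = 20, cal_tol = 1.5,
                            assign_tol = 1.0, overlap_tol = 1.0,
                            rsd_threshold = 15, n_replicates = 4L,
                            k_features = 7L, n_folds = 5L, seed = 7L,
                            paper_mode = FALSE, hyper = ffnn_hyper(),
                            glycoforms = default_glycoforms(),
                            subclasses = c("IgG1", "IgG2", "IgG3/4"),
                            include = NULL) {
  cfg <- list(threshold_mv = threshold_mv, window = window,
              tophat_width = tophat_width, cal_tol = cal_tol,
              assign_tol = assign_tol, overlap_tol = overlap_tol,
              rsd_threshold = rsd_threshold,
              n_replicates = as.integer(n_replicates),
              k_features = as.integer(k_features),
              n_folds = as.integer(n_folds), seed = as.integer(seed),
              paper_mode = paper_mode, hyper = hyper,
              glycoforms = glycoforms, subclasses = subclasses,
              include = include)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param ... Overrides passed to [pipeline_config()].
#' @export
synth_config <- function(...) {
  pipeline_config(window = c(2400, 3500), ...)
}

config_library <- function(config) {
  lib <- build_library(config$glycoforms, config$subclasses,
                       config$overlap_tol)
  if (!is.null(config$include)) {
    keep <- paste(lib$subclass, lib$glycoform) %in% config$include
    lib <- lib[keep | lib$overlapped, , drop = FALSE]
    class(lib) <- c("glyco_library", "data.frame")
  }
  lib
}

# Stable short hash of the resolved configuration (FNV-1a over the
# deparsed config), stamped into every output file.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 31 bits keeps everything inside integer range
    h <- (bitwXor(as.integer(h %% 2147483648), b) +
            (h >= 2147483648) * 2147483648)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Read a pipeline config file
#'
#' Accepts JSON (via jsonlite) or a flat `key: value` YAML subset
#' (scalars and `[a, b]` inline lists; `#` comments).  Keys must be
#' [pipeline_config()] arguments.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vals <- if (grepl("\\.json$", path) || any(grepl("^\\s*\\{", txt))) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- sub("#.*$", "", txt)
    lines <- trimws(lines[grepl(":", lines)])
    out <- list()
    for (ln in lines) {
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (!nzchar(val)) next
      if (grepl("^\\[.*\\]$", val)) {
        val <- trimws(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]])
      }
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!anyNA(num)) num
                    else if (all(val %in% c("true", "false", "TRUE", "FALSE")))
                      as.logical(toupper(val))
                    else val
    }
    out
  }
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Run the full analysis pipeline
#'
#' Reads every sample's replicate spectra from the manifest, processes
#' them (top-hat baseline, picking, internal calibration, windowing,
#' assignment, normalization, replicate averaging, RSD QC), computes
#' derived traits, case/control statistics over glycopeptides and
#' traits, cross-validates the classifier and fits the final model.
#' All outputs are written to `out_dir` and stamped with a hash of the
#' resolved configuration; runs are deterministic given the config seed.
#'
#' @param manifest Data frame (or CSV path) with columns `sample_id`,
#'   `group`, optional `aura`/`phase`/`family_history`, and replicate
#'   spectrum paths in columns `rep1`, `rep2`, ... .  Samples keep a
#'   warning (not an error) while at least one replicate file is
#'   readable.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisible list with `profiles`, `traits`, `stats`, `cv`,
#'   `model`, `rsd`, and the output paths.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = tempfile("glycomig_run_")) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  hash <- config_hash(config)
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  }
  logf("config hash %s", hash)
  logf("resolved config: %s", paste(deparse(config), collapse = " "))
  lib <- config_library(config)
  rep_cols <- grep("^rep[0-9]+$", names(manifest), value = TRUE)
  if (length(rep_cols) == 0L)
    glyco_stop("manifest has no replicate path columns (rep1, rep2, ...)",
               "glycomig_format_error")
  profiles <- list(); rsd_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    paths <- unlist(manifest[i, rep_cols], use.names = FALSE)
    paths <- paths[!is.na(paths) & nzchar(paths)]
    spectra <- list()
    for (p in paths) {
      sp <- tryCatch(read_spectrum(p, sample_id = sid),
                     glycomig_format_error = function(e) {
                       logf("WARNING %s: unreadable replicate %s (%s)",
                            sid, p, conditionMessage(e))
                       warning(sprintf("%s: skipping unreadable replicate %s",
                                       sid, p))
                       NULL
                     })
      if (!is.null(sp)) spectra[[length(spectra) + 1L]] <- sp
    }
    if (length(spectra) == 0L)
      glyco_stop(sprintf("sample %s has no readable replicate spectra", sid),
                 "glycomig_format_error")
    if (length(spectra) < config$n_replicates)
      logf("WARNING %s: only %d of %d replicates", sid, length(spectra),
           config$n_replicates)
    est <- suppressWarnings(
      estimate_profile(spectra, lib, config, sample_id = sid))
    profiles[[sid]] <- est$profile
    if (!is.null(est$rsd))
      rsd_rows[[sid]] <- data.frame(sample_id = sid,
                                    t(setNames(est$rsd$rsd_pct,
                                               sprintf("mz_%.1f", est$rsd$target_mz))),
                                    pass = attr(est$rsd, "pass"),
                                    check.names = FALSE)
    logf("%s: %d replicates, QC %s", sid, length(spectra),
         if (is.null(est$rsd)) "n/a" else if (attr(est$rsd, "pass")) "pass" else "FAIL")
  }
  feat_ids <- paste(profiles[[1]]$subclass, profiles[[1]]$glycoform)
  features <- as.data.frame(
    do.call(rbind, lapply(profiles, function(p) p$abundance)),
    check.names = FALSE)
  colnames(features) <- feat_ids
  rownames(features) <- names(profiles)
  traits <- trait_table(features)
  full_tab <- features
  full_tab[names(traits)] <- traits
  stats <- compare_all(full_tab, manifest, grouping = "group")
  y <- as.integer(manifest$group == "case")
  cv <- cross_validate(features, y, n_folds = config$n_folds,
                       seed = config$seed, k = config$k_features,
                       hyper = config$hyper, paper_mode = config$paper_mode)
  model <- fit_final(features, y, k = config$k_features,
                     hyper = modifyList(config$hyper,
                                        list(seed = config$seed)))
  logf("cv mean AUC %.3f (folds %s)", cv$mean_auc,
       paste(sprintf("%.3f", cv$fold_aucs), collapse = ", "))
  stamp <- function(df) { df$config_hash <- hash; df }
  prof_out <- stamp(cbind(sample_id = rownames(features),
                          n_replicates = vapply(profiles, attr, 1L, "n_replicates"),
                          features))
  write.csv(prof_out, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  write.csv(stamp(cbind(sample_id = rownames(traits), traits)),
            file.path(out_dir, "traits.csv"), row.names = FALSE)
  write.csv(stamp(stats), file.path(out_dir, "stats.csv"), row.names = FALSE)
  if (length(rsd_rows))
    write.csv(stamp(do.call(rbind, rsd_rows)),
              file.path(out_dir, "rsd_report.csv"), row.names = FALSE)
  cv_out <- list(config_hash = hash, seed = cv$seed,
                 fold_aucs = cv$fold_aucs, mean_auc = cv$mean_auc,
                 paper_mode = cv$paper_mode,
                 features = lapply(cv$folds, `[[`, "features"))
  jsonlite::write_json(cv_out, file.path(out_dir, "cv_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_model(model, file.path(out_dir, "model.json"))
  roc_list <- lapply(seq_along(cv$folds), function(f) {
    r <- cv$folds[[f]]$roc
    if (is.null(r)) return(NULL)
    cbind(fold = f, r)
  })
  write.csv(do.call(rbind, roc_list), file.path(out_dir, "roc_points.csv"),
            row.names = FALSE)
  invisible(list(profiles = features, traits = traits, stats = stats,
                 cv = cv, model = model,
                 rsd = if (length(rsd_rows)) do.call(rbind, rsd_rows) else NULL,
                 out_dir = out_dir, config_hash = hash))
}
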