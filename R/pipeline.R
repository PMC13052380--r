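#' Study configuration
#'
#' Bundles every setting of an end-to-end study run: the generator
#' configuration, signal-processing settings, and model-suite settings.
#' Can be created programmatically or loaded from YAML.
#'
#' @param generator a \code{\link{generator_config}}.
#' @param cutoff low-pass filter cutoff in Hz.
#' @param stab_window stabilization trailing window in s.
#' @param B bootstrap resamples for the model suite.
#' @param seed master integer seed for the whole run.
#' @return list of class \code{study_config}.
#' @export
study_config <- function(generator = generator_config(), cutoff = 7.5,
                         stab_window = 0.2, B = 500, seed = 1) {
  stopifnot(inherits(generator, "generator_config"))
  if (cutoff <= 0 || cutoff >= generator$sampling_rate / 2)
    stop_invalid("cutoff must lie in (0, Nyquist)")
  if (B < 1) stop_invalid("B must be >= 1")
  structure(list(generator = generator, cutoff = cutoff,
                 stab_window = stab_window, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Load a study configuration from YAML
#'
#' Top-level keys map to \code{\link{study_config}} arguments; keys under
#' \code{generator} map to \code{\link{generator_config}} arguments.
#'
#' @param path YAML file path.
#' @return a \code{study_config}.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator %||% list()
  gen <- do.call(generator_config, gen_args)
  args <- raw[setdiff(names(raw), "generator")]
  do.call(study_config, c(list(generator = gen), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic study pipeline
#'
#' Executes generate -> extract -> classify -> validate: draws a calibrated
#' synthetic cohort, simulates two sit-to-stand trials per subject, extracts
#' features from each raw trace through the full measurement chain, averages
#' the trial pair, computes trial-pair ICC(2,1) for peak force, T1 and T2,
#' applies the sarcopenia and frailty criteria, summarizes the frailty
#' phenotype components, and internally validates the five benchmark models
#' for both outcomes. Identical configuration and seed reproduce the bundle
#' exactly.
#'
#' @param config a \code{\link{study_config}}.
#' @param out_dir optional output directory; when given, the cohort table,
#'   feature table, ICC report, component summary, performance tables and a
#'   run manifest are written there.
#' @param verbose print progress messages.
#' @return invisibly, a list with \code{cohort} (with measured features and
#'   labels), \code{features} (per-trial rows), \code{icc} (per measure),
#'   \code{components}, \code{performance} (per outcome), \code{excluded},
#'   and \code{manifest}.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  gen <- config$generator
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating cohort (n = %d)", gen$n_subjects)
  cohort <- generate_cohort(gen, seed = seed)
  n <- nrow(cohort)
  say("simulating and measuring %d trial pairs", n)
  trial_rows <- vector("list", 2L * n)
  meas <- data.frame(peak_force = rep(NA_real_, n), T1 = NA_real_,
                     T2 = NA_real_, valid = FALSE, degraded = FALSE)
  trial_mat <- list(peak_force = matrix(NA_real_, n, 2),
                    T1 = matrix(NA_real_, n, 2), T2 = matrix(NA_real_, n, 2))
  for (i in seq_len(n)) {
    pair <- generate_trial_pair(cohort[i, ], gen, seed = child_seed(seed, 100 + i))
    feats <- lapply(pair, function(p)
      extract_sts_features(p$trace, cohort$weight[i], cutoff = config$cutoff,
                           stab_window = config$stab_window))
    for (k in 1:2) {
      f <- feats[[k]]
      trial_rows[[2 * (i - 1) + k]] <- data.frame(
        id = cohort$id[i], trial = k,
        onset_index = f$onset_index, peak_index = f$peak_index,
        stabilization_index = f$stabilization_index,
        T1 = f$T1, T2 = f$T2, peak_accel = f$peak_accel,
        peak_force = f$peak_force, valid = f$valid,
        reason = if (f$valid) "" else f$reason)
      if (f$valid) {
        trial_mat$peak_force[i, k] <- f$peak_force
        trial_mat$T1[i, k] <- f$T1
        trial_mat$T2[i, k] <- f$T2
      }
    }
    avg <- average_trials(feats[[1]], feats[[2]])
    meas$peak_force[i] <- avg$peak_force
    meas$T1[i] <- avg$T1
    meas$T2[i] <- avg$T2
    meas$valid[i] <- avg$valid
    meas$degraded[i] <- avg$degraded
  }
  features <- do.call(rbind, trial_rows)
  excluded <- cohort$id[!meas$valid]
  if (length(excluded) > 0)
    say("excluding %d participant(s) without a valid trial", length(excluded))
  cohort$peak_force <- meas$peak_force
  cohort$T1 <- meas$T1
  cohort$T2 <- meas$T2
  analysis <- cohort[meas$valid, , drop = FALSE]
  say("reliability (trial-pair ICC)")
  icc <- lapply(trial_mat, function(m) {
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 3) icc_2_1(m) else NULL
  })
  say("classification")
  analysis$sarcopenia <- classify_sarcopenia(analysis)
  fr <- classify_frailty(analysis)
  analysis$frail <- fr$frail
  labeled <- cbind(analysis, fr[c("weakness", "slowness", "n_components")])
  components <- frailty_component_summary(labeled)
  say("model suites (B = %d)", config$B)
  perf <- list(
    sarcopenia = run_model_suite(analysis, "sarcopenia", B = config$B,
                                 seed = child_seed(seed, 7)),
    frailty = run_model_suite(analysis, "frailty", B = config$B,
                              seed = child_seed(seed, 8)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("stspower")),
    seed = seed, B = config$B, cutoff = config$cutoff,
    stab_window = config$stab_window,
    n_subjects = n, n_analyzed = nrow(analysis),
    n_excluded = length(excluded), excluded = as.list(excluded),
    draw_rates = attr(cohort, "draw_rates"),
    prevalence = list(
      sarcopenia_pct = percent_of(sum(analysis$sarcopenia), nrow(analysis)),
      frailty_pct = percent_of(sum(analysis$frail), nrow(analysis))),
    icc = lapply(icc, function(r) if (is.null(r)) NULL else r$icc))
  bundle <- list(cohort = labeled, features = features, icc = icc,
                 components = components, performance = perf,
                 excluded = excluded, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort(bundle$cohort, p("cohort.csv"))
  utils::write.csv(bundle$features, p("features.csv"), row.names = FALSE)
  utils::write.csv(bundle$components, p("frailty_components.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(bundle$icc, function(r)
    if (is.null(r)) NULL else unclass(r)), p("icc.json"),
    auto_unbox = TRUE, digits = NA)
  write_performance_table(bundle$performance$sarcopenia,
                          p("performance_sarcopenia"))
  write_performance_table(bundle$performance$frailty,
                          p("performance_frailty"))
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

cohort_required_cols <- c("id", "age", "sex", "height", "weight", "grip",
                          "walking_speed", "asm", "smi", "weight_loss",
                          "exhaustion", "low_activity")

#' Write / read a cohort table
#'
#' CSV round-trip for the participant table with schema validation:
#' required columns, sex levels, and unit-plausibility checks (e.g. walking
#' speed below 5 m/s) reported with row numbers.
#'
#' @param cohort data frame with at least the participant-record columns.
#' @param file CSV path.
#' @return \code{write_cohort} returns \code{file} invisibly;
#'   \code{read_cohort} returns the validated data frame.
#' @export
write_cohort <- function(cohort, file) {
  miss <- setdiff(cohort_required_cols, names(cohort))
  if (length(miss) > 0)
    stop_invalid("cohort is missing column(s): %s", paste(miss, collapse = ", "))
  utils::write.csv(cohort, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_required_cols, names(df))
  if (length(miss) > 0)
    stop_invalid("cohort file %s is missing column(s): %s", file,
                 paste(miss, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0)
      stop_invalid("cohort file %s: %s at row(s) %s", file, what,
                   paste(utils::head(i, 5), collapse = ", "))
  }
  bad_row(!df$sex %in% c("male", "female"), "sex must be 'male' or 'female'")
  for (col in c("age", "height", "weight", "grip", "walking_speed", "asm",
                "smi")) {
    bad_row(!is.finite(df[[col]]), sprintf("non-numeric '%s'", col))
    bad_row(df[[col]] < 0, sprintf("negative '%s'", col))
  }
  bad_row(df$walking_speed > 5, "implausible walking speed (> 5 m/s)")
  bad_row(df$height > 0 & abs(compute_smi(df$asm, df$height) - df$smi) > 0.05,
          "smi inconsistent with asm/height^2")
  for (col in c("weight_loss", "exhaustion", "low_activity"))
    df[[col]] <- as.logical(df[[col]])
  df
}
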