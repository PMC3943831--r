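#' Pipeline configuration
#'
#' Collects the tunable settings of the analysis chain with their valid
#' ranges. A config serialises losslessly to JSON ([write_config()] /
#' [read_config()]).
#'
#' @param cutoff Low-pass cutoff, Hz.
#' @param order Butterworth design order per pass.
#' @param lowpass Apply the zero-lag filter.
#' @param n_points Stance-normalised length (NA = keep native grid).
#' @param threshold_fraction Stance-detection GRF threshold (fraction of body
#'   weight).
#' @param cp_window Early-stance fraction searched for the CP trough.
#' @param pp_window Search half-window (fraction of stance) around the angle
#'   maximum for the power crossing.
#' @param persistence Consecutive positive-power samples required at the PP
#'   onset.
#' @param cd_rule CD/PP boundary rule: `"power"` or `"angle"`.
#' @param normality_method `"ks"` or `"lilliefors"`.
#' @param gg_correction Greenhouse-Geisser correction in [rm_anova()].
#' @param seed Master seed used by simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cutoff = 10, order = 6, lowpass = TRUE,
                            n_points = 101, threshold_fraction = 0.03,
                            cp_window = 0.35, pp_window = 0.10,
                            persistence = 3L, cd_rule = "power",
                            normality_method = "ks", gg_correction = FALSE,
                            seed = 1L) {
  cfg <- list(cutoff = as.numeric(cutoff), order = as.integer(order),
              lowpass = isTRUE(lowpass),
              n_points = if (is.na(n_points)) NA_integer_ else as.integer(n_points),
              threshold_fraction = as.numeric(threshold_fraction),
              cp_window = as.numeric(cp_window), pp_window = as.numeric(pp_window),
              persistence = as.integer(persistence), cd_rule = cd_rule,
              normality_method = normality_method,
              gg_correction = isTRUE(gg_correction), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid config: ", msg,
                                                     call. = FALSE)
  chk(cfg$cutoff > 0, "'cutoff' must be positive")
  chk(cfg$order >= 1, "'order' must be >= 1")
  chk(is.na(cfg$n_points) || cfg$n_points >= 5, "'n_points' must be >= 5 or NA")
  chk(cfg$threshold_fraction > 0 && cfg$threshold_fraction < 1,
      "'threshold_fraction' must be in (0, 1)")
  chk(cfg$cp_window > 0 && cfg$cp_window <= 0.5, "'cp_window' must be in (0, 0.5]")
  chk(cfg$pp_window > 0 && cfg$pp_window <= 0.5, "'pp_window' must be in (0, 0.5]")
  chk(cfg$persistence >= 1, "'persistence' must be >= 1")
  chk(cfg$cd_rule %in% c("power", "angle"), "'cd_rule' must be 'power' or 'angle'")
  chk(cfg$normality_method %in% c("ks", "lilliefors"),
      "'normality_method' must be 'ks' or 'lilliefors'")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$n_points <- if (is.null(x$n_points)) NA_integer_ else x$n_points
  do.call(pipeline_config, x)
}

#' Simulate a cohort to disk
#'
#' Generates a cohort with [generate_cohort()] and writes one trial CSV plus a
#' ground-truth JSON sidecar per trial, and a `manifest.json` listing the
#' files, the seed and the cohort layout.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_subjects,presets,trials_per_cell,seed See [generate_cohort()].
#' @param ... Further arguments to [generate_cohort()].
#' @return The manifest (list), invisibly.
#' @export
run_simulate <- function(out_dir, n_subjects = 20, presets = speed_presets(),
                         trials_per_cell = 1, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_subjects, presets, trials_per_cell, seed, ...)
  files <- character(0)
  for (stem in cohort$index$stem) {
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    write_trial(cohort$trials[[stem]], csv)
    write_ground_truth(cohort$truths[[stem]],
                       file.path(out_dir, paste0(stem, ".truth.json")))
    files <- c(files, basename(csv))
  }
  manifest <- list(seed = seed, n_subjects = n_subjects,
                   trials_per_cell = trials_per_cell,
                   speeds = names(presets), files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("simulate: wrote %d trials to %s (seed %s)",
                  length(files), out_dir, format(seed)))
  invisible(manifest)
}

#' Analyse a directory of trial files
#'
#' Reads every trial CSV in `in_dir` (from the manifest when present,
#' otherwise all `*.csv` except exports), runs preprocessing, segmentation and
#' the loop mechanics, and collects one metrics row per trial. Per-trial
#' failures (e.g. no PP onset) are logged and skipped; the run continues.
#' When ground-truth sidecars are present a recovery report comparing
#' estimated to generating values is produced.
#'
#' @param in_dir Directory of trial CSVs.
#' @param out_dir Optional output directory for `metrics.csv`,
#'   `failures.csv`, `segmentations.json` and `recovery.csv`.
#' @param config A [pipeline_config()].
#' @return List with `metrics` (data.frame), `failures` (data.frame),
#'   `recovery` (data.frame or NULL), invisibly.
#' @export
run_analyze <- function(in_dir, out_dir = NULL, config = pipeline_config()) {
  validate_config(config)
  manifest_path <- file.path(in_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    files <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)$files
  } else {
    files <- basename(Sys.glob(file.path(in_dir, "*.csv")))
    files <- files[!files %in% c("metrics.csv", "failures.csv", "recovery.csv")]
  }
  if (length(files) == 0) stop("no trial files found in ", in_dir)

  rows <- list(); fails <- list(); recov <- list(); seg_out <- list()
  for (f in files) {
    path <- file.path(in_dir, f)
    res <- tryCatch({
      trial <- read_trial(path)
      pt <- process_trial(trial, n_points = config$n_points,
                          lowpass = config$lowpass, cutoff = config$cutoff,
                          order = config$order,
                          threshold_fraction = config$threshold_fraction)
      seg <- segment_phases(pt, cp_window = config$cp_window,
                            pp_window = config$pp_window,
                            persistence = config$persistence,
                            cd_rule = config$cd_rule)
      analyze_trial(pt, seg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("analyze: %s FAILED: %s", f, conditionMessage(res)))
      fails[[f]] <- data.frame(file = f, reason = conditionMessage(res),
                               stringsAsFactors = FALSE)
      next
    }
    message(sprintf("analyze: %s ok (K_CD %.3f, W_total %.3f)",
                    f, res$fits$cd$k, res$work$w_total))
    row <- metrics_row(res)
    row$file <- f
    rows[[f]] <- row
    seg_out[[f]] <- list(cp_end = res$segmentation$cp_end,
                         cd_end = res$segmentation$cd_end,
                         toe_off = res$segmentation$toe_off,
                         diagnostics = res$segmentation$diagnostics)
    truth_path <- file.path(in_dir, sub("\\.csv$", ".truth.json", f))
    if (file.exists(truth_path)) {
      tr <- read_ground_truth(truth_path)
      recov[[f]] <- data.frame(
        file = f,
        k_cd_true = tr$k_cd, k_cd_est = row$k_cd,
        k_cd_rel_err = (row$k_cd - tr$k_cd) / tr$k_cd,
        k_pp_true = tr$k_pp, k_pp_est = row$k_pp,
        k_pp_rel_err = (row$k_pp - tr$k_pp) / tr$k_pp,
        w_total_true = tr$w_total_true, w_total_est = row$w_total,
        expected_sign = tr$expected_w_total_sign,
        sign_match = sign_tol(row$w_total, 1e-6) == tr$expected_w_total_sign,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- if (length(rows)) do.call(rbind, unname(rows)) else NULL
  failures <- if (length(fails)) do.call(rbind, unname(fails)) else
    data.frame(file = character(), reason = character())
  recovery <- if (length(recov)) do.call(rbind, unname(recov)) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(metrics)) {
      utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(failures, file.path(out_dir, "failures.csv"),
                     row.names = FALSE)
    jsonlite::write_json(seg_out, file.path(out_dir, "segmentations.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(recovery)) {
      utils::write.csv(recovery, file.path(out_dir, "recovery.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(metrics = metrics, failures = failures, recovery = recovery))
}

#' Summarise cohort metrics
#'
#' Builds the cohort table, runs the repeated-measures ANOVA with
#' Bonferroni-adjusted pairwise contrasts for each metric over the speed
#' conditions, and the normality checks per metric and speed. With fewer than
#' two speed conditions the tables are still produced and the ANOVA is skipped
#' with a message.
#'
#' @param metrics Per-trial metrics data.frame (from [run_analyze()]).
#' @param out_dir Optional output directory for `cohort_table.csv/.json`,
#'   `anova.csv`, `pairwise.csv`, `normality.csv` and a rendered
#'   `cohort_table.txt`.
#' @param config A [pipeline_config()].
#' @param values Metric columns to summarise (default: the standard set).
#' @return List with `cohort` (a `cohort_table`), `anova` (named list of
#'   `rm_anova` or NULL), `normality` (data.frame), invisibly.
#' @export
run_summarize <- function(metrics, out_dir = NULL, config = pipeline_config(),
                          values = c("k_cp", "k_cd", "k_pp",
                                     "r2_cp", "r2_cd", "r2_pp",
                                     "abs_w_cp", "abs_w_cd", "abs_w_pp",
                                     "w_total", "peak_power",
                                     "mean_stance_power")) {
  validate_config(config)
  ct <- aggregate_cohort(metrics, values = values)
  anovas <- NULL
  pairwise <- NULL
  if (length(ct$speeds) >= 2 && ct$n_subjects >= 2) {
    anovas <- lapply(dimnames(ct$subject_means)[[3]], function(v) {
      rm_anova(subject_speed_matrix(ct, v), metric = v,
               gg_correction = config$gg_correction)
    })
    names(anovas) <- dimnames(ct$subject_means)[[3]]
    pairwise <- do.call(rbind, lapply(anovas, function(a) {
      cbind(metric = a$metric, a$pairwise)
    }))
  } else {
    message("summarize: fewer than 2 speed conditions or subjects; ANOVA skipped")
  }
  norm_rows <- list()
  for (v in dimnames(ct$subject_means)[[3]]) {
    for (sp in ct$speeds) {
      x <- ct$subject_means[, sp, v]
      nr <- tryCatch(ks_normality(x, metric = v, method = config$normality_method),
                     error = function(e) NULL)
      if (!is.null(nr)) {
        norm_rows[[paste(v, sp)]] <- data.frame(metric = v, speed = sp,
                                                D = nr$D, p = nr$p,
                                                method = nr$method, n = nr$n,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  normality <- if (length(norm_rows)) do.call(rbind, unname(norm_rows)) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ct$table, file.path(out_dir, "cohort_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ct$table, file.path(out_dir, "cohort_table.json"),
                         dataframe = "rows", digits = NA)
    writeLines(utils::capture.output(print(ct)),
               file.path(out_dir, "cohort_table.txt"))
    if (!is.null(anovas)) {
      an_df <- do.call(rbind, lapply(anovas, function(a) {
        data.frame(metric = a$metric, F = a$F, df_effect = a$df_effect,
                   df_error = a$df_error, p = a$p, epsilon = a$epsilon,
                   stringsAsFactors = FALSE)
      }))
      utils::write.csv(an_df, file.path(out_dir, "anova.csv"), row.names = FALSE)
      utils::write.csv(pairwise, file.path(out_dir, "pairwise.csv"),
                       row.names = FALSE)
    }
    if (!is.null(normality)) {
      utils::write.csv(normality, file.path(out_dir, "normality.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(cohort = ct, anova = anovas, pairwise = pairwise,
                 normality = normality))
}

#' Run the full pipeline
#'
#' simulate -> analyze -> summarize with one master seed; deterministic given
#' the seed.
#'
#' @param out_dir Root output directory (`trials/`, `analysis/`, `summary/`).
#' @param n_subjects,presets,trials_per_cell See [run_simulate()].
#' @param config A [pipeline_config()]; its `seed` drives the simulation.
#' @return List with the manifest, analysis and summary results, invisibly.
#' @export
run_pipeline <- function(out_dir, n_subjects = 20, presets = speed_presets(),
                         trials_per_cell = 1, config = pipeline_config()) {
  trials_dir <- file.path(out_dir, "trials")
  manifest <- run_simulate(trials_dir, n_subjects, presets, trials_per_cell,
                           seed = config$seed)
  ana <- run_analyze(trials_dir, file.path(out_dir, "analysis"), config)
  if (is.null(ana$metrics)) stop("all trials failed analysis")
  summ <- run_summarize(ana$metrics, file.path(out_dir, "summary"), config)
  invisible(list(manifest = manifest, analysis = ana, summary = summ))
}
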