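#' Aggregate per-trial metrics into a cohort table
#'
#' Averages repeated trials within each subject x speed cell first, drops
#' subjects that are missing any speed condition (complete-case, with a
#' warning reporting the count), and tabulates mean, SD and n of the
#' subject-level values per speed for each metric: the "mean (SD) by speed"
#' layout of cohort summaries.
#'
#' @param metrics Data frame of per-trial metrics with columns `subject_id`,
#'   `speed_category` and the metric columns (see [metrics_row()]).
#' @param values Character vector of metric column names to tabulate.
#' @param speeds Order of the speed columns (default the four standard
#'   categories present in the data).
#' @return A `cohort_table`: list with `table` (long data.frame: metric,
#'   speed, mean, sd, n), `subject_means` (subject x speed x metric array
#'   input to [rm_anova()]), `speeds`, `n_subjects`, `n_dropped`.
#' @export
aggregate_cohort <- function(metrics,
                             values = c("k_cp", "k_cd", "k_pp",
                                        "r2_cp", "r2_cd", "r2_pp",
                                        "abs_w_cp", "abs_w_cd", "abs_w_pp",
                                        "w_total", "peak_power",
                                        "mean_stance_power"),
                             speeds = NULL) {
  stopifnot(all(c("subject_id", "speed_category") %in% names(metrics)))
  values <- intersect(values, names(metrics))
  if (length(values) == 0) stop("no requested metric columns found")
  if (is.null(speeds)) {
    speeds <- intersect(SPEED_LEVELS, unique(metrics$speed_category))
    if (length(speeds) == 0) speeds <- unique(metrics$speed_category)
  }
  metrics <- metrics[metrics$speed_category %in% speeds, , drop = FALSE]

  # within-subject trial means per cell
  cell <- stats::aggregate(metrics[values],
                           by = list(subject_id = metrics$subject_id,
                                     speed_category = metrics$speed_category),
                           FUN = mean)

  counts <- table(cell$subject_id)
  complete <- names(counts)[counts == length(speeds)]
  n_dropped <- length(counts) - length(complete)
  if (n_dropped > 0) {
    warning(n_dropped, " subject(s) missing at least one speed condition ",
            "were excluded (complete-case)")
  }
  cell <- cell[cell$subject_id %in% complete, , drop = FALSE]
  subjects <- sort(unique(cell$subject_id))
  n <- length(subjects)

  subject_means <- array(NA_real_, dim = c(n, length(speeds), length(values)),
                         dimnames = list(subjects, speeds, values))
  for (i in seq_len(nrow(cell))) {
    subject_means[cell$subject_id[i], cell$speed_category[i], ] <-
      as.numeric(cell[i, values])
  }

  tab <- do.call(rbind, lapply(values, function(v) {
    do.call(rbind, lapply(speeds, function(sp) {
      x <- subject_means[, sp, v]
      data.frame(metric = v, speed = sp, mean = mean(x),
                 sd = stats::sd(x), n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(table = tab, subject_means = subject_means,
                 speeds = speeds, n_subjects = n, n_dropped = n_dropped),
            class = "cohort_table")
}

#' Subject x speed matrix for one metric
#'
#' @param ct A `cohort_table`.
#' @param metric Metric column name.
#' @return Numeric matrix, rows = subjects, columns = speeds.
#' @export
subject_speed_matrix <- function(ct, metric) {
  if (!metric %in% dimnames(ct$subject_means)[[3]]) {
    stop("metric '", metric, "' not present in the cohort table")
  }
  ct$subject_means[, , metric, drop = TRUE]
}

#' Render a cohort table as "mean (SD)" text
#'
#' @param ct A `cohort_table`.
#' @param digits Decimal places.
#' @return Character matrix (metrics x speeds) of "mean (SD)" cells.
#' @export
render_cohort_table <- function(ct, digits = 2) {
  tab <- ct$table
  metrics <- unique(tab$metric)
  out <- matrix("", nrow = length(metrics), ncol = length(ct$speeds),
                dimnames = list(metrics, ct$speeds))
  for (i in seq_len(nrow(tab))) {
    out[tab$metric[i], tab$speed[i]] <-
      sprintf("%.*f (SD %.*f)", digits, tab$mean[i], digits, tab$sd[i])
  }
  out
}

#' @export
print.cohort_table <- function(x, digits = 2, ...) {
  cat(sprintf("<cohort_table> %d subjects x %d speeds (%d dropped)\n",
              x$n_subjects, length(x$speeds), x$n_dropped))
  print(render_cohort_table(x, digits = digits), quote = FALSE)
  invisible(x)
}

#' One-way repeated-measures ANOVA with Bonferroni-adjusted pairwise contrasts
#'
#' Within-subject decomposition of a complete subject x condition matrix:
#' `SS_total = SS_subjects + SS_conditions + SS_error`,
#' `F = MS_conditions / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. All condition pairs are compared with paired t tests and the raw p
#' values are Bonferroni-multiplied by the number of pairs (capped at 1). No
#' sphericity correction is applied by default; set `gg_correction = TRUE` for
#' Greenhouse-Geisser adjusted degrees of freedom.
#'
#' @param values Numeric matrix, rows = subjects, columns = conditions
#'   (complete; aggregate repeated trials first).
#' @param metric Optional metric label stored in the result.
#' @param gg_correction Apply the Greenhouse-Geisser epsilon to the F test's
#'   degrees of freedom (default FALSE).
#' @return An `rm_anova` object: `F`, `df_effect`, `df_error`, `p`, the sums
#'   of squares (`ss_subjects`, `ss_conditions`, `ss_error`), `epsilon` (GG,
#'   reported even when unused) and `pairwise` (data.frame: pair, mean_diff,
#'   p_raw, p_bonferroni).
#' @export
rm_anova <- function(values, metric = NA_character_, gg_correction = FALSE) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    stop("'values' must be a complete numeric matrix; aggregate trials first")
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 2) stop("need at least 2 subjects")
  if (k < 2) stop("need at least 2 conditions")
  grand <- mean(values)
  row_m <- rowMeans(values)
  col_m <- colMeans(values)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_effect <- k - 1
  df_error <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df_effect
  ms_err <- ss_err / df_error
  f_stat <- if (ms_err <= 0) {
    if (ms_cond <= 0) 0 else Inf
  } else ms_cond / ms_err

  # Greenhouse-Geisser epsilon from the double-centred covariance matrix
  s <- stats::cov(values)
  sc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) +
    mean(s)
  eps <- sum(diag(sc))^2 / ((k - 1) * sum(sc^2))
  eps <- min(1, max(1 / (k - 1), eps))

  d1 <- df_effect; d2 <- df_error
  if (gg_correction) { d1 <- d1 * eps; d2 <- d2 * eps }
  p <- if (is.infinite(f_stat)) 0 else stats::pf(f_stat, d1, d2, lower.tail = FALSE)
  if (f_stat == 0) p <- 1

  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  m_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- values[, a] - values[, b]
    tt <- stats::t.test(d)
    data.frame(pair = paste(cn[a], "vs", cn[b]),
               mean_diff = mean(d),
               p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m_pairs),
               stringsAsFactors = FALSE)
  }))

  structure(list(metric = metric, F = f_stat,
                 df_effect = df_effect, df_error = df_error, p = p,
                 ss_subjects = ss_subj, ss_conditions = ss_cond,
                 ss_error = ss_err, epsilon = eps,
                 gg_correction = gg_correction,
                 n_subjects = n, pairwise = pw),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova%s> F(%g, %g) = %.4g, p = %.4g (n = %d%s)\n",
              if (is.na(x$metric)) "" else paste0(" ", x$metric),
              x$df_effect, x$df_error, x$F, x$p, x$n_subjects,
              if (x$gg_correction) sprintf(", GG eps = %.3f", x$epsilon) else ""))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' KS statistic of the sample against a normal distribution with the sample's
#' own mean and SD, with the p value from the asymptotic Kolmogorov
#' distribution. Because the parameters are estimated from the same sample,
#' this p value is conservative (the Lilliefors caveat); `method =
#' "lilliefors"` uses the Lilliefors-corrected test instead.
#'
#' @param values Numeric sample, n >= 5, non-degenerate.
#' @param metric Optional label.
#' @param method `"ks"` (default, parameters estimated, asymptotic p) or
#'   `"lilliefors"`.
#' @return A `normality_result` list: `metric`, `D`, `p`, `method`, `n`.
#' @export
ks_normality <- function(values, metric = NA_character_,
                         method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5) stop("need at least 5 observations, got ", n)
  s <- stats::sd(values)
  if (s <= 0) stop("zero variance: normality test undefined")
  if (method == "ks") {
    kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values), s,
                                          exact = FALSE))
    res <- list(metric = metric, D = unname(kt$statistic), p = kt$p.value,
                method = "ks_parameters_estimated", n = n)
  } else {
    lt <- nortest::lillie.test(values)
    res <- list(metric = metric, D = unname(lt$statistic), p = lt$p.value,
                method = "lilliefors", n = n)
  }
  structure(res, class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("<normality_result%s> D = %.4f, p = %.4g (n = %d, %s)\n",
              if (is.na(x$metric)) "" else paste0(" ", x$metric),
              x$D, x$p, x$n, x$method))
  invisible(x)
}
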