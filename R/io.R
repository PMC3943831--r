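#' Write a stance trial to delimited text
#'
#' Trial CSV dialect: comma separated, UTF-8, '.' decimal, one header row
#' (`time,angle_deg,moment_Nm,grf_N`), preceded by `#`-prefixed metadata lines
#' (`subject_id`, `speed_category`, `body_mass_kg`, `sampling_rate_hz`).
#' Numbers are written with 17 significant digits so a write/read round trip
#' reproduces the series exactly.
#'
#' @param trial A `gait_trial`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_gait_trial(trial)
  meta <- c(
    sprintf("# subject_id: %s", trial$subject_id),
    sprintf("# speed_category: %s", trial$speed_category),
    sprintf("# body_mass_kg: %.17g", trial$body_mass),
    sprintf("# sampling_rate_hz: %.17g", trial$sampling_rate)
  )
  num <- function(x) sprintf("%.17g", x)
  rows <- paste(num(trial$time), num(trial$angle_deg),
                num(trial$moment_nm), num(trial$grf_n), sep = ",")
  writeLines(c(meta, "time,angle_deg,moment_Nm,grf_N", rows), path)
  invisible(path)
}

#' Read a stance trial from delimited text
#'
#' Parses the trial CSV schema written by [write_trial()] and validates it:
#' required columns present, all values finite (offending data rows are named
#' by line index), time strictly increasing, at least 20 samples, and
#' non-negative vertical GRF. The moment column holds the un-normalised joint
#' moment in N m, plantarflexor-positive; the angle is in degrees,
#' dorsiflexion-positive.
#'
#' @param path Path to a trial CSV file.
#' @return A `gait_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  for (req in c("subject_id", "speed_category", "body_mass_kg", "sampling_rate_hz")) {
    if (is.null(meta[[req]])) stop("trial file ", path, " is missing metadata '", req, "'")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  required <- c("time", "angle_deg", "moment_Nm", "grf_N")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trial file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in required) {
    v <- df[[cn]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("trial file ", path, ": non-finite '", cn, "' value at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[cn]] <- v
  }
  if (nrow(df) < 20) {
    stop("trial file ", path, " has only ", nrow(df), " samples; at least 20 required")
  }
  if (any(diff(df$time) <= 0)) {
    stop("trial file ", path, ": 'time' must be strictly increasing")
  }
  if (any(df$grf_N < 0)) {
    stop("trial file ", path, ": 'grf_N' must be non-negative")
  }
  trial <- structure(list(
    subject_id = meta$subject_id,
    speed_category = meta$speed_category,
    body_mass = as.numeric(meta$body_mass_kg),
    sampling_rate = as.numeric(meta$sampling_rate_hz),
    time = df$time,
    angle_deg = df$angle_deg,
    moment_nm = df$moment_Nm,
    grf_n = df$grf_N
  ), class = "gait_trial")
  validate_gait_trial(trial)
  trial
}

#' Write / read a ground-truth sidecar
#'
#' Ground truth for a generated trial is stored as a JSON sidecar next to the
#' trial CSV so analyses can score parameter recovery.
#'
#' @param truth A `gait_ground_truth`.
#' @param path Output JSON path.
#' @return `path` (write) or a `gait_ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "gait_ground_truth")
}

#' Export a processed trial
#'
#' Writes the stance-normalised series (`percent_stance, angle_rad,
#' moment_norm, omega, power_norm`) as CSV.
#'
#' @param ptrial A `processed_trial` (see [process_trial()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_processed <- function(ptrial, path) {
  df <- data.frame(percent_stance = ptrial$percent_stance,
                   angle_rad = ptrial$angle_rad,
                   moment_norm = ptrial$moment_norm,
                   omega = ptrial$omega,
                   power_norm = ptrial$power_norm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
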