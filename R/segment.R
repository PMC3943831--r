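#' Segment stance into CP, CD and PP sub-phases
#'
#' Locates the two internal boundaries of the three stance sub-phases on a
#' processed trial:
#'
#' * `cp_end` — end of controlled plantarflexion: the global angle minimum
#'   (maximum early plantarflexion) within the first `cp_window` fraction of
#'   stance;
#' * `cd_end` — end of controlled dorsiflexion: by the default `"power"` rule,
#'   the last sample before joint power crosses from negative to positive and
#'   stays positive for at least `persistence` samples, searched within
#'   `pp_window` of stance around the angle maximum. This guarantees that
#'   power is non-positive throughout CD and positive at the start of PP. The
#'   alternative `"angle"` rule places the boundary at the angle maximum
#'   itself.
#'
#' Heel strike and toe-off are the first and last samples of the processed
#' (stance-cropped) trial. A diagnostics field records the sample distance
#' between the power crossing and the angle maximum, which the two boundary
#' definitions can disagree by.
#'
#' @param ptrial A `processed_trial`.
#' @param cp_window Fraction of stance searched for the CP trough (default
#'   0.35; CP is short, and the search must not reach the toe-off
#'   plantarflexion).
#' @param pp_window Half-width, as a fraction of stance, of the search window
#'   around the angle maximum for the power crossing (default 0.10).
#' @param persistence Number of consecutive positive-power samples required to
#'   accept the crossing (default 3; suppresses noise-induced zero-crossing
#'   chatter).
#' @param cd_rule `"power"` (default) or `"angle"`.
#' @return A `stance_segmentation`: indices `heel_strike`, `cp_end`, `cd_end`,
#'   `toe_off`, a per-sample factor `phase_of` with levels CP/CD/PP, and
#'   `diagnostics`.
#' @export
segment_phases <- function(ptrial, cp_window = 0.35, pp_window = 0.10,
                           persistence = 3L, cd_rule = c("power", "angle")) {
  cd_rule <- match.arg(cd_rule)
  angle <- ptrial$angle_rad
  power <- ptrial$power_norm
  n <- length(angle)
  if (n < 9) stop("processed trial too short to segment")

  # CP trough: global angle minimum in the early-stance window
  w_end <- max(4L, as.integer(floor(cp_window * n)))
  cp_end <- which.min(angle[1:w_end])
  trough_ok <- cp_end > 1L &&
    (cp_end < w_end || (w_end < n && angle[w_end + 1L] >= angle[w_end]))
  if (!trough_ok || angle[cp_end] >= angle[1]) {
    stop("no CP trough: angle has no early-stance plantarflexion minimum")
  }
  if (cp_end < 3L) cp_end <- 3L  # CP must contain at least 3 samples

  i_max <- which.max(angle[cp_end:n]) + cp_end - 1L

  if (cd_rule == "angle") {
    cd_end <- i_max
  } else {
    half <- max(2L, as.integer(round(pp_window * n)))
    lo <- max(cp_end + 3L, i_max - half)
    hi <- min(n - 3L, i_max + half)
    cd_end <- NA_integer_
    if (lo <= hi) {
      for (j in lo:hi) {
        run_end <- min(n, j + persistence - 1L)
        if (power[j] > 0 && all(power[j:run_end] > 0)) {
          cd_end <- j - 1L
          break
        }
      }
    }
    if (is.na(cd_end)) {
      stop("no PP onset: power never crosses to sustained positive values ",
           "near the dorsiflexion maximum")
    }
    # the boundary sample is the local dorsiflexion peak: if the sample after
    # the crossing is still higher, the peak itself ends CD (at most one step)
    if (cd_end + 1L <= n - 3L && angle[cd_end + 1L] > angle[cd_end]) {
      cd_end <- cd_end + 1L
    }
  }
  if (cd_end - cp_end < 3L || n - cd_end < 3L) {
    stop("segmentation failed: a sub-phase has fewer than 3 samples")
  }

  phase_of <- factor(rep("PP", n), levels = c("CP", "CD", "PP"))
  phase_of[1:cp_end] <- "CP"
  phase_of[(cp_end + 1L):cd_end] <- "CD"

  structure(list(
    heel_strike = 1L,
    cp_end = cp_end,
    cd_end = cd_end,
    toe_off = n,
    phase_of = phase_of,
    diagnostics = list(
      angle_max_index = i_max,
      power_crossing_minus_angle_max = if (cd_rule == "power") {
        (cd_end + 1L) - i_max
      } else NA_integer_,
      cd_rule = cd_rule
    )
  ), class = "stance_segmentation")
}

#' Per-phase index ranges of a segmentation
#'
#' Integration and regression segments share their boundary samples, so the
#' per-phase trapezoidal works telescope to the whole-stance integral.
#'
#' @param seg A `stance_segmentation`.
#' @return Named list of integer index vectors `cp`, `cd`, `pp`.
#' @export
phase_segments <- function(seg) {
  list(cp = seg$heel_strike:seg$cp_end,
       cd = seg$cp_end:seg$cd_end,
       pp = seg$cd_end:seg$toe_off)
}

#' @export
print.stance_segmentation <- function(x, ...) {
  cat(sprintf("<stance_segmentation> CP [%d..%d], CD (..%d], PP (..%d]\n",
              x$heel_strike, x$cp_end, x$cd_end, x$toe_off))
  cat(sprintf("  cd rule: %s; power crossing vs angle max: %s samples\n",
              x$diagnostics$cd_rule,
              x$diagnostics$power_crossing_minus_angle_max))
  invisible(x)
}

#' Export a segmentation as JSON
#'
#' @param seg A `stance_segmentation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  out <- list(heel_strike = seg$heel_strike, cp_end = seg$cp_end,
              cd_end = seg$cd_end, toe_off = seg$toe_off,
              phase_of = as.character(seg$phase_of),
              diagnostics = seg$diagnostics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
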