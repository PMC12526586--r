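# Freezing-like event (FLE) detection: intervals where walking speed
# drops below a fraction of a baseline speed for at least a minimum
# duration, attributed to the doorway when they overlap the doorway
# passage.

#' Detect freezing-like runs in a speed trace
#'
#' Pure run-detection core: maximal runs of frames with
#' `speed < threshold_frac * baseline_speed` lasting at least
#' `min_duration_s`.
#'
#' @param speed Numeric speed trace (m/s), one sample per frame.
#' @param rate_hz Sampling rate, Hz.
#' @param baseline_speed Baseline speed, m/s (> 0).
#' @param threshold_frac Fraction of baseline defining a freeze (default 0.10).
#' @param min_duration_s Minimum event duration, s (default 0.5).
#' @return Data frame with `start_frame`, `end_frame` (0-based, half-open)
#'   and `duration_s`.
#' @export
fle_from_speed <- function(speed, rate_hz, baseline_speed,
                           threshold_frac = 0.10, min_duration_s = 0.5) {
  if (baseline_speed <= 0) stop("baseline_speed must be > 0")
  below <- speed < threshold_frac * baseline_speed
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate_hz) >= min_duration_s
  data.frame(start_frame = starts[keep] - 1L,
             end_frame = ends[keep],
             duration_s = r$lengths[keep] / rate_hz)
}

#' Detect freezing-like events in a trial
#'
#' Walking speed is the absolute AP velocity of the pelvis midpoint
#' (6 Hz zero-lag low-pass before differentiating). Events are maximal
#' sub-threshold runs of at least `min_duration_s` restricted to walking
#' task windows (scripted stops such as the turn or the reach do not
#' count), located at the doorway when they overlap the doorway passage.
#'
#' @param trial A preprocessed [trial_recording()].
#' @param baseline_speed Baseline walking speed, m/s, from
#'   [baseline_speed_from_tug()].
#' @param segments Named list of [task_segment()] from [segment_trial()];
#'   walking windows are `walk_out`, `walk_back` and `locomotion_lap`.
#' @param threshold_frac,min_duration_s See [fle_from_speed()].
#' @param kin Optional precomputed [segment_kinematics()].
#' @return Data frame with `start_frame`, `end_frame`, `duration_s` and
#'   `location` (`"doorway"`, `"open_walkway"`).
#' @export
detect_fle <- function(trial, baseline_speed, segments,
                       threshold_frac = 0.10, min_duration_s = 0.5,
                       kin = segment_kinematics(trial)) {
  if (baseline_speed <= 0) stop("baseline_speed must be > 0")
  rate <- kin$rate_hz
  speed <- abs(deriv_central(lp_zerolag(kin$pelvis_mid[, 1], rate), rate))
  walking <- segments[names(segments) %in% c("walk_out", "walk_back", "locomotion_lap")]
  doors <- segments[grepl("^doorway_pass", names(segments))]
  out <- NULL
  for (seg in walking) {
    idx <- seg_idx(seg)
    ev <- fle_from_speed(speed[idx], rate, baseline_speed,
                         threshold_frac, min_duration_s)
    if (!nrow(ev)) next
    ev$start_frame <- ev$start_frame + seg$start_frame
    ev$end_frame <- ev$end_frame + seg$start_frame
    ev$location <- "open_walkway"
    for (door in doors) {
      overlap <- pmin(ev$end_frame, door$end_frame) -
                 pmax(ev$start_frame, door$start_frame)
      ev$location[overlap > 0] <- "doorway"
    }
    out <- rbind(out, ev)
  }
  if (is.null(out))
    out <- data.frame(start_frame = integer(), end_frame = integer(),
                      duration_s = numeric(), location = character())
  out[order(out$start_frame), , drop = FALSE]
}

#' Baseline walking speed from timed-up-and-go trials
#'
#' The mean of the departure walking speed and the absolute value of the
#' return walking speed (negative by trajectory), each from the pelvis
#' midpoint AP displacement over its walking segment, averaged over
#' trials.
#'
#' @param tug_trials List of preprocessed [trial_recording()] objects
#'   (timed-up-and-go protocol).
#' @return Baseline speed, m/s.
#' @export
baseline_speed_from_tug <- function(tug_trials) {
  if (!length(tug_trials)) stop("no trials: baseline speed unavailable")
  speeds <- vapply(tug_trials, function(trial) {
    sg <- segment_trial(trial)
    w_out <- sg$segments[["walk_out"]]
    w_back <- sg$segments[["walk_back"]]
    if (is.null(w_out) && is.null(w_back))
      stop("no walking segments in trial: baseline speed unavailable")
    seg_speed <- function(seg) {
      ap <- sg$kin$pelvis_mid[seg_idx(seg), 1]
      (ap[length(ap)] - ap[1]) / ((seg$end_frame - seg$start_frame) / sg$kin$rate_hz)
    }
    vals <- c()
    if (!is.null(w_out)) vals <- c(vals, seg_speed(w_out))
    if (!is.null(w_back)) vals <- c(vals, abs(seg_speed(w_back)))
    mean(vals)
  }, numeric(1))
  mean(speeds)
}
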