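# Task segmentation: cut a trial into the protocol's labeled phases.
#
# Frames are 0-based, segments half-open [start_frame, end_frame).

#' Construct a task segment
#'
#' @param task Task label (e.g. `"sit_to_stand"`, `"turn"`).
#' @param start_frame,end_frame 0-based half-open frame interval.
#' @param events Named list of delimiting event frames.
#' @param flags Character vector of quality flags.
#' @return Object of class `task_segment`.
#' @export
task_segment <- function(task, start_frame, end_frame, events = list(),
                         flags = character()) {
  if (start_frame >= end_frame) stop("task segment requires start < end")
  structure(list(task = task, start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame), events = events,
                 flags = flags),
            class = "task_segment")
}

#' @export
print.task_segment <- function(x, ...) {
  cat(sprintf("<task_segment %s: [%d, %d)%s>\n", x$task, x$start_frame,
              x$end_frame,
              if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

# Internal: 1-based R indices of a segment's frames.
seg_idx <- function(seg) (seg$start_frame + 1L):seg$end_frame

# Internal: first index (1-based) where x exceeds `thresh` for at least
# `min_run` consecutive samples, searching from `from`; NA if none.
sustained_above <- function(x, thresh, min_run, from = 1L) {
  above <- x > thresh
  above[seq_len(from - 1L)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1]]
}

# Internal: trunk bend velocity (deg/s), low-passed. Uses the
# heading-invariant angle from vertical so bend onsets are detected
# identically on the outbound and return paths.
incl_velocity <- function(kin) {
  deriv_central(lp_zerolag(kin$incl_mag, kin$rate_hz), kin$rate_hz)
}

#' Segment the sit-to-stand transition
#'
#' Starts at the onset of the trunk bend (AP inclination velocity above
#' `bend_rate_deg_s` sustained for `sustain_s`) and ends at the first toe
#' off of either foot. If no footstep is found, the end falls back to the
#' first frame with more than 0.2 m of pelvis AP displacement (flagged).
#'
#' @param trial A [trial_recording()].
#' @param events A [gait_events()].
#' @param kin Optional precomputed [segment_kinematics()].
#' @param bend_rate_deg_s Trunk-bend onset threshold, deg/s.
#' @param sustain_s Time the threshold must be sustained, s.
#' @return A [task_segment()] or `NULL` when no trunk motion exists.
#' @export
segment_sit_to_stand <- function(trial, events, kin = segment_kinematics(trial),
                                 bend_rate_deg_s = 10, sustain_s = 0.1) {
  rate <- kin$rate_hz
  vel <- incl_velocity(kin)
  onset <- sustained_above(vel, bend_rate_deg_s, max(1L, round(sustain_s * rate)))
  if (is.na(onset)) return(NULL)
  start <- onset - 1L                      # 0-based
  tos <- sort(c(events$L$to, events$R$to))
  tos <- tos[tos > start]
  flags <- character()
  if (length(tos)) {
    end <- tos[1]
  } else {
    disp <- abs(kin$pelvis_mid[, 1] - kin$pelvis_mid[onset, 1])
    hit <- which(disp > 0.2 & seq_along(disp) > onset)
    if (!length(hit)) return(NULL)
    end <- hit[1] - 1L
    flags <- "no_footstep_fallback"
  }
  task_segment("sit_to_stand", start, end,
               events = list(bend_onset = start, first_toe_off = end),
               flags = flags)
}

#' Segment the 180-degree turn
#'
#' Locates the pelvis-yaw excursion; the segment runs from the last toe
#' off of the turning foot (ipsilateral to the turn direction) before yaw
#' onset to the first heel strike of the swing foot after the cumulative
#' yaw reaches 180 degrees minus `yaw_tol`.
#'
#' @inheritParams segment_sit_to_stand
#' @param yaw_tol Completion tolerance, degrees (default 10).
#' @return A [task_segment()] or `NULL` (with a warning) when the yaw
#'   excursion never reaches 180 - `yaw_tol` degrees.
#' @export
segment_turn <- function(trial, events, kin = segment_kinematics(trial),
                         yaw_tol = 10) {
  yaw <- lp_zerolag(kin$yaw[, "pelvis"], kin$rate_hz)
  y0 <- stats::quantile(yaw, 0.02, names = FALSE)
  y <- yaw - y0
  if (max(y) < 180 - yaw_tol) {
    warning("pelvis yaw never reaches a 180-degree excursion; no turn segment")
    return(NULL)
  }
  onset <- which(y > 5)[1]
  complete <- which(y >= 180 - yaw_tol)[1]
  turning_foot <- if (identical(trial$subject_meta$turn_direction, "CW")) "R" else "L"
  swing_foot <- setdiff(c("L", "R"), turning_foot)
  tos <- events[[turning_foot]]$to
  tos <- tos[tos <= onset - 1L]
  start <- if (length(tos)) max(tos) else onset - 1L
  hss <- events[[swing_foot]]$hs
  hss <- hss[hss >= complete - 1L]
  if (!length(hss)) {
    warning("no swing-foot heel strike after turn completion")
    return(NULL)
  }
  task_segment("turn", start, hss[1],
               events = list(yaw_onset = onset - 1L, yaw_complete = complete - 1L,
                             turning_foot = turning_foot))
}

#' Segment the functional reach (key pick-up)
#'
#' From the first trunk-bend onset after the turn to the key-lift proxy:
#' the first frame where the dominant wrist, having reached its height
#' minimum, rises by more than `rise_m`.
#'
#' @inheritParams segment_sit_to_stand
#' @param after_frame 0-based frame after which to search (turn end).
#' @param rise_m Wrist rise (m) above its minimum taken as the key lift.
#' @param descend_below_m The wrist must descend below this height (m) for
#'   a reach to exist at all.
#' @param gap_s Maximum gap (s) between wrist descents counted as repeated
#'   attempts of the same reach.
#' @return A [task_segment()] (attempt count recorded in `events`) or
#'   `NULL` when no reach is found.
#' @export
segment_functional_reach <- function(trial, kin = segment_kinematics(trial),
                                     after_frame = 0L, rise_m = 0.02,
                                     descend_below_m = 0.40,
                                     bend_rate_deg_s = 10, sustain_s = 0.1,
                                     gap_s = 1) {
  rate <- kin$rate_hz
  vel <- incl_velocity(kin)
  onset <- sustained_above(vel, bend_rate_deg_s, max(1L, round(sustain_s * rate)),
                           from = after_frame + 1L)
  if (is.na(onset)) return(NULL)
  wname <- if (identical(trial$subject_meta$dominant_hand, "L")) "LWRA" else "RWRA"
  wz <- lp_zerolag(get_marker(trial, wname, "functional reach")$positions[, 3], rate)
  n <- length(wz)
  below <- wz < descend_below_m
  if (onset > 1L) below[seq_len(onset - 1L)] <- FALSE
  if (!any(below)) return(NULL)
  # contiguous below-threshold descents; runs separated by less than
  # `gap_s` belong to the same reach (repeated grab attempts), while the
  # later, unrelated descent of the hanging arm when sitting does not
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  gap <- round(gap_s * rate)
  keep <- 1L
  while (keep < nrow(runs) &&
         runs$start[keep + 1L] - runs$end[keep] <= gap) keep <- keep + 1L
  attempts <- keep
  win <- runs$start[1]:runs$end[attempts]
  imin <- win[which.min(wz[win])]
  lift <- which(wz > wz[imin] + rise_m & seq_len(n) > imin)
  end <- if (length(lift)) lift[1] - 1L else n - 1L
  task_segment("functional_reach", onset - 1L, end,
               events = list(bend_onset = onset - 1L, wrist_min = imin - 1L,
                             attempts = attempts))
}

#' Segment the stand-to-sit transition
#'
#' Starts at the last heel strike preceding the sustained reverse trunk
#' bend near the chair and ends when the pelvis vertical velocity returns
#' to zero with the pelvis within 10% of its initial seated height.
#'
#' @inheritParams segment_sit_to_stand
#' @param seat_tol Relative tolerance on the seated pelvis height.
#' @return A [task_segment()] (open-ended and flagged if the pelvis never
#'   returns to seated height) or `NULL`.
#' @export
segment_stand_to_sit <- function(trial, events, kin = segment_kinematics(trial),
                                 seat_tol = 0.10, bend_rate_deg_s = 10,
                                 sustain_s = 0.1) {
  rate <- kin$rate_hz
  z <- lp_zerolag(kin$pelvis_mid[, 3], rate)
  n <- length(z)
  h_seat <- z[1]
  h_stand <- stats::quantile(z, 0.95, names = FALSE)
  if (h_stand - h_seat < 0.1) return(NULL)
  mid <- (h_stand + h_seat) / 2
  below <- z < mid
  desc <- which(!below[-n] & below[-1]) + 1L     # downward crossings
  desc <- desc[desc > n / 2]
  if (!length(desc)) return(NULL)
  t_mid <- desc[length(desc)]
  vel <- incl_velocity(kin)
  run <- max(1L, round(sustain_s * rate))
  onsets <- which(vel > bend_rate_deg_s)
  onsets <- onsets[onsets < t_mid]
  onset <- if (length(onsets)) max(onsets) else t_mid
  hss <- sort(c(events$L$hs, events$R$hs))
  hss <- hss[hss <= onset - 1L]
  start <- if (length(hss)) max(hss) else onset - 1L
  vz <- deriv_central(z, rate)
  settled <- which(abs(vz) < 0.05 & z <= h_seat * (1 + seat_tol) &
                   seq_len(n) > t_mid)
  if (length(settled)) {
    end <- settled[1] - 1L
    flags <- character()
  } else {
    end <- n - 1L
    flags <- "open_ended"
  }
  if (end <= start) end <- min(n - 1L, start + 1L)
  task_segment("stand_to_sit", start, end,
               events = list(bend_onset = onset - 1L, descent_mid = t_mid - 1L),
               flags = flags)
}

#' Segment quiet standing
#'
#' The 10 s window (centered in case of ties) with minimal pelvis
#' horizontal displacement. Trials shorter than the window are used whole
#' and flagged.
#'
#' @inheritParams segment_sit_to_stand
#' @param window_s Window length, s (default 10).
#' @return A [task_segment()].
#' @export
segment_standing <- function(trial, kin = segment_kinematics(trial),
                             window_s = 10) {
  rate <- kin$rate_hz
  n <- nrow(kin$pelvis_mid)
  w <- round(window_s * rate)
  if (n <= w)
    return(task_segment("standing", 0L, n, flags = "short_trial"))
  xy <- kin$pelvis_mid[, 1:2]
  # displacement range inside each window, via running min/max
  score <- vapply(seq_len(n - w + 1L), function(i) {
    win <- xy[i:(i + w - 1L), , drop = FALSE]
    sum(apply(win, 2, function(c) diff(range(c))))
  }, numeric(1))
  best <- which(score <= min(score) + 1e-12)
  i0 <- best[which.min(abs(best - (n - w) / 2))]   # prefer centered
  task_segment("standing", i0 - 1L, i0 - 1L + w)
}

#' Segment a whole trial into its protocol's tasks
#'
#' Orchestrates event detection and the task segmenters for the trial's
#' protocol. For the full mobility sequence this yields sit_to_stand,
#' walk_out, doorway_pass, turn, functional_reach (sequence protocol
#' only), walk_back and stand_to_sit; the standing protocol yields the
#' quiet-standing window; the locomotion protocol yields a single
#' locomotion lap spanning the walking interval.
#'
#' @param trial A preprocessed [trial_recording()].
#' @param kin Optional precomputed [segment_kinematics()].
#' @param events Optional precomputed [gait_events()].
#' @param doorway_ap_m AP position of the doorframe, m (default 1.5).
#' @param doorway_halfwidth_m Half-extent of the doorway passage, m.
#' @return List with `segments` (named list of [task_segment()]), `events`
#'   and `kin`.
#' @export
segment_trial <- function(trial, kin = NULL, events = NULL,
                          doorway_ap_m = 1.5, doorway_halfwidth_m = 0.25) {
  if (is.null(kin)) kin <- segment_kinematics(trial)
  if (is.null(events)) events <- detect_gait_events(trial)
  n <- n_frames(trial)
  segs <- list()
  if (trial$protocol == "standing") {
    segs$standing <- segment_standing(trial, kin)
    return(list(segments = segs, events = events, kin = kin))
  }
  if (trial$protocol == "locomotion") {
    hs_all <- sort(c(events$L$hs, events$R$hs))
    if (length(hs_all) >= 2)
      segs$locomotion_lap <- task_segment("locomotion_lap", max(0L, hs_all[1] - 50L),
                                          min(n, hs_all[length(hs_all)] + 50L))
    else segs$locomotion_lap <- task_segment("locomotion_lap", 0L, n)
    return(list(segments = segs, events = events, kin = kin))
  }
  sts <- segment_sit_to_stand(trial, events, kin)
  trn <- segment_turn(trial, events, kin)
  segs$sit_to_stand <- sts
  segs$turn <- trn
  reach <- NULL
  if (trial$protocol == "fmap" && !is.null(trn))
    reach <- segment_functional_reach(trial, kin, after_frame = trn$end_frame)
  segs$functional_reach <- reach
  sit <- segment_stand_to_sit(trial, events, kin)
  segs$stand_to_sit <- sit
  if (!is.null(sts) && !is.null(trn) && trn$start_frame > sts$end_frame)
    segs$walk_out <- task_segment("walk_out", sts$end_frame, trn$start_frame)
  back_start <- if (!is.null(reach)) reach$end_frame
                else if (!is.null(trn)) trn$end_frame else NA
  # walking resumes at the first toe off after the preceding task ends
  if (!is.na(back_start)) {
    tos <- sort(c(events$L$to, events$R$to))
    tos <- tos[tos >= back_start]
    if (length(tos)) back_start <- tos[1]
  }
  back_end <- if (!is.null(sit)) sit$start_frame else n
  if (!is.na(back_start) && back_end > back_start)
    segs$walk_back <- task_segment("walk_back", back_start, back_end)
  # doorway passages: contiguous runs with the pelvis within +-0.25 m AP
  # of the doorframe (one run per crossing direction)
  ap <- kin$pelvis_mid[, 1]
  near <- abs(ap - doorway_ap_m) <= doorway_halfwidth_m
  r <- rle(near)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2)
  for (k in seq_along(runs)) {
    nm <- if (k == 1) "doorway_pass" else sprintf("doorway_pass_%d", k)
    segs[[nm]] <- task_segment("doorway_pass", starts[runs[k]] - 1L,
                               ends[runs[k]])
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  list(segments = segs, events = events, kin = kin)
}

#' Export segment boundaries as JSON
#'
#' @param segments Named list of [task_segment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_json <- function(segments, path) {
  out <- lapply(segments, function(s)
    list(task = s$task, start_frame = s$start_frame, end_frame = s$end_frame))
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE)
  invisible(path)
}
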