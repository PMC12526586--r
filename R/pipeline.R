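# End-to-end per-trial analysis: preprocessing, event detection, task
# segmentation and metric extraction into a tidy metric table; plus a
# YAML-driven batch runner for the command-line interface.

# Internal: append one metric row.
mrow <- function(subject_id, group, protocol, phase, trial_index, task,
                 metric_name, value, units) {
  data.frame(subject_id = subject_id, group = group, protocol = protocol,
             phase = phase, trial_index = trial_index, task = task,
             metric_name = metric_name, value = as.numeric(value),
             units = units, stringsAsFactors = FALSE)
}

#' Analyze one trial into metric rows
#'
#' Runs preprocessing (gap filling, despiking, COP filtering), gait-event
#' detection, task segmentation and the full metric set appropriate to the
#' trial's protocol. Metrics whose preconditions fail (missing markers,
#' too few strides, degenerate geometry) are skipped with a warning rather
#' than reported as fabricated values.
#'
#' @param trial A [trial_recording()].
#' @param subject_id,group,trial_index,phase Identification columns for
#'   the output rows.
#' @param baseline_speed Baseline walking speed (m/s) enabling
#'   freezing-like-event metrics, typically [baseline_speed_from_tug()].
#' @param preprocess Apply [preprocess_trial()] first (default `TRUE`).
#' @return A [metric_table()].
#' @export
analyze_trial <- function(trial, subject_id = "S001", group = "control",
                          trial_index = 1L, phase = NA_character_,
                          baseline_speed = NULL, preprocess = TRUE) {
  if (preprocess) trial <- preprocess_trial(trial)$trial
  sg <- segment_trial(trial)
  segs <- sg$segments; events <- sg$events; kin <- sg$kin
  rows <- NULL
  add <- function(task, metric, value, units) {
    if (is.null(value) || !length(value) || !is.finite(value)) return()
    rows <<- rbind(rows, mrow(subject_id, group, trial$protocol, phase,
                              trial_index, task, metric, value, units))
  }
  try_metric <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NULL
  })

  for (task in c("sit_to_stand", "stand_to_sit")) {
    seg <- segs[[task]]
    if (is.null(seg)) next
    ti <- try_metric(trunk_inclination(seg, kin))
    add(task, "peak_trunk_inclination_ap", ti$peak_ap, "deg")
    add(task, "peak_trunk_inclination_ml", ti$peak_ml, "deg")
    td <- try_metric(trunk_dynamics(seg, kin))
    add(task, "peak_trunk_velocity_ap", td$peak_velocity_ap, "m/s")
    add(task, "rms_trunk_accel_ap", td$rms_accel_ap, "m/s^2")
    add(task, "mean_trunk_jerk", td$mean_jerk, "m/s^3")
    jf <- try_metric(joint_flexion(seg, trial, kin))
    add(task, "peak_pelvis_flexion", jf$peak_pelvis_flexion, "deg")
    add(task, "peak_knee_flexion", jf$peak_knee_flexion, "deg")
    cp <- if (!is.null(trial$mat)) try_metric(cop_displacement(seg, trial$mat, trial))
    add(task, "mean_cop_ap_mm", cp$mean_ap_mm, "mm")
    add(task, "mean_cop_ml_mm", cp$mean_ml_mm, "mm")
  }

  if (!is.null(segs$turn)) {
    seg <- segs$turn
    yp <- try_metric(yaw_turning_profile(seg, kin, events))
    for (s in c("head", "trunk", "pelvis"))
      add("turn", paste0("abs_yaw_", s), yp$abs_yaw[[s]], "deg")
    for (s in names(yp$rel_yaw))
      add("turn", paste0("rel_yaw_", s), yp$rel_yaw[[s]], "deg")
    for (s in c("head", "trunk", "pelvis"))
      add("turn", paste0("onset_", s, "_pct"), yp$onset_pct[[s]], "%")
    ti <- try_metric(trunk_inclination(seg, kin))
    add("turn", "peak_trunk_inclination_ap", ti$peak_ap, "deg")
    add("turn", "peak_trunk_inclination_ml", ti$peak_ml, "deg")
    fa <- try_metric(foot_angles(trial, events, seg))
    add("turn", "to_angle_deg", fa$to_angle, "deg")
    add("turn", "hs_angle_deg", fa$hs_angle, "deg")
    cp <- if (!is.null(trial$mat)) try_metric(cop_displacement(seg, trial$mat, trial))
    add("turn", "mean_cop_ap_mm", cp$mean_ap_mm, "mm")
    add("turn", "mean_cop_ml_mm", cp$mean_ml_mm, "mm")
  }

  if (!is.null(segs$functional_reach)) {
    seg <- segs$functional_reach
    st <- try_metric(stance_geometry(seg, trial))
    add("functional_reach", "ap_foot_distance_m", st$ap_foot_distance_m, "m")
    add("functional_reach", "max_stance_width_m", st$max_stance_width_m, "m")
    add("functional_reach", "aperture_angle_deg", st$aperture_angle_deg, "deg")
    add("functional_reach", "max_to_angle_deg", st$max_to_angle_deg, "deg")
    add("functional_reach", "arm_alignment_angle_deg",
        st$arm_alignment_angle_deg, "deg")
    add("functional_reach", "reach_attempts", seg$events$attempts, "count")
  }

  if (!is.null(segs$standing)) {
    seg <- segs$standing
    cp <- if (!is.null(trial$mat))
      try_metric(cop_displacement(seg, trial$mat, trial, standing = TRUE))
    add("standing", "mean_cop_ap_mm", cp$mean_ap_mm, "mm")
    add("standing", "mean_cop_ml_mm", cp$mean_ml_mm, "mm")
    add("standing", "range_cop_ap_mm", cp$range_ap_mm, "mm")
    add("standing", "range_cop_ml_mm", cp$range_ml_mm, "mm")
    add("standing", "rms_cop_ap_mm", cp$rms_ap_mm, "mm")
    add("standing", "rms_cop_ml_mm", cp$rms_ml_mm, "mm")
    lt <- try_metric(lateral_tilt(seg, trial))
    add("standing", "mean_lateral_tilt_deg", lt$mean_deg, "deg")
    add("standing", "max_lateral_tilt_deg", lt$max_deg, "deg")
  }

  # walking windows: the lap for the locomotion protocol, the out/back
  # walkway passes otherwise
  walk_segs <- segs[names(segs) %in% c("locomotion_lap", "walk_out", "walk_back")]
  if (length(walk_segs)) {
    walk_task <- if (trial$protocol == "locomotion") "locomotion_lap" else "walking"
    det <- NULL
    for (seg in walk_segs) {
      g <- tryCatch(spatiotemporal_gait(events, trial, seg, min_strides = 1),
                    error = function(e) NULL)
      if (!is.null(g)) det <- rbind(det, g$detail)
    }
    if (!is.null(det) && nrow(det) >= 3) {
      g <- summarize_stride_detail(det)
      add(walk_task, "stride_length_m", g$stride_length_m, "m")
      add(walk_task, "stride_time_s", g$stride_time_s, "s")
      add(walk_task, "stride_velocity_m_s", g$stride_velocity_m_s, "m/s")
      add(walk_task, "stride_width_m", g$stride_width_m, "m")
      add(walk_task, "double_support_pct", g$double_support_pct, "%")
      for (pn in names(g$asymmetry_pct))
        add(walk_task, paste0("asym_", pn), g$asymmetry_pct[[pn]], "%")
      for (pn in names(g$variability_pct))
        add(walk_task, paste0("cv_", pn), g$variability_pct[[pn]], "%")
    }
    # foot angles over the walking windows (pooled events)
    fa_vals <- list(to = c(), hs = c(), fc = c())
    for (seg in walk_segs) {
      fa <- try_metric(foot_angles(trial, events, seg))
      if (is.null(fa) || is.null(fa$detail)) next
      fa_vals$to <- c(fa_vals$to, fa$detail$angle[fa$detail$event == "TO"])
      fa_vals$hs <- c(fa_vals$hs, fa$detail$angle[fa$detail$event == "HS"])
      fa_vals$fc <- c(fa_vals$fc, fa$detail$clearance[fa$detail$event == "swing"])
    }
    if (length(fa_vals$to)) add(walk_task, "to_angle_deg", mean(fa_vals$to), "deg")
    if (length(fa_vals$hs)) add(walk_task, "hs_angle_deg", mean(fa_vals$hs), "deg")
    if (length(fa_vals$fc))
      add(walk_task, "min_foot_clearance_m", mean(fa_vals$fc), "m")
    # arm swing on the walking segment holding the most strides
    n_str <- vapply(walk_segs, function(s)
      sum(events$strides$start_hs >= s$start_frame &
          events$strides$end_hs <= s$end_frame), numeric(1))
    best <- walk_segs[[which.max(n_str)]]
    aw <- try_metric(arm_swing(best, trial, kin, events))
    add(walk_task, "total_swing_dominant", aw$total_swing_dominant, "deg")
    add(walk_task, "total_swing_nondominant", aw$total_swing_nondominant, "deg")
    add(walk_task, "asa_percent", aw$asa_percent, "%")
    if (!is.null(aw))
      add(walk_task, "mean_arm_velocity", mean(aw$segment_velocities), "deg/s")
    if (!is.null(baseline_speed)) {
      fe <- try_metric(detect_fle(trial, baseline_speed, segs, kin = kin))
      if (!is.null(fe)) {
        add(walk_task, "fle_count", nrow(fe), "count")
        add(walk_task, "fle_total_duration_s",
            if (nrow(fe)) sum(fe$duration_s) else 0, "s")
        add(walk_task, "fle_doorway_count", sum(fe$location == "doorway"), "count")
      }
    }
  }

  if (is.null(rows))
    rows <- mrow(subject_id, group, trial$protocol, phase, trial_index,
                 "none", "none", NA, "")[0, ]
  metric_table(rows)
}

#' Read a batch run configuration
#'
#' YAML with top-level keys `output` (metric table CSV path), optional
#' `baseline_speed_m_s`, and `subjects`: a list of `{id, group, trials:
#' [{file, protocol, trial_index, phase, mat}]}` where `mat` is an
#' optional pressure-mat export CSV attached to the trial. Unknown
#' top-level keys are rejected.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("output", "baseline_speed_m_s", "subjects")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$subjects) || !length(cfg$subjects))
    stop("configuration needs at least one subject")
  cfg
}

# Internal: load a trial from a file path by extension, optionally
# attaching a pressure-mat export.
load_trial_file <- function(file, protocol, trial_index,
                            subject_meta = list(), mat_file = NULL) {
  trial <- if (grepl("\\.c3d$", file, ignore.case = TRUE))
    read_c3d_trial(file, protocol = protocol, trial_index = trial_index,
                   subject_meta = subject_meta)
  else
    read_marker_csv(file, protocol = protocol, trial_index = trial_index,
                    subject_meta = subject_meta)
  if (!is.null(mat_file))
    trial$mat <- read_gaitmat_export(mat_file, rate_hz = trial_rate(trial))
  trial
}

#' Run a batch analysis from a configuration
#'
#' @param cfg A configuration from [read_run_config()].
#' @return The combined [metric_table()] (also written to `cfg$output`
#'   when set), invisibly.
#' @export
run_pipeline <- function(cfg) {
  rows <- NULL
  for (sub in cfg$subjects) {
    for (tr in sub$trials) {
      trial <- load_trial_file(tr$file, tr$protocol %||% "fmap",
                               tr$trial_index %||% 1L,
                               mat_file = tr$mat)
      mt <- analyze_trial(trial, subject_id = sub$id,
                          group = sub$group %||% "control",
                          trial_index = tr$trial_index %||% 1L,
                          phase = tr$phase %||% NA_character_,
                          baseline_speed = cfg$baseline_speed_m_s)
      rows <- rbind(rows, as.data.frame(mt))
    }
  }
  tab <- metric_table(rows)
  if (!is.null(cfg$output)) write_metric_table(tab, cfg$output)
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
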