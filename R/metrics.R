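# Biomechanical metric set, computed per task segment.
#
# Conventions: angles in degrees with 0 = upright/neutral; joint flexion
# reported as 180 minus the inter-vector angle (larger value = deeper
# flexion); lengths in meters; COP in mm; derivatives always taken on
# low-passed signals (4th-order zero-lag Butterworth at 6 Hz) by central
# differences, so jerk-scale quantities are a declared function of that
# filter.

# Internal: angle (deg) between two sets of row vectors.
angle_between <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

#' Peak trunk inclination over a segment
#'
#' Angle between the trunk vector (pelvis midpoint to shoulder midpoint)
#' projected onto the AP-vertical (resp. ML-vertical) plane and the
#' vertical axis; 0 degrees = upright. Reports the peak magnitude over the
#' segment.
#'
#' @param seg A [task_segment()].
#' @param kin A [segment_kinematics()].
#' @return List with `peak_ap` and `peak_ml` (degrees).
#' @export
trunk_inclination <- function(seg, kin) {
  idx <- seg_idx(seg)
  if (any(kin$trunk_len[idx] < 0.05, na.rm = TRUE))
    stop("trunk vector degenerate (length < 5 cm); metric unavailable")
  list(peak_ap = max(abs(kin$incl_ap[idx])),
       peak_ml = max(abs(kin$incl_ml[idx])))
}

#' Trunk dynamics over a segment
#'
#' Velocity, acceleration and jerk of the shoulder-midpoint AP trajectory
#' by successive central differences of the 6 Hz low-passed position.
#'
#' @inheritParams trunk_inclination
#' @param point Which midpoint drives the dynamics: `"shoulder"` (trunk)
#'   or `"pelvis"`.
#' @return List with `peak_velocity_ap` (signed extremum, m/s),
#'   `rms_accel_ap` (m/s^2) and `mean_jerk` (signed mean, m/s^3).
#' @export
trunk_dynamics <- function(seg, kin, point = c("shoulder", "pelvis")) {
  point <- match.arg(point)
  rate <- kin$rate_hz
  if ((seg$end_frame - seg$start_frame) / rate < 0.3)
    stop("segment too short (< 0.3 s) for trunk dynamics")
  x <- if (point == "shoulder") kin$shoulder_mid[, 1] else kin$pelvis_mid[, 1]
  v <- deriv_central(lp_zerolag(x, rate), rate)
  a <- deriv_central(v, rate)
  j <- deriv_central(a, rate)
  idx <- seg_idx(seg)
  pv <- v[idx][which.max(abs(v[idx]))]
  list(peak_velocity_ap = pv,
       rms_accel_ap = sqrt(mean(a[idx]^2)),
       mean_jerk = mean(j[idx]))
}

#' Peak pelvis and knee flexion over a segment
#'
#' Pelvis flexion from the angle between the trunk-pelvis and trunk-knee
#' vectors; knee flexion from the angle between the knee-pelvis and
#' knee-heel vectors. Both are reported as 180 degrees minus the minimum
#' inter-vector angle, so a straight (collinear) limb scores 0 and deeper
#' bends score higher.
#'
#' @param seg A [task_segment()].
#' @param trial The [trial_recording()] (marker access).
#' @param kin A [segment_kinematics()].
#' @param side `"L"`, `"R"` or `"both"` (the deeper of the two).
#' @return List with `peak_pelvis_flexion` and `peak_knee_flexion` (deg).
#' @export
joint_flexion <- function(seg, trial, kin = segment_kinematics(trial),
                          side = "both") {
  idx <- seg_idx(seg)
  sides <- if (side == "both") c("L", "R") else side
  pel <- kin$pelvis_mid[idx, , drop = FALSE]
  tr <- kin$shoulder_mid[idx, , drop = FALSE]
  pf <- kf <- -Inf
  for (s in sides) {
    knee <- get_marker(trial, paste0(s, "KNE"), "joint flexion")$positions[idx, , drop = FALSE]
    heel <- get_marker(trial, paste0(s, "HEE"), "joint flexion")$positions[idx, , drop = FALSE]
    pelvis_angle <- angle_between(pel - tr, knee - tr)
    knee_angle <- angle_between(pel - knee, heel - knee)
    pf <- max(pf, 180 - min(pelvis_angle))
    kf <- max(kf, 180 - min(knee_angle))
  }
  list(peak_pelvis_flexion = pf, peak_knee_flexion = kf)
}

#' Segmental yaw profile of the turn
#'
#' Absolute (total sign-normalized excursion) and relative (pairwise
#' difference extremum, positive = leading segment ahead) yaw of head,
#' trunk and pelvis over the turn, plus the onset of each segment's
#' rotation expressed as a percentage of the first turn stride's duration
#' (may be negative when rotation starts before the stride).
#'
#' @param seg The turn [task_segment()].
#' @param kin A [segment_kinematics()].
#' @param events A [gait_events()].
#' @param onset_frac Fraction of the total excursion defining rotation
#'   onset (default 0.05).
#' @return List with `abs_yaw`, `rel_yaw`, `onset_pct` (named vectors).
#' @export
yaw_turning_profile <- function(seg, kin, events, onset_frac = 0.05) {
  idx <- seg_idx(seg)
  segments <- c("head", "trunk", "pelvis")
  yaw <- kin$yaw[, segments, drop = FALSE]
  # reference: yaw just before the turn
  ref <- yaw[max(1, seg$start_frame - 9):(seg$start_frame + 1), , drop = FALSE]
  y0 <- apply(ref, 2, stats::median)
  exc <- sweep(yaw, 2, y0)
  abs_yaw <- apply(exc[idx, , drop = FALSE], 2, function(v) max(abs(v)))
  pair <- function(a, b) {
    d <- exc[idx, a] - exc[idx, b]
    d[which.max(abs(d))]
  }
  rel_yaw <- c("head_trunk" = pair("head", "trunk"),
               "trunk_pelvis" = pair("trunk", "pelvis"),
               "head_pelvis" = pair("head", "pelvis"))
  # first turn stride: first stride whose start lies in the turn window
  st <- events$strides
  st <- st[st$start_hs >= seg$start_frame - 25 & st$start_hs < seg$end_frame, , drop = FALSE]
  onset_pct <- c(head = NA_real_, trunk = NA_real_, pelvis = NA_real_)
  if (nrow(st)) {
    s1 <- st[which.min(st$start_hs), ]
    dur <- s1$end_hs - s1$start_hs
    for (sgm in segments) {
      thr <- onset_frac * abs_yaw[[sgm]]
      hit <- which(abs(exc[, sgm]) > thr & seq_len(nrow(exc)) >= seg$start_frame - 50)
      if (length(hit))
        onset_pct[[sgm]] <- 100 * (hit[1] - 1 - s1$start_hs) / dur
    }
  }
  list(abs_yaw = abs_yaw, rel_yaw = rel_yaw, onset_pct = onset_pct)
}

#' Foot-to-ground angles and minimum foot clearance
#'
#' Toe-off angle: peak heel-to-ground elevation of the heel-toe line over
#' the push-off window (heel raised). Heel-strike angle: peak toe
#' elevation over the landing window (toe raised). Minimum foot clearance:
#' smallest toe height above the ground plane during mid-swing. The ground
#' plane is the 5th percentile of foot-marker height over the trial.
#'
#' @param trial A [trial_recording()].
#' @param events A [gait_events()].
#' @param seg Optional [task_segment()] restricting the strides used.
#' @param window_s Half-window (s) around each event for the angle search.
#' @return List with per-foot means `to_angle`, `hs_angle` (deg) and
#'   `min_foot_clearance` (m), plus per-event values in `detail`.
#' @export
foot_angles <- function(trial, events, seg = NULL, window_s = 0.15) {
  rate <- trial_rate(trial)
  w <- round(window_s * rate)
  n <- n_frames(trial)
  inwin <- function(fr) is.null(seg) || (fr >= seg$start_frame && fr < seg$end_frame)
  det <- NULL
  for (side in c("L", "R")) {
    heel <- get_marker(trial, paste0(side, "HEE"), "foot angles")$positions
    toe <- get_marker(trial, paste0(side, "TOE"), "foot angles")$positions
    ground <- stats::quantile(c(heel[, 3], toe[, 3]), 0.05, names = FALSE)
    hz <- heel[, 3] - ground
    tz <- toe[, 3] - ground
    flen <- stats::median(sqrt(rowSums((toe - heel)^2)))
    elev <- asin(pmin(1, pmax(-1, (hz - tz) / flen))) * 180 / pi  # + = heel up
    ev <- events[[side]]
    for (tf in ev$to) {
      if (!inwin(tf)) next
      i <- max(1, tf + 1 - w):min(n, tf + 1 + round(w / 3))
      det <- rbind(det, data.frame(foot = side, event = "TO", frame = tf,
                                   angle = max(elev[i]), clearance = NA_real_))
    }
    for (hf in ev$hs) {
      if (!inwin(hf)) next
      i <- max(1, hf + 1 - round(w / 3)):min(n, hf + 1 + w)
      det <- rbind(det, data.frame(foot = side, event = "HS", frame = hf,
                                   angle = max(-elev[i]), clearance = NA_real_))
    }
    # swing windows: toe off to next ipsilateral heel strike
    for (tf in ev$to) {
      nxt <- ev$hs[ev$hs > tf]
      if (!length(nxt) || !inwin(tf)) next
      hf <- nxt[1]
      span <- hf - tf
      if (span < 4) next
      mid <- (tf + round(0.25 * span)):(tf + round(0.75 * span)) + 1L
      det <- rbind(det, data.frame(foot = side, event = "swing", frame = tf,
                                   angle = NA_real_, clearance = min(tz[mid])))
    }
  }
  if (is.null(det))
    return(list(to_angle = NA_real_, hs_angle = NA_real_,
                min_foot_clearance = NA_real_, detail = NULL))
  list(to_angle = mean(det$angle[det$event == "TO"]),
       hs_angle = mean(det$angle[det$event == "HS"]),
       min_foot_clearance = if (any(det$event == "swing"))
         mean(det$clearance[det$event == "swing"]) else NA_real_,
       detail = det)
}

#' Spatiotemporal gait parameters
#'
#' Stride length (AP distance between successive ipsilateral heel
#' strikes), stride width (ML distance between opposite-foot heel
#' positions at strike), stride time, stride velocity, double-support
#' percentage of the gait cycle, plus per-parameter asymmetry
#' (|L-R| / mean x 100) and variability (coefficient of variation, %).
#'
#' @param events A [gait_events()].
#' @param trial A [trial_recording()].
#' @param seg Optional [task_segment()]: only strides fully inside it are
#'   used (double-support pairing still sees all events).
#' @param min_strides Minimum number of strides required (default 3).
#'   Callers pooling several walking windows may lower this and summarize
#'   the pooled `detail` themselves.
#' @return List of means (`stride_length_m`, `stride_width_m`,
#'   `stride_time_s`, `stride_velocity_m_s`, `double_support_pct`),
#'   `asymmetry_pct` and `variability_pct` named vectors, and `detail`.
#' @export
spatiotemporal_gait <- function(events, trial, seg = NULL, min_strides = 3) {
  rate <- trial_rate(trial)
  strides <- events$strides
  if (!is.null(seg))
    strides <- strides[strides$start_hs >= seg$start_frame &
                       strides$end_hs <= seg$end_frame, , drop = FALSE]
  if (nrow(strides) < min_strides)
    stop("need at least ", min_strides, " strides")
  per_foot <- list()
  for (side in c("L", "R")) {
    heel <- get_marker(trial, paste0(side, "HEE"), "gait parameters")$positions
    st <- strides[strides$foot == side, , drop = FALSE]
    if (!nrow(st)) next
    len <- abs(heel[st$end_hs + 1L, 1] - heel[st$start_hs + 1L, 1])
    tim <- (st$end_hs - st$start_hs) / rate
    oheel <- get_marker(trial, paste0(setdiff(c("L", "R"), side), "HEE"),
                        "gait parameters")$positions
    oev <- events[[setdiff(c("L", "R"), side)]]
    wid <- vapply(seq_len(nrow(st)), function(i) {
      ohs <- oev$hs[oev$hs > st$start_hs[i] & oev$hs < st$end_hs[i]]
      if (!length(ohs)) return(NA_real_)
      abs(oheel[ohs[1] + 1L, 2] - heel[st$start_hs[i] + 1L, 2])
    }, numeric(1))
    # double support: from this foot's HS to the opposite foot's TO, twice
    # per cycle, as a % of stride time
    ds <- vapply(seq_len(nrow(st)), function(i) {
      oto <- oev$to[oev$to >= st$start_hs[i] & oev$to < st$end_hs[i]]
      ito <- st$to_frame[i]
      ohs <- oev$hs[oev$hs > st$start_hs[i] & oev$hs < st$end_hs[i]]
      if (!length(oto) || !length(ohs)) return(NA_real_)
      ds1 <- oto[1] - st$start_hs[i]
      ds2 <- ito - ohs[1]
      100 * (ds1 + ds2) / (st$end_hs[i] - st$start_hs[i])
    }, numeric(1))
    per_foot[[side]] <- data.frame(foot = side, length = len, time = tim,
                                   velocity = len / tim, width = wid,
                                   double_support = ds)
  }
  d <- do.call(rbind, per_foot)
  summarize_stride_detail(d)
}

# Internal: summary statistics over a per-stride detail frame (columns
# foot/length/time/velocity/width/double_support).
summarize_stride_detail <- function(d) {
  pars <- c("length", "time", "velocity", "width", "double_support")
  m <- vapply(pars, function(p) mean(d[[p]], na.rm = TRUE), numeric(1))
  asym <- vapply(pars, function(p) {
    l <- mean(d[[p]][d$foot == "L"], na.rm = TRUE)
    r <- mean(d[[p]][d$foot == "R"], na.rm = TRUE)
    if (!is.finite(l) || !is.finite(r) || (l + r) == 0) return(NA_real_)
    100 * abs(l - r) / (0.5 * (l + r))
  }, numeric(1))
  cv <- vapply(pars, function(p) {
    v <- d[[p]][is.finite(d[[p]])]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  }, numeric(1))
  list(stride_length_m = m[["length"]], stride_time_s = m[["time"]],
       stride_velocity_m_s = m[["velocity"]], stride_width_m = m[["width"]],
       double_support_pct = m[["double_support"]],
       asymmetry_pct = asym, variability_pct = cv, detail = d)
}

#' Arm-swing asymmetry index
#'
#' The symmetry-angle form: `|45 - atan(nondominant/dominant)| / 90 x 100`,
#' with the dominant arm defined as the one with the larger absolute total
#' swing. 0% at perfect symmetry (ratio 1), 100% at equal-and-opposite
#' swing (ratio -1). The literal difference form (arctangent of the
#' difference of the two swings) is available behind `form =
#' "difference"` for comparison.
#'
#' @param swing_a,swing_b Signed total arm-swing values (degrees), in any
#'   order.
#' @param form `"ratio"` (default) or `"difference"`.
#' @return ASA in percent (0-100 for the ratio form).
#' @export
asa <- function(swing_a, swing_b, form = c("ratio", "difference")) {
  form <- match.arg(form)
  if (abs(swing_a) >= abs(swing_b)) {
    dom <- swing_a; nond <- swing_b
  } else {
    dom <- swing_b; nond <- swing_a
  }
  if (dom == 0) stop("ASA undefined: zero dominant swing")
  if (form == "ratio") {
    abs(45 - atan(nond / dom) * 180 / pi) / 90 * 100
  } else {
    abs(45 - atan(dom - nond) * 180 / pi) / 90 * 100
  }
}

#' Arm-swing summary over a locomotion segment
#'
#' Sagittal-plane angle of each arm (shoulder-to-wrist vector, referenced
#' to the pelvis midpoint frame) relative to vertical; total swing is the
#' per-stride peak-to-peak range averaged over strides, signed positive
#' when the arm swings in normal anti-phase with its ipsilateral leg and
#' negative when in phase. Includes mean absolute angular speeds of the
#' shoulder-elbow, elbow-wrist and shoulder-wrist segments and the ASA.
#'
#' @param seg A locomotion [task_segment()].
#' @param trial The [trial_recording()].
#' @param kin A [segment_kinematics()].
#' @param events A [gait_events()].
#' @return List with `total_swing_dominant`, `total_swing_nondominant`
#'   (signed degrees), `asa_percent`, and `segment_velocities` (deg/s).
#' @export
arm_swing <- function(seg, trial, kin = segment_kinematics(trial), events) {
  rate <- trial_rate(trial)
  idx <- seg_idx(seg)
  if (nrow(events$strides) < 3) stop("need at least 3 strides for arm swing")
  sag_angle <- function(prox, dist) {
    # sagittal plane of the walking body: AP-vertical, pelvis-referenced
    v <- dist - prox
    atan2(v[, 1] * sign_dir, -v[, 3]) * 180 / pi
  }
  pm_v <- deriv_central(lp_zerolag(kin$pelvis_mid[, 1], rate), rate)
  sign_dir <- sign(stats::median(pm_v[idx]))
  if (sign_dir == 0) sign_dir <- 1
  out <- list()
  vels <- c()
  for (side in c("L", "R")) {
    sho <- get_marker(trial, paste0(side, "SHO"), "arm swing")$positions
    elb <- get_marker(trial, paste0(side, "ELB"), "arm swing")$positions
    wri <- get_marker(trial, paste0(side, "WRA"), "arm swing")$positions
    phi <- sag_angle(sho, wri)
    # per-stride peak-to-peak range, averaged over ipsilateral strides in
    # the segment
    st <- events$strides[events$strides$foot == side, , drop = FALSE]
    st <- st[st$start_hs >= seg$start_frame & st$end_hs < seg$end_frame, , drop = FALSE]
    rng <- vapply(seq_len(nrow(st)), function(i) {
      j <- (st$start_hs[i] + 1L):(st$end_hs[i] + 1L)
      diff(range(phi[j]))
    }, numeric(1))
    total <- if (length(rng)) mean(rng) else diff(range(phi[idx]))
    # sign: anti-phase with the ipsilateral leg (normal) = positive
    heel <- get_marker(trial, paste0(side, "HEE"), "arm swing")$positions
    leg <- (heel[idx, 1] - kin$pelvis_mid[idx, 1]) * sign_dir
    rho <- suppressWarnings(stats::cor(phi[idx], leg))
    if (is.finite(rho) && rho > 0) total <- -total
    out[[side]] <- total
    for (pair in list(c("sho", "elb"), c("elb", "wri"), c("sho", "wri"))) {
      a <- switch(pair[1], sho = sho, elb = elb)
      b <- switch(pair[2], elb = elb, wri = wri)
      ang <- sag_angle(a, b)
      vels[paste(side, pair[1], pair[2], sep = "_")] <-
        mean(abs(deriv_central(lp_zerolag(ang, rate), rate))[idx])
    }
  }
  dom_side <- if (abs(out$L) >= abs(out$R)) "L" else "R"
  dom <- out[[dom_side]]; nond <- out[[setdiff(c("L", "R"), dom_side)]]
  list(total_swing_dominant = dom, total_swing_nondominant = nond,
       dominant_side = dom_side,
       asa_percent = asa(dom, nond),
       segment_velocities = vels)
}

#' Stance geometry during the reach
#'
#' AP foot distance (toe markers, sagittal plane), maximum stance width
#' (largest horizontal distance between the two foot segments), feet
#' aperture angle (between the two toe-to-heel vectors in the transverse
#' plane) and the alignment angle of the dominant shoulder-to-wrist vector
#' with the sagittal plane (0 = reaching straight ahead, 90 = fully
#' lateral).
#'
#' @param seg The reach [task_segment()].
#' @param trial A [trial_recording()].
#' @return List with `ap_foot_distance_m`, `max_stance_width_m`,
#'   `aperture_angle_deg`, `max_to_angle_deg`, `arm_alignment_angle_deg`.
#' @export
stance_geometry <- function(seg, trial) {
  idx <- seg_idx(seg)
  lh <- get_marker(trial, "LHEE", "stance geometry")$positions[idx, , drop = FALSE]
  rh <- get_marker(trial, "RHEE", "stance geometry")$positions[idx, , drop = FALSE]
  lt <- get_marker(trial, "LTOE", "stance geometry")$positions[idx, , drop = FALSE]
  rt <- get_marker(trial, "RTOE", "stance geometry")$positions[idx, , drop = FALSE]
  ap_dist <- mean(abs(lt[, 1] - rt[, 1]))
  # largest horizontal distance between any pairing of the foot endpoints
  horiz <- function(a, b) sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  width <- max(horiz(lh, rh), horiz(lt, rt), horiz(lh, rt), horiz(lt, rh))
  # aperture between toe->heel vectors in the transverse plane
  vl <- (lh - lt)[, 1:2, drop = FALSE]
  vr <- (rh - rt)[, 1:2, drop = FALSE]
  aperture <- mean(angle_between(cbind(vl, 0), cbind(vr, 0)))
  # foot elevation angle during the reach (push-off style)
  flen <- stats::median(sqrt(rowSums((lt - lh)^2)))
  elevL <- asin(pmin(1, pmax(-1, (lh[, 3] - lt[, 3]) / flen))) * 180 / pi
  elevR <- asin(pmin(1, pmax(-1, (rh[, 3] - rt[, 3]) / flen))) * 180 / pi
  max_to <- max(elevL, elevR)
  wname <- if (identical(trial$subject_meta$dominant_hand, "L")) c("LSHO", "LWRA")
           else c("RSHO", "RWRA")
  sho <- get_marker(trial, wname[1], "stance geometry")$positions[idx, , drop = FALSE]
  wri <- get_marker(trial, wname[2], "stance geometry")$positions[idx, , drop = FALSE]
  v <- wri - sho
  # angle with the sagittal (AP-vertical) plane = elevation toward ML
  align <- asin(pmin(1, pmax(-1, abs(v[, 2]) / sqrt(rowSums(v^2))))) * 180 / pi
  # evaluate at the wrist minimum (deepest reach)
  at <- which.min(wri[, 3])
  list(ap_foot_distance_m = ap_dist, max_stance_width_m = width,
       aperture_angle_deg = aperture, max_to_angle_deg = max_to,
       arm_alignment_angle_deg = align[at])
}

#' COP displacement over a segment
#'
#' Displacement relative to the COP at segment start, sign-normalized for
#' turn direction; reports the signed mean over the segment and, for
#' standing, also the sway range and RMS per axis.
#'
#' @param seg A [task_segment()].
#' @param mat A (filtered) [mat_recording()].
#' @param trial The [trial_recording()] (for the turn-direction sign).
#' @param standing If `TRUE`, adds sway range and RMS.
#' @return List with `mean_ap_mm`, `mean_ml_mm` and, for standing,
#'   `range_ap_mm`, `range_ml_mm`, `rms_ap_mm`, `rms_ml_mm`.
#' @export
cop_displacement <- function(seg, mat, trial, standing = FALSE) {
  if (is.null(mat)) stop("COP unavailable: no mat recording")
  idx <- seg_idx(seg)
  idx <- idx[idx <= nrow(mat$cop)]
  if (!length(idx)) stop("segment beyond COP trace")
  s <- turn_sign(trial)
  disp <- sweep(mat$cop[idx, , drop = FALSE], 2, mat$cop[idx[1], ])
  disp[, 2] <- s * disp[, 2]
  out <- list(mean_ap_mm = mean(disp[, 1]), mean_ml_mm = mean(disp[, 2]))
  if (standing) {
    out$range_ap_mm <- diff(range(disp[, 1]))
    out$range_ml_mm <- diff(range(disp[, 2]))
    out$rms_ap_mm <- sqrt(mean((disp[, 1] - mean(disp[, 1]))^2))
    out$rms_ml_mm <- sqrt(mean((disp[, 2] - mean(disp[, 2]))^2))
  }
  out
}

#' Upper-body lateral tilt during standing
#'
#' Frontal-plane angle between the inter-shoulder line and the
#' inter-ASIS (pelvis) line.
#'
#' @param seg The standing [task_segment()].
#' @param trial A [trial_recording()].
#' @return List with `mean_deg` and `max_deg`.
#' @export
lateral_tilt <- function(seg, trial) {
  idx <- seg_idx(seg)
  ls <- get_marker(trial, "LSHO", "lateral tilt")$positions[idx, , drop = FALSE]
  rs <- get_marker(trial, "RSHO", "lateral tilt")$positions[idx, , drop = FALSE]
  la <- get_marker(trial, "LASI", "lateral tilt")$positions[idx, , drop = FALSE]
  ra <- get_marker(trial, "RASI", "lateral tilt")$positions[idx, , drop = FALSE]
  # frontal plane: ML-vertical components
  sho <- (ls - rs)[, c(2, 3), drop = FALSE]
  pel <- (la - ra)[, c(2, 3), drop = FALSE]
  ang <- abs(atan2(sho[, 2], sho[, 1]) - atan2(pel[, 2], pel[, 1])) * 180 / pi
  ang <- pmin(ang, 360 - ang)
  list(mean_deg = mean(ang), max_deg = max(ang))
}
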