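# Synthetic trial generator: a phase-composed kinematic avatar executing
# the instrumented mobility protocols, emitting marker trajectories and a
# pressure-mat stream together with the scripted ground truth (segment
# boundaries, footfall events, parameter values, freezing episodes).
#
# Design notes (all deliberate, see the vignette):
# - Foot contacts are scripted first (a step schedule); heel/toe marker
#   trajectories and mat footfalls are synthesized from that schedule, so
#   the emitted footfall frames ARE the ground-truth events.
# - Angle profiles use raised-cosine interpolation with short plateaus at
#   their extrema so that the fixed 15-sample despike average does not
#   bias recovered peak values.
# - Freezing-like episodes are produced by time-warping the nominal
#   timeline: during a freeze, nominal time advances at 2% speed, so every
#   body channel slows together, exactly like a whole-body halt.

# ---- small interpolation helpers -------------------------------------------

cos_step <- function(u) (1 - cos(pi * pmin(1, pmax(0, u)))) / 2

# Piecewise raised-cosine interpolation through keyframes (clamped).
cos_interp <- function(u, ku, kv) {
  i <- findInterval(u, ku, all.inside = TRUE)
  w <- pmin(1, pmax(0, (u - ku[i]) / (ku[i + 1] - ku[i])))
  kv[i] + (kv[i + 1] - kv[i]) * (1 - cos(pi * w)) / 2
}

wrap180 <- function(d) ((d + 180) %% 360) - 180

# ---- parameters -------------------------------------------------------------

#' Avatar parameters for the trial simulator
#'
#' All scripted quantities of the synthetic subject. Defaults describe an
#' unimpaired adult; pathology is expressed by overriding them (smaller
#' stride, asymmetric arm swing, freezing script, ...).
#'
#' @param stature Body height, m.
#' @param seat_height_m Pelvis height when seated, m.
#' @param stride_length_m,cadence_spm,stride_width_m Gait descriptors
#'   (cadence in steps/min).
#' @param double_support_pct Double support per gait cycle, percent.
#' @param arm_swing_deg Named vector `c(L=,R=)`: sagittal arm-swing
#'   amplitude half-range in degrees (total swing = 2x this value).
#' @param arm_phase_deg Named vector `c(L=,R=)`: phase of the arm relative
#'   to the ipsilateral leg; 180 = normal anti-phase, 0 = in-phase.
#' @param arm_length_m Shoulder-to-wrist length, m.
#' @param trunk_bend_deg Peak trunk inclination during chair transfers, deg.
#' @param reach_bend_deg Trunk inclination while picking the key, deg.
#' @param to_angle_deg,hs_angle_deg Foot-to-ground angles at toe off and
#'   heel strike, deg.
#' @param min_clearance_m Minimum toe clearance at mid-swing, m.
#' @param foot_length_m Heel-to-toe marker distance, m.
#' @param turn_duration_s Duration of the 180-degree turn, s.
#' @param turn_direction `"CCW"` or `"CW"`.
#' @param head_lead_s,trunk_lead_s Time by which head/trunk rotation leads
#'   the pelvis during the turn, s.
#' @param walkway_m Chair-to-turn-point distance, m.
#' @param key_ap_m AP position of the key on the return path, m.
#' @param doorway_ap_m AP position of the doorframe, m.
#' @param locomotion_distance_m Straight-walk distance for the locomotion
#'   protocol, m.
#' @param rate_hz Sampling rate.
#' @param noise_mm Marker noise SD, mm. @param cop_noise_mm COP noise SD, mm.
#' @param fle_script `NULL` or a data frame with `bout`
#'   (`"walk_out"`/`"walk_back"`/`"lap"`), `at_frac` (0.1-0.8 position
#'   along the bout) and `duration_s`: scripted freezing-like episodes.
#' @param gap_script `NULL` or data frame `marker`, `start_frame`, `length`:
#'   occlusions to inject.
#' @param spike_script `NULL` or data frame `marker`, `frame`,
#'   `magnitude_m`: single-frame spikes to inject.
#' @param dominant_hand `"L"` or `"R"`.
#' @param subject_meta Extra metadata merged into the trial.
#' @param seed Optional RNG seed for the noise.
#' @return List of class `avatar_params`.
#' @export
avatar_params <- function(stature = 1.72, seat_height_m = 0.50,
                          stride_length_m = 1.25, cadence_spm = 110,
                          stride_width_m = 0.10, double_support_pct = 20,
                          arm_swing_deg = c(L = 15, R = 15),
                          arm_phase_deg = c(L = 180, R = 180),
                          arm_length_m = 0.55,
                          trunk_bend_deg = 35, reach_bend_deg = 40,
                          to_angle_deg = 20, hs_angle_deg = 15,
                          min_clearance_m = 0.015, foot_length_m = 0.25,
                          turn_duration_s = 2, turn_direction = "CCW",
                          head_lead_s = 0.15, trunk_lead_s = 0.07,
                          walkway_m = 3, key_ap_m = 2.25, doorway_ap_m = 1.5,
                          locomotion_distance_m = 6,
                          rate_hz = 100, noise_mm = 1, cop_noise_mm = 2,
                          fle_script = NULL, gap_script = NULL,
                          spike_script = NULL, dominant_hand = "R",
                          subject_meta = list(), seed = NULL) {
  if (stride_length_m <= 0 || cadence_spm <= 0) stop("gait parameters must be > 0")
  if (double_support_pct <= 0 || double_support_pct >= 50)
    stop("double_support_pct must be in (0, 50)")
  if (!turn_direction %in% c("CCW", "CW")) stop("turn_direction must be CCW or CW")
  p <- as.list(environment())
  class(p) <- "avatar_params"
  p
}

# ---- time warp (freezing) ---------------------------------------------------

# freezes: data.frame(t_nominal, duration_s); eps = residual speed fraction.
build_warp <- function(freezes, eps = 0.02) {
  if (is.null(freezes) || !nrow(freezes)) {
    id <- function(t) t
    return(list(tau_of_t = id, t_of_tau = id, events = NULL))
  }
  freezes <- freezes[order(freezes$t_nominal), , drop = FALSE]
  rk <- 0; nk <- 0; r <- 0; n <- 0
  ev <- NULL
  for (i in seq_len(nrow(freezes))) {
    tn <- freezes$t_nominal[i]; d <- freezes$duration_s[i]
    if (tn <= n) stop("freeze script entries overlap")
    r <- r + (tn - n); n <- tn
    rk <- c(rk, r); nk <- c(nk, n)
    ev <- rbind(ev, data.frame(t_real = r, duration_s = d, t_nominal = tn))
    r <- r + d; n <- n + eps * d
    rk <- c(rk, r); nk <- c(nk, n)
  }
  rk <- c(rk, r + 1e4); nk <- c(nk, n + 1e4)
  list(tau_of_t = stats::approxfun(rk, nk, rule = 2),
       t_of_tau = stats::approxfun(nk, rk, rule = 2),
       events = ev)
}

# ---- foot trajectory from a step schedule -----------------------------------

# st: data.frame(t_hs, x, y, heading) for ONE foot, ordered; row 1 is the
# initial stance (covers the trial start). Returns heel/toe T x 3.
foot_traj <- function(tau, st, sw, fl, to_ang, hs_ang, mfc,
                      ramp = 0.2, hold = 0.08) {
  rad <- pi / 180
  n <- length(tau)
  heel <- matrix(0, n, 3); toe <- matrix(0, n, 3)
  K <- nrow(st)
  fvec <- function(h) c(cos(h * rad), sin(h * rad))
  zmid <- max(0.06, fl * sin(hs_ang * rad) + 0.01)
  for (k in seq_len(K)) {
    hs_t <- st$t_hs[k]
    to_t <- if (k < K) st$t_hs[k + 1] - sw else Inf
    f <- fvec(st$heading[k])
    heel_home <- c(st$x[k], st$y[k])
    toe_home <- heel_home + fl * f
    lo <- if (k == 1) -Inf else hs_t
    i <- which(tau >= lo & tau < to_t)
    if (length(i)) {
      ti <- tau[i]
      th <- numeric(length(i))
      if (k > 1) {          # landing: flatten from -hs_ang
        u <- (ti - hs_t - hold) / ramp
        th <- th - hs_ang * (1 - cos_step(u))
      }
      if (k < K) {          # departure: pitch up to +to_ang
        u <- (ti - (to_t - hold - ramp)) / ramp
        th <- th + to_ang * cos_step(u)
      }
      up <- th >= 0
      # toe-anchored when pitched up, heel-anchored otherwise
      heel[i, 1] <- ifelse(up, toe_home[1] - fl * cos(th * rad) * f[1], heel_home[1])
      heel[i, 2] <- ifelse(up, toe_home[2] - fl * cos(th * rad) * f[2], heel_home[2])
      heel[i, 3] <- ifelse(up, fl * sin(th * rad), 0)
      toe[i, 1] <- ifelse(up, toe_home[1], heel_home[1] + fl * cos(th * rad) * f[1])
      toe[i, 2] <- ifelse(up, toe_home[2], heel_home[2] + fl * cos(th * rad) * f[2])
      toe[i, 3] <- ifelse(up, 0, -fl * sin(th * rad))
    }
    if (k > 1) {            # swing into this placement
      i <- which(tau >= hs_t - sw & tau < hs_t)
      if (length(i)) {
        u <- (tau[i] - (hs_t - sw)) / sw
        h_prev <- st$heading[k - 1]
        h_u <- h_prev + cos_step(u) * wrap180(st$heading[k] - h_prev)
        f_prev <- fvec(h_prev)
        toe_from <- c(st$x[k - 1], st$y[k - 1]) + fl * f_prev
        toe_to <- heel_home + fl * cos(hs_ang * rad) * f
        cs <- cos_step(u)
        tx <- toe_from[1] + cs * (toe_to[1] - toe_from[1])
        ty <- toe_from[2] + cs * (toe_to[2] - toe_from[2])
        th <- cos_interp(u, c(0, 0.2, 0.45, 0.7, 0.8, 1),
                         c(to_ang, to_ang, 0, 0, -hs_ang, -hs_ang))
        tz <- cos_interp(u, c(0, 0.2, 0.3, 0.7, 0.8, 1),
                         c(0, zmid, mfc, mfc, zmid, fl * sin(hs_ang * rad)))
        toe[i, 1] <- tx; toe[i, 2] <- ty; toe[i, 3] <- tz
        heel[i, 1] <- tx - fl * cos(th * rad) * cos(h_u * rad)
        heel[i, 2] <- ty - fl * cos(th * rad) * sin(h_u * rad)
        heel[i, 3] <- tz + fl * sin(th * rad)
      }
    }
  }
  list(heel = heel, toe = toe)
}

# ---- step schedule builders -------------------------------------------------

other_foot <- function(f) if (f == "L") "R" else "L"

# Straight walking bout along heading `dir_h` from (x0, 0), distance D.
# Returns the appended step rows (tagged with `bout`) and the arrival time
# (the last closing step's heel strike).
walk_steps <- function(t0, x0, dir_h, D, lead, p, v, Tst, sw, bout) {
  rad <- pi / 180
  f <- c(cos(dir_h * rad), sin(dir_h * rad))
  l <- c(-f[2], f[1])
  step_len <- p$stride_length_m / 2
  step_t <- Tst / 2
  rows <- NULL
  foot <- lead
  t <- t0 + sw
  along <- v * sw + step_len / 2
  place <- function(foot, along, t) {
    off <- (if (foot == "L") 1 else -1) * p$stride_width_m / 2
    data.frame(foot = foot, t_hs = t,
               x = x0 + f[1] * along + l[1] * off,
               y = f[2] * along + l[2] * off,
               heading = dir_h, bout = bout, stringsAsFactors = FALSE)
  }
  while (along < D - 0.45) {
    rows <- rbind(rows, place(foot, along, t))
    along <- along + step_len; t <- t + step_t; foot <- other_foot(foot)
  }
  for (a in c(D - 0.20, D - 0.06)) {        # closing pair
    rows <- rbind(rows, place(foot, a, t))
    t <- t + step_t; foot <- other_foot(foot)
  }
  list(rows = rows, t_arr = max(rows$t_hs), next_lead = foot)
}

foot_home <- function(center_xy, heading, foot, p) {
  rad <- pi / 180
  f <- c(cos(heading * rad), sin(heading * rad))
  l <- c(-f[2], f[1])
  off <- (if (foot == "L") 1 else -1) * p$stride_width_m / 2
  center_xy - 0.10 * f + off * l
}

# ---- ground truth helpers ---------------------------------------------------

# Definitional gait statistics straight from the emitted footfall schedule
# (frames + heel placements): the forward-model truth for what the
# pipeline should recover.
gait_truth_from_schedule <- function(ff, rate, windows = NULL) {
  inwin <- function(hs0, hs1) {
    if (is.null(windows)) return(TRUE)
    any(vapply(windows, function(w) hs0 >= w[1] && hs1 <= w[2], logical(1)))
  }
  out <- NULL
  for (side in c("L", "R")) {
    f <- ff[ff$foot == side, , drop = FALSE]
    o <- ff[ff$foot != side, , drop = FALSE]
    if (nrow(f) < 2) next
    for (i in seq_len(nrow(f) - 1)) {
      hs0 <- f$on_frame[i]; hs1 <- f$on_frame[i + 1]; ito <- f$off_frame[i]
      if (!(ito > hs0 && ito < hs1)) next
      if (!inwin(hs0, hs1)) next
      ohs <- o$on_frame[o$on_frame > hs0 & o$on_frame < hs1]
      oto <- o$off_frame[o$off_frame >= hs0 & o$off_frame < hs1]
      len <- abs(f$x[i + 1] - f$x[i]); tim <- (hs1 - hs0) / rate
      wid <- if (length(ohs)) abs(o$y[match(ohs[1], o$on_frame)] - f$y[i]) else NA_real_
      ds <- if (length(oto) && length(ohs))
        100 * ((oto[1] - hs0) + (ito - ohs[1])) / (hs1 - hs0) else NA_real_
      out <- rbind(out, data.frame(foot = side, length = len, time = tim,
                                   velocity = len / tim, width = wid,
                                   double_support = ds))
    }
  }
  if (is.null(out)) return(NULL)
  list(stride_length_m = mean(out$length), stride_time_s = mean(out$time),
       stride_velocity_m_s = mean(out$velocity),
       stride_width_m = mean(out$width, na.rm = TRUE),
       double_support_pct = mean(out$double_support, na.rm = TRUE),
       detail = out)
}

# ---- the simulator ----------------------------------------------------------

#' Simulate one instrumented trial with ground truth
#'
#' Composes the avatar through the protocol's phases and renders the
#' 20-marker set plus the pressure-mat stream. Returns the trial together
#' with the scripted truth: segment boundaries, footfall events, gait
#' statistics derived from the emitted schedule, scripted parameter values
#' and freezing episodes.
#'
#' @param p An [avatar_params()].
#' @param protocol `"fmap"`, `"tug"`, `"standing"` or `"locomotion"`.
#' @return List with `trial` (a [trial_recording()]), `truth` and `params`.
#' @export
simulate_trial <- function(p, protocol = c("fmap", "tug", "standing", "locomotion")) {
  protocol <- match.arg(protocol)
  if (!is.null(p$seed)) set.seed(p$seed)
  rate <- p$rate_hz
  rad <- pi / 180
  Tst <- 120 / p$cadence_spm
  v <- p$stride_length_m / Tst
  s_frac <- 0.5 + p$double_support_pct / 200
  sw <- (1 - s_frac) * Tst
  sgn <- if (identical(p$turn_direction, "CW")) -1 else 1
  stand_z <- 0.55 * p$stature
  trunk_len <- 0.27 * p$stature
  xs <- 0.30

  steps <- NULL
  bouts <- list()
  x_keys_t <- NULL; x_keys_v <- NULL
  z_keys_t <- c(0); z_keys_v <- c(stand_z)
  b_keys_t <- c(0); b_keys_v <- c(0)
  heading_fun <- function(tau) rep(0, length(tau))
  reach <- NULL
  gt_seg <- NULL
  freezes <- NULL
  walk_bend <- 8

  init_stance <- function(center_x, heading = 0) {
    rbind(
      data.frame(foot = "L", t_hs = 0, x = center_x - 0.10,
                 y = p$stride_width_m / 2, heading = heading, bout = "init",
                 stringsAsFactors = FALSE),
      data.frame(foot = "R", t_hs = 0, x = center_x - 0.10,
                 y = -p$stride_width_m / 2, heading = heading, bout = "init",
                 stringsAsFactors = FALSE))
  }

  if (protocol %in% c("fmap", "tug")) {
    t_sit <- 1.0; sts_dur <- 1.5
    t_walk0 <- t_sit + sts_dur
    XT <- p$walkway_m
    steps <- init_stance(xs)
    w1 <- walk_steps(t_walk0, xs, 0, XT - xs, "R", p, v, Tst, sw, "walk_out")
    steps <- rbind(steps, w1$rows)
    t_out_arr <- w1$t_arr
    t_turn0 <- t_out_arr + 0.15
    dur <- p$turn_duration_s
    t_turn1 <- t_turn0 + dur
    # the inside foot of the turn (left when counterclockwise, right when
    # clockwise) steps first; the outside foot closes the turn
    inside <- if (sgn > 0) "L" else "R"
    outside <- other_foot(inside)
    tI_to <- t_turn0 + 0.05 * dur
    tI_hs <- tI_to + sw
    tO_hs <- t_turn0 + max(0.55 * dur + sw, 0.78 * dur)
    pI <- foot_home(c(XT, 0), sgn * 100, inside, p)
    pO <- foot_home(c(XT, 0), sgn * 180, outside, p)
    steps <- rbind(steps,
      data.frame(foot = inside, t_hs = tI_hs, x = pI[1], y = pI[2],
                 heading = sgn * 100, bout = "turn", stringsAsFactors = FALSE),
      data.frame(foot = outside, t_hs = tO_hs, x = pO[1], y = pO[2],
                 heading = sgn * 180, bout = "turn", stringsAsFactors = FALSE))
    tm <- t_turn0 + dur / 2; kk <- 12 / dur
    heading_fun <- function(tau) sgn * 180 * stats::plogis(kk * (tau - tm))
    if (protocol == "fmap") {
      a1 <- walk_steps(t_turn1, XT, sgn * 180, XT - p$key_ap_m, inside,
                       p, v, Tst, sw, "approach")
      steps <- rbind(steps, a1$rows)
      t_app_arr <- a1$t_arr
      t_r0 <- t_app_arr + 0.2
      t_wb0 <- t_r0 + 1.5
      back_from <- p$key_ap_m; back_t0_nom <- t_r0 + 1.2
      b_keys_t <- c(b_keys_t, t_r0, t_r0 + 0.9, t_r0 + 1.1, t_r0 + 1.9)
      b_keys_v <- c(b_keys_v, walk_bend, p$reach_bend_deg, p$reach_bend_deg, walk_bend)
      z_hang <- stand_z + trunk_len - p$arm_length_m
      reach <- list(t0 = t_r0, t1 = t_r0 + 2.0,
                    kx_t = c(t_r0, t_r0 + 0.9, t_r0 + 1.1, t_r0 + 2.0),
                    kx_v = c(p$key_ap_m, p$key_ap_m - 0.35,
                             p$key_ap_m - 0.35, p$key_ap_m - 0.05),
                    kz_v = c(z_hang, 0.30, 0.30, z_hang))
      wlead <- a1$next_lead
    } else {
      t_wb0 <- max(t_turn1, tO_hs + 0.1)
      back_from <- XT; back_t0_nom <- t_wb0
      wlead <- inside
    }
    w2 <- walk_steps(t_wb0, back_from, sgn * 180, back_from - xs, wlead,
                     p, v, Tst, sw, "walk_back")
    # heading-180 walk moves toward -AP: fix x sign (walk_steps works in
    # its own frame along f); rows already use f so x decreases for 180.
    steps <- rbind(steps, w2$rows)
    t_back_arr <- w2$t_arr
    t_sit2 <- t_back_arr + 0.3
    T_end <- t_sit2 + 1.5 + 1.0
    # trunk bend keys (chair transfers)
    b_keys_t <- c(b_keys_t, t_sit, t_sit + 0.65, t_sit + 0.85, t_walk0,
                  t_sit2, t_sit2 + 0.55, t_sit2 + 0.75, t_sit2 + 1.5, T_end)
    b_keys_v <- c(b_keys_v, 0, p$trunk_bend_deg, p$trunk_bend_deg, walk_bend,
                  walk_bend, p$trunk_bend_deg, p$trunk_bend_deg, 0, 0)
    ord <- order(b_keys_t); b_keys_t <- b_keys_t[ord]; b_keys_v <- b_keys_v[ord]
    # pelvis height keys
    z_keys_t <- c(0, t_sit + 0.6, t_walk0, t_sit2 + 0.3, t_sit2 + 1.3, T_end)
    z_keys_v <- c(p$seat_height_m, p$seat_height_m, stand_z, stand_z,
                  p$seat_height_m, p$seat_height_m)
    # pelvis AP keys (piecewise linear)
    if (protocol == "fmap") {
      x_keys_t <- c(0, t_walk0, t_out_arr, t_turn1, t_app_arr, t_wb0,
                    t_back_arr, T_end)
      x_keys_v <- c(xs, xs, XT, XT, p$key_ap_m, p$key_ap_m, xs, xs)
    } else {
      x_keys_t <- c(0, t_walk0, t_out_arr, t_wb0, t_back_arr, T_end)
      x_keys_v <- c(xs, xs, XT, XT, xs, xs)
    }
    bouts <- list(list(name = "walk_out", t0 = t_walk0, t1 = t_out_arr),
                  list(name = "walk_back", t0 = t_wb0, t1 = t_back_arr))
    gt_seg <- list(sit_to_stand = c(t_sit, t_walk0),
                   walk_out = c(t_walk0, tI_to),
                   turn = c(tI_to, tO_hs),
                   walk_back = c(back_t0_nom, max(steps$t_hs)),
                   stand_to_sit = c(max(steps$t_hs), t_sit2 + 1.3))
    if (protocol == "fmap")
      gt_seg$functional_reach <- c(t_r0, t_r0 + 1.2)
    # freezing script -> nominal times
    if (!is.null(p$fle_script) && nrow(p$fle_script)) {
      for (i in seq_len(nrow(p$fle_script))) {
        b <- p$fle_script$bout[i]
        bt <- switch(b, walk_out = c(t_walk0, t_out_arr),
                     walk_back = c(t_wb0, t_back_arr),
                     stop("fle_script bout must be walk_out/walk_back for this protocol"))
        fr <- min(0.8, max(0.1, p$fle_script$at_frac[i]))
        freezes <- rbind(freezes,
          data.frame(t_nominal = bt[1] + fr * (bt[2] - bt[1]),
                     duration_s = p$fle_script$duration_s[i]))
      }
    }
  } else if (protocol == "locomotion") {
    t0 <- 0.5
    D <- p$locomotion_distance_m
    steps <- init_stance(xs)
    w1 <- walk_steps(t0, xs, 0, D, "R", p, v, Tst, sw, "lap")
    steps <- rbind(steps, w1$rows)
    t_arr <- w1$t_arr
    T_end <- t_arr + 1.0
    x_keys_t <- c(0, t0, t_arr, T_end)
    x_keys_v <- c(xs, xs, xs + D, xs + D)
    z_keys_t <- c(0, T_end); z_keys_v <- c(stand_z, stand_z)
    b_keys_t <- c(0, T_end); b_keys_v <- c(walk_bend, walk_bend)
    bouts <- list(list(name = "lap", t0 = t0, t1 = t_arr))
    gt_seg <- list(locomotion_lap = c(t0, t_arr))
    if (!is.null(p$fle_script) && nrow(p$fle_script)) {
      for (i in seq_len(nrow(p$fle_script))) {
        fr <- min(0.8, max(0.1, p$fle_script$at_frac[i]))
        freezes <- rbind(freezes,
          data.frame(t_nominal = t0 + fr * (t_arr - t0),
                     duration_s = p$fle_script$duration_s[i]))
      }
    }
  } else {                                    # standing
    T_end <- 12
    steps <- init_stance(1.0)
    x_keys_t <- c(0, T_end); x_keys_v <- c(0.9, 0.9)
    z_keys_t <- c(0, T_end); z_keys_v <- c(stand_z, stand_z)
    b_keys_t <- c(0, T_end); b_keys_v <- c(0, 0)
    gt_seg <- list(standing = c(1, 11))
  }

  warp <- build_warp(freezes)
  r_of <- warp$t_of_tau
  n <- as.integer(floor(r_of(T_end) * rate)) + 1L
  t_real <- (seq_len(n) - 1) / rate
  tau <- pmin(T_end, warp$tau_of_t(t_real))
  fr_of <- function(t_nom) as.integer(round(r_of(t_nom) * rate))

  # ---- body channels at tau --------------------------------------------
  px <- stats::approx(x_keys_t, x_keys_v, tau, rule = 2)$y
  py <- rep(0, n)
  if (protocol == "standing") {
    px <- px + 0.004 * sin(2 * pi * 0.30 * tau)
    py <- py + 0.003 * sin(2 * pi * 0.23 * tau + 1)
  }
  pz <- cos_interp(tau, z_keys_t, z_keys_v)
  bend <- cos_interp(tau, b_keys_t, b_keys_v)
  th_p <- heading_fun(tau)
  th_t <- heading_fun(tau + p$trunk_lead_s)
  th_h <- heading_fun(tau + p$head_lead_s)
  fp <- cbind(cos(th_p * rad), sin(th_p * rad)); lp <- cbind(-fp[, 2], fp[, 1])
  ft <- cbind(cos(th_t * rad), sin(th_t * rad)); lt <- cbind(-ft[, 2], ft[, 1])
  fh <- cbind(cos(th_h * rad), sin(th_h * rad)); lh <- cbind(-fh[, 2], fh[, 1])

  P <- cbind(px, py, pz)
  S <- cbind(px + trunk_len * sin(bend * rad) * ft[, 1],
             py + trunk_len * sin(bend * rad) * ft[, 2],
             pz + trunk_len * cos(bend * rad))
  Hc <- S + cbind(0.02 * fh[, 1], 0.02 * fh[, 2], 0.15)

  mk <- list(
    LASI = P + cbind(0.12 * lp[, 1] + 0.05 * fp[, 1],
                     0.12 * lp[, 2] + 0.05 * fp[, 2], 0),
    RASI = P + cbind(-0.12 * lp[, 1] + 0.05 * fp[, 1],
                     -0.12 * lp[, 2] + 0.05 * fp[, 2], 0),
    # ASIS/PSIS fore-aft offsets cancel so the four-marker mean is the
    # pelvis center
    LPSI = P + cbind(0.06 * lp[, 1] - 0.05 * fp[, 1],
                     0.06 * lp[, 2] - 0.05 * fp[, 2], 0),
    RPSI = P + cbind(-0.06 * lp[, 1] - 0.05 * fp[, 1],
                     -0.06 * lp[, 2] - 0.05 * fp[, 2], 0),
    LSHO = S + cbind(0.18 * lt[, 1], 0.18 * lt[, 2], 0),
    RSHO = S + cbind(-0.18 * lt[, 1], -0.18 * lt[, 2], 0),
    CLAV = S + cbind(0.07 * ft[, 1], 0.07 * ft[, 2], -0.02),
    C7   = S + cbind(-0.07 * ft[, 1], -0.07 * ft[, 2], 0),
    LFHD = Hc + cbind(0.08 * lh[, 1] + 0.09 * fh[, 1],
                      0.08 * lh[, 2] + 0.09 * fh[, 2], 0),
    RFHD = Hc + cbind(-0.08 * lh[, 1] + 0.09 * fh[, 1],
                      -0.08 * lh[, 2] + 0.09 * fh[, 2], 0))

  # arms -------------------------------------------------------------
  alpha <- list(L = rep(0, n), R = rep(0, n))
  h_first <- list()
  for (b in bouts) {
    g <- cos_step((tau - (b$t0 - 0.2)) / 0.3) * (1 - cos_step((tau - (b$t1 - 0.1)) / 0.3))
    sb <- steps[steps$bout == b$name, , drop = FALSE]
    for (side in c("L", "R")) {
      h0 <- suppressWarnings(min(sb$t_hs[sb$foot == side]))
      if (!is.finite(h0)) next
      ph <- p$arm_phase_deg[[side]] * rad
      alpha[[side]] <- alpha[[side]] +
        p$arm_swing_deg[[side]] * cos(2 * pi * (tau - h0) / Tst + ph) * g
    }
  }
  for (side in c("L", "R")) {
    sho <- mk[[paste0(side, "SHO")]]
    a <- alpha[[side]] * rad
    wri <- cbind(sho[, 1] + p$arm_length_m * sin(a) * ft[, 1],
                 sho[, 2] + p$arm_length_m * sin(a) * ft[, 2],
                 sho[, 3] - p$arm_length_m * cos(a))
    mk[[paste0(side, "WRA")]] <- wri
  }
  if (!is.null(reach)) {
    dw <- paste0(p$dominant_hand, "WRA")
    sho <- mk[[paste0(p$dominant_hand, "SHO")]]
    b <- cos_step((tau - reach$t0) / 0.2) * (1 - cos_step((tau - (reach$t1 - 0.2)) / 0.2))
    rx <- cos_interp(tau, reach$kx_t, reach$kx_v)
    rz <- cos_interp(tau, reach$kx_t, reach$kz_v)
    w0 <- mk[[dw]]
    mk[[dw]] <- cbind(w0[, 1] + b * (rx - w0[, 1]),
                      w0[, 2] + b * (sho[, 2] - w0[, 2]),
                      w0[, 3] + b * (rz - w0[, 3]))
  }
  for (side in c("L", "R"))
    mk[[paste0(side, "ELB")]] <-
      (mk[[paste0(side, "SHO")]] + mk[[paste0(side, "WRA")]]) / 2

  # feet --------------------------------------------------------------
  ffl <- NULL
  for (side in c("L", "R")) {
    st <- steps[steps$foot == side, , drop = FALSE]
    st <- st[order(st$t_hs), , drop = FALSE]
    tr <- foot_traj(tau, st, sw, p$foot_length_m, p$to_angle_deg,
                    p$hs_angle_deg, p$min_clearance_m)
    mk[[paste0(side, "HEE")]] <- tr$heel
    mk[[paste0(side, "TOE")]] <- tr$toe
    on_f <- fr_of(st$t_hs); on_f[1] <- 0L
    off_f <- c(fr_of(st$t_hs[-1] - sw), n - 1L)
    ffl <- rbind(ffl, data.frame(foot = side, on_frame = on_f, off_frame = off_f,
                                 x = st$x, y = st$y,
                                 cx_mm = st$x * 1000, cy_mm = st$y * 1000,
                                 stringsAsFactors = FALSE))
  }
  for (side in c("L", "R")) {
    hip <- mk[[paste0(side, "ASI")]]
    ank <- mk[[paste0(side, "HEE")]] + matrix(rep(c(0, 0, 0.07), each = n), n, 3)
    mk[[paste0(side, "KNE")]] <- 0.55 * hip + 0.45 * ank +
      cbind(0.03 * fp[, 1], 0.03 * fp[, 2], 0)
  }

  # noise + scripted artifacts ----------------------------------------
  sd_m <- p$noise_mm / 1000
  series <- list()
  for (nm in names(mk)) {
    pos <- mk[[nm]] + matrix(stats::rnorm(3 * n, 0, sd_m), n, 3)
    valid <- rep(TRUE, n)
    if (!is.null(p$spike_script)) {
      sp <- p$spike_script[p$spike_script$marker == nm, , drop = FALSE]
      for (i in seq_len(nrow(sp)))
        pos[sp$frame[i] + 1L, 1] <- pos[sp$frame[i] + 1L, 1] + sp$magnitude_m[i]
    }
    if (!is.null(p$gap_script)) {
      gp <- p$gap_script[p$gap_script$marker == nm, , drop = FALSE]
      for (i in seq_len(nrow(gp))) {
        idx <- (gp$start_frame[i] + 1L):min(n, gp$start_frame[i] + gp$length[i])
        pos[idx, ] <- NA_real_
        valid[idx] <- FALSE
      }
    }
    series[[nm]] <- marker_series(nm, pos, valid, rate)
  }

  cop <- cbind(px, py) * 1000 +
    matrix(stats::rnorm(2 * n, 0, p$cop_noise_mm), n, 2)
  area <- if (protocol == "locomotion")
    c(p$locomotion_distance_m + 1, 1.22) else c(4.88, 1.22)
  mat <- mat_recording(cop, ffl[, c("foot", "on_frame", "off_frame",
                                    "cx_mm", "cy_mm")], rate, area)

  meta <- utils::modifyList(
    list(height_m = p$stature, foot_length_m = p$foot_length_m,
         dominant_hand = p$dominant_hand, turn_direction = p$turn_direction),
    p$subject_meta)
  trial <- trial_recording(series, mat, protocol = protocol,
                           subject_meta = meta)

  # ---- ground truth --------------------------------------------------
  seg_df <- do.call(rbind, lapply(names(gt_seg), function(nm)
    data.frame(task = nm, start_frame = fr_of(gt_seg[[nm]][1]),
               end_frame = fr_of(gt_seg[[nm]][2]), stringsAsFactors = FALSE)))
  # gait truth mirrors the analysis windowing: strides fully inside the
  # walking windows (walkway passes, or the whole lap for locomotion)
  walk_names <- intersect(c("walk_out", "walk_back", "locomotion_lap"),
                          names(gt_seg))
  walk_wins <- if (length(walk_names))
    lapply(gt_seg[walk_names],
           function(w) c(fr_of(w[1]), fr_of(w[2]))) else NULL
  truth <- list(segments = seg_df, footfalls = ffl,
                gait = gait_truth_from_schedule(ffl, rate, walk_wins))
  sign_arm <- function(side)
    if (cos(p$arm_phase_deg[[side]] * rad) < 0) 1 else -1
  tsw <- c(L = 2 * p$arm_swing_deg[["L"]] * sign_arm("L"),
           R = 2 * p$arm_swing_deg[["R"]] * sign_arm("R"))
  dom <- if (abs(tsw["L"]) >= abs(tsw["R"])) "L" else "R"
  truth$params <- list(
    stride_length_m = p$stride_length_m,
    stride_time_s = Tst,
    to_angle_deg = p$to_angle_deg, hs_angle_deg = p$hs_angle_deg,
    min_foot_clearance_m = p$min_clearance_m,
    total_swing_dominant = unname(tsw[dom]),
    total_swing_nondominant = unname(tsw[other_foot(dom)]),
    asa_percent = asa(unname(tsw[dom]), unname(tsw[other_foot(dom)])),
    peak_trunk_inclination_ap = p$trunk_bend_deg)
  if (protocol %in% c("fmap", "tug")) {
    # yaw excursions evaluated exactly as the turning metric defines them
    th_abs <- function(t, lead = 0) 180 * stats::plogis(kk * (t + lead - tm))
    fr_s <- fr_of(gt_seg$turn[1]); fr_e <- fr_of(gt_seg$turn[2])
    tau_at <- function(frame) warp$tau_of_t(frame / rate)
    ref_t <- tau_at((fr_s - 9):(fr_s + 1))
    end_t <- tau_at(fr_e - 1)
    ab <- vapply(c(pelvis = 0, trunk = p$trunk_lead_s, head = p$head_lead_s),
                 function(ld) th_abs(end_t, ld) - stats::median(th_abs(ref_t, ld)),
                 numeric(1))
    truth$params$abs_yaw <- ab[c("head", "trunk", "pelvis")]
    # baseline walking speed from the ground-truth walking windows
    spd <- function(seg_nm) {
      tt <- gt_seg[[seg_nm]]
      x0 <- stats::approx(x_keys_t, x_keys_v, tt[1], rule = 2)$y
      x1 <- stats::approx(x_keys_t, x_keys_v, tt[2], rule = 2)$y
      (x1 - x0) / (r_of(tt[2]) - r_of(tt[1]))
    }
    truth$baseline_speed_m_s <- mean(c(spd("walk_out"), abs(spd("walk_back"))))
  }
  if (!is.null(warp$events)) {
    loc <- vapply(warp$events$t_nominal, function(tn) {
      x <- stats::approx(x_keys_t, x_keys_v, tn, rule = 2)$y
      if (abs(x - p$doorway_ap_m) <= 0.25) "doorway" else "open_walkway"
    }, character(1))
    truth$fle <- data.frame(
      start_frame = as.integer(round(warp$events$t_real * rate)),
      end_frame = as.integer(round((warp$events$t_real + warp$events$duration_s) * rate)),
      duration_s = warp$events$duration_s, location = loc,
      stringsAsFactors = FALSE)
  } else {
    truth$fle <- data.frame(start_frame = integer(), end_frame = integer(),
                            duration_s = numeric(), location = character())
  }
  list(trial = trial, truth = truth, params = p)
}

# ---- cohort-level simulation ------------------------------------------------

#' Base metric distributions for cohort simulation
#'
#' Plausible means and spreads for a compact metric subset used by the
#' metric-level cohort simulator; names match [default_families()].
#'
#' @return Data frame with `task`, `metric_name`, `units`, `mean`, `sd`.
#' @export
cohort_metric_base <- function() {
  data.frame(
    task = c("sit_to_stand", "sit_to_stand", "sit_to_stand",
             "turn", "turn", "turn",
             "locomotion_lap", "locomotion_lap", "locomotion_lap", "locomotion_lap"),
    metric_name = c("peak_trunk_inclination_ap", "peak_trunk_velocity_ap",
                    "mean_cop_ap_mm",
                    "abs_yaw_trunk", "rel_yaw_head_trunk", "to_angle_deg",
                    "stride_length_m", "stride_velocity_m_s", "asa_percent",
                    "total_swing_dominant"),
    units = c("deg", "m/s", "mm", "deg", "deg", "deg", "m", "m/s", "%", "deg"),
    mean = c(32, 0.8, 40, 175, 12, 18, 1.25, 1.15, 8, 30),
    sd = c(6, 0.2, 15, 8, 5, 4, 0.15, 0.2, 5, 8),
    stringsAsFactors = FALSE)
}

#' Simulate a study cohort
#'
#' Two levels. `level = "metrics"` draws metric values directly from a
#' linear model (subject random intercept + specified effects + residual
#' noise) -- fast, for statistical power/false-positive studies.
#' `level = "trials"` runs the full avatar for every subject, protocol and
#' trial and extracts metrics through the analysis pipeline -- slow, for
#' end-to-end checks.
#'
#' @param n_per_group Subjects per group (or total subjects for the phase
#'   design).
#' @param design `"group_protocol"` (control/pd x fmap/tug) or `"phase"`
#'   (Baseline/Pre/Post within subject).
#' @param effects List of named numeric vectors keyed by metric name:
#'   `group` (added for group "pd"), `protocol` (added for protocol
#'   "fmap"), `interaction` (added for pd x fmap), and for the phase
#'   design `phase` = list(metric = c(Pre = d, Post = d)).
#' @param seed RNG seed.
#' @param level `"metrics"` or `"trials"`.
#' @param n_trials Trials per condition (default 3).
#' @param missing_frac Fraction of values deleted completely at random.
#' @param subject_sd,residual_sd Random-intercept and residual SD in units
#'   of each metric's base `sd`.
#' @param base_metrics Metric base table, see [cohort_metric_base()].
#' @param param_tweaks For `level = "trials"`: function(group) returning a
#'   named list of [avatar_params()] overrides.
#' @return List with `table` (a [metric_table()]), `covariates` and
#'   `truth` (the injected effects).
#' @export
simulate_cohort <- function(n_per_group = 12,
                            design = c("group_protocol", "phase"),
                            effects = list(), seed = 1,
                            level = c("metrics", "trials"),
                            n_trials = 3, missing_frac = 0,
                            subject_sd = 0.6, residual_sd = 0.5,
                            base_metrics = cohort_metric_base(),
                            param_tweaks = NULL) {
  design <- match.arg(design)
  level <- match.arg(level)
  set.seed(seed)
  eff <- function(kind, metric) {
    e <- effects[[kind]]
    if (is.null(e) || !metric %in% names(e) || !is.finite(e[[metric]])) 0
    else e[[metric]]
  }
  if (design == "group_protocol") {
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(2 * n_per_group)),
      group = rep(c("control", "pd"), each = n_per_group),
      stringsAsFactors = FALSE)
    conds <- c("fmap", "tug")
  } else {
    subjects <- data.frame(subject_id = sprintf("S%03d", seq_len(n_per_group)),
                           group = "pd", stringsAsFactors = FALSE)
    conds <- c("Baseline", "Pre", "Post")
  }
  covariates <- data.frame(
    subject_id = subjects$subject_id,
    age = round(stats::rnorm(nrow(subjects), 66, 8)),
    sex = sample(c("F", "M"), nrow(subjects), replace = TRUE),
    height_m = round(stats::rnorm(nrow(subjects), 1.70, 0.08), 3),
    stringsAsFactors = FALSE)
  covariates$foot_length_m <- round(0.15 * covariates$height_m, 3)

  if (level == "trials") {
    if (design != "group_protocol")
      stop("level='trials' supports the group_protocol design")
    if (is.null(param_tweaks))
      param_tweaks <- function(group)
        if (group == "pd")
          list(stride_length_m = 1.05, arm_swing_deg = c(L = 6, R = 14),
               trunk_bend_deg = 40, cadence_spm = 104)
        else list()
    rows <- NULL
    for (i in seq_len(nrow(subjects))) {
      tw <- param_tweaks(subjects$group[i])
      for (prot in conds) {
        for (tr in seq_len(n_trials)) {
          pa <- do.call(avatar_params,
                        utils::modifyList(tw, list(seed = seed * 10000 + i * 100 +
                                                     tr + (prot == "tug") * 50)))
          sim <- simulate_trial(pa, protocol = prot)
          mt <- analyze_trial(sim$trial, subject_id = subjects$subject_id[i],
                              group = subjects$group[i], trial_index = tr)
          rows <- rbind(rows, as.data.frame(mt))
        }
      }
    }
    tab <- metric_table(rows)
    return(list(table = tab, covariates = covariates, truth = effects))
  }

  rows <- NULL
  for (i in seq_len(nrow(subjects))) {
    subj_u <- stats::rnorm(nrow(base_metrics), 0, subject_sd)
    for (cond in conds) {
      for (tr in seq_len(n_trials)) {
        m <- base_metrics
        delta <- numeric(nrow(m))
        if (design == "group_protocol") {
          for (j in seq_len(nrow(m))) {
            mn <- m$metric_name[j]
            if (subjects$group[i] == "pd") delta[j] <- delta[j] + eff("group", mn)
            if (cond == "fmap") delta[j] <- delta[j] + eff("protocol", mn)
            if (subjects$group[i] == "pd" && cond == "fmap")
              delta[j] <- delta[j] + eff("interaction", mn)
          }
          protocol <- cond; phase <- NA_character_
        } else {
          for (j in seq_len(nrow(m))) {
            ph <- if (m$metric_name[j] %in% names(effects$phase))
              effects$phase[[m$metric_name[j]]] else NULL
            if (!is.null(ph) && cond %in% names(ph)) delta[j] <- delta[j] + ph[[cond]]
          }
          protocol <- "fmap"; phase <- cond
        }
        val <- m$mean + delta + m$sd * (subj_u + stats::rnorm(nrow(m), 0, residual_sd))
        rows <- rbind(rows, data.frame(
          subject_id = subjects$subject_id[i], group = subjects$group[i],
          protocol = protocol, phase = phase, trial_index = tr,
          task = m$task, metric_name = m$metric_name, value = val,
          units = m$units, stringsAsFactors = FALSE))
      }
    }
  }
  if (missing_frac > 0) {
    k <- round(missing_frac * nrow(rows))
    rows$value[sample.int(nrow(rows), k)] <- NA_real_
  }
  list(table = metric_table(rows), covariates = covariates, truth = effects)
}
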