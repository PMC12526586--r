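# Derived segment kinematics: yaw angles, trunk inclination, midpoints,
# and the filtered differentiation chain used by all dynamic metrics.

# Internal: unwrap a degree series (remove +-360 jumps).
unwrap_deg <- function(x) {
  d <- diff(x)
  d <- ((d + 180) %% 360) - 180
  c(x[1], x[1] + cumsum(d))
}

# Internal: yaw (deg) of a body segment from its left/right marker pair.
# At heading 0 (facing +AP) the left marker sits at +ML; positive yaw is a
# counterclockwise rotation about the vertical axis.
yaw_from_pair <- function(left, right) {
  lr <- left - right
  unwrap_deg(atan2(-lr[, 1], lr[, 2]) * 180 / pi)
}

# Internal: zero-lag low-pass used before differentiation (4th order at
# 6 Hz by default). Jerk-type metrics depend on this filter; it is part of
# the declared method configuration.
lp_zerolag <- function(x, rate_hz, cutoff_hz = 6, order = 4) {
  nyq <- rate_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  signal::filtfilt(bf, x)
}

# Internal: central-difference derivative.
deriv_central <- function(x, rate_hz) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate_hz / 2
  d[1] <- (x[2] - x[1]) * rate_hz
  d[n] <- (x[n] - x[n - 1]) * rate_hz
  d
}

#' Compute segment kinematics for a trial
#'
#' Derives, per frame: head/trunk/pelvis yaw (degrees, unwrapped and
#' sign-normalized so counterclockwise turns are canonical), trunk
#' inclination in the AP-vertical and ML-vertical planes (degrees,
#' 0 = upright), and the pelvis and shoulder midpoints (meters).
#'
#' @param trial A [trial_recording()] (ideally after [preprocess_trial()]).
#' @return A list of class `segment_kinematics` with elements `yaw`
#'   (T x 3 matrix, columns head/trunk/pelvis), `incl_ap`, `incl_ml`
#'   (signed degrees), `pelvis_mid`, `shoulder_mid` (T x 3), `rate_hz`,
#'   and `valid` (frames where all constituent markers are valid).
#' @export
segment_kinematics <- function(trial) {
  s <- turn_sign(trial)
  head_ok <- has_markers(trial, c("LFHD", "RFHD"))
  pm <- midpoint_of(trial, c("LASI", "RASI", "LPSI", "RPSI"), "segment kinematics")
  sm <- midpoint_of(trial, c("LSHO", "RSHO"), "segment kinematics")
  yaw <- cbind(
    head = if (head_ok)
      s * yaw_from_pair(get_marker(trial, "LFHD")$positions,
                        get_marker(trial, "RFHD")$positions) else NA_real_,
    trunk = s * yaw_from_pair(get_marker(trial, "LSHO")$positions,
                              get_marker(trial, "RSHO")$positions),
    pelvis = s * yaw_from_pair(get_marker(trial, "LASI")$positions,
                               get_marker(trial, "RASI")$positions))
  tv <- sm - pm                                   # trunk vector
  len <- sqrt(rowSums(tv^2))
  incl_ap <- atan2(tv[, 1], tv[, 3]) * 180 / pi   # + = leaning forward
  incl_ml <- s * atan2(tv[, 2], tv[, 3]) * 180 / pi
  # heading-invariant bend: angle of the trunk vector from vertical
  incl_mag <- atan2(sqrt(tv[, 1]^2 + tv[, 2]^2), tv[, 3]) * 180 / pi
  valid <- valid_of(trial, intersect(
    c("LASI", "RASI", "LPSI", "RPSI", "LSHO", "RSHO"), names(trial$markers)))
  structure(list(yaw = yaw, incl_ap = incl_ap, incl_ml = incl_ml,
                 incl_mag = incl_mag,
                 trunk_len = len, pelvis_mid = pm, shoulder_mid = sm,
                 rate_hz = trial_rate(trial), valid = valid),
            class = "segment_kinematics")
}
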