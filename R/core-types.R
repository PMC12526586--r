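# Core domain types for instrumented mobility trials.
#
# Coordinate convention (fixed here, documented in the vignette): the lab
# frame has +AP pointing from the chair toward the turn point, vertical
# pointing up, and ML completing a right-handed triad (AP x ML = vertical).
# All internal lengths are meters; center-of-pressure data are kept in mm.
# Frame indexing is 0-based and intervals are half-open [start, end).

#' Construct a lab reference frame
#'
#' The lab frame fixes the anteroposterior (AP) walking direction (+AP from
#' the chair toward the turn point), the mediolateral (ML) axis and the
#' vertical (up) axis as a right-handed orthonormal triad, plus the chair
#' origin in meters.
#'
#' @param ap_axis,ml_axis,vertical_axis Numeric length-3 unit vectors.
#' @param origin Numeric length-3 chair start position, meters.
#' @return An object of class `lab_frame`.
#' @export
lab_frame <- function(ap_axis = c(1, 0, 0), ml_axis = c(0, 1, 0),
                      vertical_axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  ap <- as.numeric(ap_axis); ml <- as.numeric(ml_axis); up <- as.numeric(vertical_axis)
  stopifnot(length(ap) == 3, length(ml) == 3, length(up) == 3, length(origin) == 3)
  tol <- 1e-9
  if (abs(sum(ap^2) - 1) > tol || abs(sum(ml^2) - 1) > tol || abs(sum(up^2) - 1) > tol)
    stop("lab_frame axes must be unit vectors")
  if (abs(sum(ap * ml)) > tol || abs(sum(ap * up)) > tol || abs(sum(ml * up)) > tol)
    stop("lab_frame axes must be mutually orthogonal")
  cr <- c(ap[2] * ml[3] - ap[3] * ml[2],
          ap[3] * ml[1] - ap[1] * ml[3],
          ap[1] * ml[2] - ap[2] * ml[1])
  if (max(abs(cr - up)) > 1e-9)
    stop("lab_frame must be right-handed: ap x ml = vertical")
  structure(list(ap_axis = ap, ml_axis = ml, vertical_axis = up,
                 origin = as.numeric(origin)),
            class = "lab_frame")
}

#' Construct a marker trajectory series
#'
#' @param name Marker label (Plug-in-Gait / CGM2 vocabulary where possible).
#' @param positions T x 3 numeric matrix, meters, lab frame (AP, ML, vertical).
#' @param valid_mask Logical vector length T; `FALSE` marks occluded frames.
#'   Defaults to marking every frame with a non-finite coordinate invalid.
#' @param rate_hz Sampling rate in Hz (100 for the supported hardware).
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(name, positions, valid_mask = NULL, rate_hz = 100) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be a T x 3 matrix")
  n <- nrow(positions)
  # default mask: frames with any non-finite coordinate are invalid (gaps)
  if (is.null(valid_mask)) valid_mask <- is.finite(rowSums(positions))
  valid_mask <- as.logical(valid_mask)
  if (length(valid_mask) != n) stop("valid_mask length must match positions")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0")
  if (any(valid_mask & !is.finite(rowSums(positions))))
    stop("positions must be finite wherever valid_mask is TRUE")
  structure(list(name = as.character(name), positions = positions,
                 valid_mask = valid_mask, rate_hz = rate_hz),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series '%s': %d frames @ %g Hz, %d invalid>\n",
              x$name, nrow(x$positions), x$rate_hz, sum(!x$valid_mask)))
  invisible(x)
}

#' Construct a pressure-mat recording
#'
#' @param cop T x 2 numeric matrix of center-of-pressure samples (AP, ML), mm.
#' @param footfalls Data frame with columns `foot` ("L"/"R"), `on_frame`,
#'   `off_frame`, `cx_mm`, `cy_mm` (footfall centroid), or `NULL`.
#' @param rate_hz Sampling rate, Hz.
#' @param active_area Length-2 numeric, mat active area (AP, ML) in meters.
#' @return An object of class `mat_recording`.
#' @export
mat_recording <- function(cop, footfalls = NULL, rate_hz = 100,
                          active_area = c(4.88, 1.22)) {
  cop <- as.matrix(cop)
  if (ncol(cop) != 2) stop("cop must be a T x 2 matrix (AP, ML) in mm")
  colnames(cop) <- c("ap_mm", "ml_mm")
  if (is.null(footfalls)) {
    footfalls <- data.frame(foot = character(), on_frame = integer(),
                            off_frame = integer(), cx_mm = numeric(),
                            cy_mm = numeric(), stringsAsFactors = FALSE)
  } else {
    footfalls <- as.data.frame(footfalls)
    need <- c("foot", "on_frame", "off_frame")
    if (!all(need %in% names(footfalls))) stop("footfalls need foot/on_frame/off_frame")
    bad <- footfalls$off_frame <= footfalls$on_frame
    if (any(bad)) {
      warning(sprintf("dropping %d footfall row(s) with off_frame <= on_frame", sum(bad)))
      footfalls <- footfalls[!bad, , drop = FALSE]
    }
    footfalls <- footfalls[order(footfalls$on_frame), , drop = FALSE]
    for (ft in c("L", "R")) {
      f <- footfalls[footfalls$foot == ft, , drop = FALSE]
      if (nrow(f) > 1 && any(f$on_frame[-1] < f$off_frame[-nrow(f)]))
        stop(sprintf("overlapping footfalls for foot %s", ft))
    }
    rownames(footfalls) <- NULL
  }
  structure(list(cop = cop, footfalls = footfalls, rate_hz = rate_hz,
                 active_area = as.numeric(active_area)),
            class = "mat_recording")
}

#' Segment-to-marker model
#'
#' Maps body segments to the marker labels that define them, and names the
#' derived midpoints (pelvis and shoulder midpoints as convex combinations
#' of their markers).
#'
#' @param segments Named list mapping segment name to character vector of
#'   marker labels (each segment needs at least 2 markers).
#' @return An object of class `segment_model`.
#' @export
segment_model <- function(segments) {
  stopifnot(is.list(segments), length(names(segments)) == length(segments))
  for (s in names(segments)) {
    if (length(segments[[s]]) < 2)
      stop(sprintf("segment '%s' must resolve to >= 2 markers", s))
  }
  structure(list(segments = segments), class = "segment_model")
}

#' Default full-body segment model
#'
#' The minimal marker subset the metric set needs: front head pair,
#' shoulders, elbows, wrists, ASIS/PSIS pelvis cluster, knees, heels, toes.
#'
#' @return A `segment_model`.
#' @export
default_segment_model <- function() {
  segment_model(list(
    head      = c("LFHD", "RFHD"),
    trunk     = c("LSHO", "RSHO", "CLAV", "C7"),
    pelvis    = c("LASI", "RASI", "LPSI", "RPSI"),
    upper_arm_L = c("LSHO", "LELB"), upper_arm_R = c("RSHO", "RELB"),
    forearm_L = c("LELB", "LWRA"),   forearm_R = c("RELB", "RWRA"),
    thigh_L   = c("LASI", "LKNE"),   thigh_R   = c("RASI", "RKNE"),
    shank_L   = c("LKNE", "LHEE"),   shank_R   = c("RKNE", "RHEE"),
    foot_L    = c("LHEE", "LTOE"),   foot_R    = c("RHEE", "RTOE")
  ))
}

#' Construct a trial recording
#'
#' A synchronized set of marker trajectories plus (optionally) a pressure-mat
#' recording for one execution of a protocol. Marker and mat streams share
#' the start time and the sampling rate.
#'
#' @param markers Named list of [marker_series()] (names = marker labels).
#' @param mat A [mat_recording()] or `NULL`.
#' @param protocol One of `"fmap"`, `"tug"`, `"standing"`, `"locomotion"`.
#' @param trial_index Trial number within the session (1..3 in practice).
#' @param subject_meta List with `age`, `sex`, `height_m`, `foot_length_m`,
#'   `dominant_hand` ("L"/"R") and `turn_direction` ("CW"/"CCW").
#' @param frame The [lab_frame()] of the recording.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(markers, mat = NULL, protocol = "fmap",
                            trial_index = 1L, subject_meta = list(),
                            frame = lab_frame()) {
  protocol <- match.arg(protocol, c("fmap", "tug", "standing", "locomotion"))
  if (is.null(names(markers)) || any(names(markers) == ""))
    stop("markers must be a named list")
  lens <- vapply(markers, function(m) nrow(m$positions), integer(1))
  if (length(unique(lens)) > 1)
    stop("all marker series in a trial must have the same number of frames")
  rates <- vapply(markers, function(m) m$rate_hz, numeric(1))
  if (length(unique(rates)) > 1) stop("all marker series must share rate_hz")
  if (!is.null(mat) && !inherits(mat, "mat_recording"))
    stop("mat must be a mat_recording or NULL")
  meta_defaults <- list(age = NA_real_, sex = NA_character_, height_m = NA_real_,
                        foot_length_m = NA_real_, dominant_hand = "R",
                        turn_direction = "CCW")
  subject_meta <- utils::modifyList(meta_defaults, subject_meta)
  structure(list(markers = markers, mat = mat, protocol = protocol,
                 trial_index = as.integer(trial_index),
                 subject_meta = subject_meta, frame = frame),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording: %s, %d markers, %d frames @ %g Hz, mat: %s>\n",
              x$protocol, length(x$markers), n_frames(x), trial_rate(x),
              if (is.null(x$mat)) "absent" else "present"))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial A `trial_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(trial) {
  if (length(trial$markers) == 0) return(0L)
  nrow(trial$markers[[1]]$positions)
}

#' Sampling rate of a trial
#' @param trial A `trial_recording`.
#' @return Rate in Hz.
#' @export
trial_rate <- function(trial) {
  if (length(trial$markers) == 0) return(NA_real_)
  trial$markers[[1]]$rate_hz
}

#' Fetch one marker series from a trial
#'
#' Errors with a message naming the requiring computation when the marker
#' is absent (declared-unavailable, never a silent zero).
#'
#' @param trial A [trial_recording()].
#' @param name Marker label, e.g. `"LHEE"`.
#' @param required_by Optional name of the computation needing the marker,
#'   used in the error message.
#' @return A [marker_series()].
#' @export
get_marker <- function(trial, name, required_by = NULL) {
  m <- trial$markers[[name]]
  if (is.null(m)) {
    msg <- sprintf("marker '%s' not present in trial", name)
    if (!is.null(required_by)) msg <- sprintf("%s (required for %s)", msg, required_by)
    stop(msg, call. = FALSE)
  }
  m
}

has_markers <- function(trial, names) all(names %in% names(trial$markers))

# Internal: mean of several marker position matrices (derived midpoints).
midpoint_of <- function(trial, names, required_by = NULL) {
  mats <- lapply(names, function(nm) get_marker(trial, nm, required_by)$positions)
  Reduce(`+`, mats) / length(mats)
}

# Internal: combined validity of several markers.
valid_of <- function(trial, names) {
  Reduce(`&`, lapply(names, function(nm) trial$markers[[nm]]$valid_mask))
}

# Internal: sign normalization for turn direction. Yaw and ML-signed
# quantities are multiplied by -1 for CW turns so CCW is canonical.
turn_sign <- function(trial) {
  if (identical(trial$subject_meta$turn_direction, "CW")) -1 else 1
}
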