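# Gait event detection: heel strikes and toe offs per foot, from marker
# kinematics (pelvis-relative AP extrema) cross-checked against and, when
# present, overridden by pressure-mat footfalls.

#' Construct a gait events object
#'
#' @param L,R Lists with integer vectors `hs` (heel strikes) and `to`
#'   (toe offs), 0-based frames, strictly increasing.
#' @param source `"markers"`, `"mat"` or `"none"`.
#' @param mat_offset Median frame offset between mat and marker events when
#'   both were available (`NA` otherwise).
#' @return Object of class `gait_events` with derived per-foot strides
#'   (`start_hs`, `to_frame`, `end_hs`): consecutive ipsilateral heel
#'   strikes enclosing exactly one toe off.
#' @export
gait_events <- function(L = list(hs = integer(), to = integer()),
                        R = list(hs = integer(), to = integer()),
                        source = "markers", mat_offset = NA_real_) {
  for (f in list(L, R)) {
    if (is.unsorted(f$hs, strictly = TRUE) || is.unsorted(f$to, strictly = TRUE))
      stop("gait events must be strictly increasing per foot")
  }
  strides <- function(f, foot) {
    out <- NULL
    hs <- f$hs
    if (length(hs) >= 2) {
      for (i in seq_len(length(hs) - 1)) {
        tos <- f$to[f$to > hs[i] & f$to < hs[i + 1]]
        if (length(tos) == 1)
          out <- rbind(out, data.frame(foot = foot, start_hs = hs[i],
                                       to_frame = tos, end_hs = hs[i + 1]))
      }
    }
    out
  }
  st <- rbind(strides(L, "L"), strides(R, "R"))
  if (is.null(st))
    st <- data.frame(foot = character(), start_hs = integer(),
                     to_frame = integer(), end_hs = integer())
  structure(list(L = L, R = R, strides = st, source = source,
                 mat_offset = mat_offset),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events [%s]: L %d HS/%d TO, R %d HS/%d TO, %d strides>\n",
              x$source, length(x$L$hs), length(x$L$to),
              length(x$R$hs), length(x$R$to), nrow(x$strides)))
  invisible(x)
}

# Internal: local maxima with minimum height and separation; ties resolved
# toward the higher peak.
find_peaks <- function(x, min_height = -Inf, min_sep = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-x[cand])]
  keep <- integer(0)
  for (i in cand) if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}

#' Detect heel-strike and toe-off events
#'
#' Coordinate-based detection: heel strikes at local maxima of the heel
#' marker's AP position relative to the pelvis midpoint (along the current
#' walking direction), toe offs at local minima of the toe marker's
#' relative AP position. Candidates are restricted to frames where the
#' pelvis actually translates, so a quiet-standing trial yields no events.
#' When pressure-mat footfalls are present they override the marker events
#' (heel strike = footfall onset, toe off = footfall release) and the
#' median frame offset between paired mat and marker events is reported.
#'
#' @param trial A [trial_recording()] with heel/toe markers and pelvis
#'   cluster.
#' @param min_speed Minimum smoothed pelvis AP speed (m/s) for marker
#'   events to be considered.
#' @param pair_tol Pairing tolerance (frames) for the mat cross-check.
#' @return A [gait_events()].
#' @export
detect_gait_events <- function(trial, min_speed = 0.15, pair_tol = 10) {
  rate <- trial_rate(trial)
  pm <- midpoint_of(trial, c("LASI", "RASI", "LPSI", "RPSI"), "gait events")
  v <- deriv_central(lp_zerolag(pm[, 1], rate), rate)
  dirsign <- sign(v)
  moving <- abs(v) > min_speed
  min_sep <- round(0.5 * rate)

  foot_events <- function(side) {
    heel <- get_marker(trial, paste0(side, "HEE"), "gait events")$positions[, 1]
    toe <- get_marker(trial, paste0(side, "TOE"), "gait events")$positions[, 1]
    rel_h <- (heel - pm[, 1]) * dirsign
    rel_t <- (toe - pm[, 1]) * dirsign
    rel_h[!moving] <- -Inf
    rel_t[!moving] <- Inf
    hs <- find_peaks(rel_h, min_height = 0.05, min_sep = min_sep)
    to <- find_peaks(-rel_t, min_height = 0.05, min_sep = min_sep)
    list(hs = sort(hs) - 1L, to = sort(to) - 1L)     # 0-based
  }
  mk <- list(L = foot_events("L"), R = foot_events("R"))

  ff <- if (!is.null(trial$mat)) trial$mat$footfalls else NULL
  if (!is.null(ff) && nrow(ff)) {
    offsets <- numeric(0)
    mat_ev <- list()
    for (side in c("L", "R")) {
      f <- ff[ff$foot == side, , drop = FALSE]
      hs <- sort(unique(as.integer(f$on_frame)))
      to <- sort(unique(as.integer(f$off_frame)))
      # a stance already present at recording start is not a heel strike,
      # and one still present at recording end is not a toe off
      hs <- hs[hs > 0L]
      to <- to[to < n_frames(trial) - 1L]
      for (h in hs) {
        d <- mk[[side]]$hs - h
        if (length(d) && min(abs(d)) <= pair_tol) offsets <- c(offsets, d[which.min(abs(d))])
      }
      mat_ev[[side]] <- list(hs = hs, to = to)
    }
    return(gait_events(mat_ev$L, mat_ev$R, source = "mat",
                       mat_offset = if (length(offsets)) stats::median(offsets) else NA_real_))
  }
  n_str <- nrow(gait_events(mk$L, mk$R)$strides)
  if (n_str < 2 && (length(mk$L$hs) + length(mk$R$hs)) > 0)
    warning("fewer than 2 strides detectable from markers")
  gait_events(mk$L, mk$R, source = "markers")
}
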