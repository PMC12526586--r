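# Trajectory conditioning: gap filling, spike mitigation, COP filtering,
# exclusion rules.
#
# Order of operations downstream: gaps are filled first, the moving-average
# despike runs second, and differentiation (in the metrics layer) always
# happens after both.

# Internal: locate runs of FALSE in a logical vector.
# Returns data.frame(start, len) with 0-based starts.
invalid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- !r$values
  data.frame(start = starts[bad] - 1L, len = r$lengths[bad])
}

#' Fill occlusion gaps in a marker trajectory
#'
#' Interior gaps up to `max_poly_gap` frames are filled with a local cubic
#' polynomial fitted to the flanking valid frames; longer gaps up to
#' `max_spline_gap` are filled with a cubic spline through flanking
#' context; anything longer, and any gap touching the sequence boundary,
#' is left invalid and reported as excluded. Originally valid frames are
#' never modified.
#'
#' @param series A [marker_series()].
#' @param max_poly_gap Longest gap (frames) filled by polynomial; default 10.
#' @param max_spline_gap Longest gap (frames) filled by spline; default 100
#'   (1 s at 100 Hz). Beyond this, data are excluded.
#' @param context Valid frames used on each side of a gap for the fits.
#' @return List with elements `series` (filled [marker_series()]) and
#'   `report` (data frame `gap_start`, `gap_len`, `method`; 0-based starts).
#' @export
fill_gaps <- function(series, max_poly_gap = 10, max_spline_gap = 100,
                      context = 25) {
  pos <- series$positions
  valid <- series$valid_mask
  n <- length(valid)
  runs <- invalid_runs(valid)
  report <- data.frame(gap_start = integer(), gap_len = integer(),
                       method = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(runs))) {
    g0 <- runs$start[i]            # 0-based first invalid frame
    glen <- runs$len[i]
    idx <- (g0 + 1):(g0 + glen)    # 1-based R indices of the gap
    boundary <- g0 == 0 || (g0 + glen) == n
    method <- if (boundary || glen > max_spline_gap) "excluded"
              else if (glen <= max_poly_gap) "polynomial" else "spline"
    if (method != "excluded") {
      left <- which(valid[seq_len(g0)])
      right <- g0 + glen + which(valid[(g0 + glen + 1):n])
      ctx <- if (method == "polynomial") min(context, 5L) else context
      lctx <- utils::tail(left, ctx)
      rctx <- utils::head(right, ctx)
      xs <- c(lctx, rctx)
      if (length(lctx) == 0 || length(rctx) == 0) {
        method <- "excluded"
      } else if (method == "polynomial") {
        deg <- min(3L, length(xs) - 1L)
        mid <- mean(idx)                      # center for conditioning
        X <- outer(xs - mid, 0:deg, `^`)
        Xg <- outer(idx - mid, 0:deg, `^`)
        for (d in 1:3) {
          beta <- stats::lm.fit(X, pos[xs, d])$coefficients
          beta[is.na(beta)] <- 0
          pos[idx, d] <- Xg %*% beta
        }
        valid[idx] <- TRUE
      } else {
        for (d in 1:3)
          pos[idx, d] <- stats::spline(xs, pos[xs, d], xout = idx,
                                       method = "fmm")$y
        valid[idx] <- TRUE
      }
    }
    report <- rbind(report, data.frame(gap_start = g0, gap_len = glen,
                                       method = method))
  }
  out <- series
  out$positions <- pos
  out$valid_mask <- valid
  list(series = out, report = report)
}

#' Mitigate spikes with a centered moving average
#'
#' A centered moving average of `window` samples (0.15 s at 100 Hz with the
#' default 15) applied per coordinate. Windows shrink at the edges, and
#' invalid frames are never used as sources (the average runs over the
#' valid frames inside the window). Values at invalid frames are left
#' untouched.
#'
#' @param series A [marker_series()].
#' @param window Window length in samples; forced odd; default 15.
#' @return A smoothed [marker_series()].
#' @export
despike <- function(series, window = 15) {
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  if (window %% 2 == 0) window <- window + 1L
  if (window == 1L) return(series)
  half <- (window - 1L) %/% 2L
  valid <- series$valid_mask
  n <- length(valid)
  v <- as.numeric(valid)
  # windowed sums via padded cumulative sums (edges shrink automatically)
  wsum <- function(x) {
    cs <- c(0, cumsum(x))
    hi <- pmin(n, seq_len(n) + half)
    lo <- pmax(0L, seq_len(n) - half - 1L)
    cs[hi + 1L] - cs[lo + 1L]
  }
  counts <- wsum(v)
  out <- series$positions
  for (d in 1:3) {
    x <- series$positions[, d]
    x[!valid] <- 0
    s <- wsum(x)
    sm <- ifelse(counts > 0, s / counts, series$positions[, d])
    out[valid, d] <- sm[valid]
  }
  res <- series
  res$positions <- out
  res
}

#' Zero-lag Butterworth filter for center-of-pressure data
#'
#' Forward-backward (zero phase) low-pass Butterworth, 5 poles at 10 Hz by
#' default, applied to each COP channel. DC gain is 1, so a constant trace
#' passes unchanged.
#'
#' @param mat A [mat_recording()].
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @param poles Filter order.
#' @return A filtered [mat_recording()].
#' @export
filter_cop <- function(mat, cutoff_hz = 10, poles = 5) {
  nyq <- mat$rate_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff must be below the Nyquist frequency")
  warmup <- 3 * (poles + 1)
  if (nrow(mat$cop) <= 3 * warmup)
    stop("COP trace too short for zero-lag filtering")
  bf <- signal::butter(poles, cutoff_hz / nyq, type = "low")
  out <- mat
  for (d in 1:2) out$cop[, d] <- signal::filtfilt(bf, mat$cop[, d])
  out
}

#' Decide whether a conditioned series is usable
#'
#' A series is unusable iff invalid frames remain (an excluded gap) inside
#' any of the task windows of interest. Boundary gaps outside all task
#' windows do not disqualify a trial.
#'
#' @param series A [marker_series()] after [fill_gaps()].
#' @param report The fill report from [fill_gaps()].
#' @param task_windows Optional data frame with `start_frame`, `end_frame`
#'   (0-based, half-open). Default: the whole series is the window.
#' @return List with `usable` (logical) and `reason` (string or `NA`).
#' @export
exclusion_check <- function(series, report, task_windows = NULL) {
  n <- length(series$valid_mask)
  if (is.null(task_windows))
    task_windows <- data.frame(start_frame = 0L, end_frame = n)
  bad <- which(!series$valid_mask) - 1L       # 0-based invalid frames
  for (i in seq_len(nrow(task_windows))) {
    hit <- bad[bad >= task_windows$start_frame[i] &
               bad < task_windows$end_frame[i]]
    if (length(hit)) {
      return(list(usable = FALSE,
                  reason = sprintf("%d invalid frame(s) inside task window [%d, %d)",
                                   length(hit), task_windows$start_frame[i],
                                   task_windows$end_frame[i])))
    }
  }
  list(usable = TRUE, reason = NA_character_)
}

#' Condition every marker of a trial and filter its COP
#'
#' Applies [fill_gaps()] then [despike()] to each marker and
#' [filter_cop()] to the mat (when present and long enough).
#'
#' @param trial A [trial_recording()].
#' @param max_poly_gap,max_spline_gap Passed to [fill_gaps()].
#' @param despike_window Passed to [despike()].
#' @param cop_cutoff_hz,cop_poles Passed to [filter_cop()].
#' @return List with `trial` (conditioned) and `fill_reports` (named list
#'   of per-marker fill reports).
#' @export
preprocess_trial <- function(trial, max_poly_gap = 10, max_spline_gap = 100,
                             despike_window = 15, cop_cutoff_hz = 10,
                             cop_poles = 5) {
  reports <- list()
  for (nm in names(trial$markers)) {
    f <- fill_gaps(trial$markers[[nm]], max_poly_gap, max_spline_gap)
    reports[[nm]] <- f$report
    trial$markers[[nm]] <- despike(f$series, despike_window)
  }
  if (!is.null(trial$mat) && nrow(trial$mat$cop) > 9 * (cop_poles + 1))
    trial$mat <- filter_cop(trial$mat, cop_cutoff_hz, cop_poles)
  list(trial = trial, fill_reports = reports)
}
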