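# Plain-text interchange: marker CSV fixtures and pressure-mat exports.

#' Write markers to the plain CSV dialect
#'
#' Long format, one row per frame per marker:
#' `frame, marker, x, y, z, valid` (0-based frames, meters).
#'
#' @param trial A [trial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(trial, path) {
  n <- n_frames(trial)
  rows <- lapply(names(trial$markers), function(nm) {
    m <- trial$markers[[nm]]
    data.frame(frame = seq_len(n) - 1L, marker = nm,
               x = m$positions[, 1], y = m$positions[, 2], z = m$positions[, 3],
               valid = as.integer(m$valid_mask))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read markers from the plain CSV dialect
#'
#' @param path CSV with columns `frame, marker, x, y, z, valid`.
#' @param rate_hz Sampling rate to attach (the dialect carries none).
#' @inheritParams read_c3d_trial
#' @return A [trial_recording()].
#' @export
read_marker_csv <- function(path, rate_hz = 100, protocol = "fmap",
                            trial_index = 1L, subject_meta = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "marker", "x", "y", "z", "valid")
  if (!all(need %in% names(df))) stop("marker CSV needs columns: ", paste(need, collapse = ", "))
  markers <- lapply(split(df, df$marker), function(d) {
    d <- d[order(d$frame), ]
    marker_series(d$marker[1], cbind(d$x, d$y, d$z), as.logical(d$valid), rate_hz)
  })
  trial_recording(markers, protocol = protocol, trial_index = trial_index,
                  subject_meta = subject_meta)
}

#' Read a pressure-mat CSV export
#'
#' The dialect has a COP table (`frame, cop_ap_mm, cop_ml_mm`) optionally
#' followed by a blank line and a footfall table
#' (`foot, on_frame, off_frame, cx_mm, cy_mm`). Footfalls are sorted by
#' `on_frame`; rows with `off_frame <= on_frame` are skipped with a
#' warning. The mat's native orientation relative to the walking direction
#' is hardware configuration, so an explicit `swap_axes` flag is exposed
#' instead of guessing.
#'
#' @param path Path to the CSV export.
#' @param rate_hz Sampling rate, Hz.
#' @param swap_axes If `TRUE`, the file's two COP columns are interpreted
#'   as (ML, AP) and swapped into canonical (AP, ML) order.
#' @return A [mat_recording()].
#' @export
read_gaitmat_export <- function(path, rate_hz = 100, swap_axes = FALSE) {
  lines <- readLines(path)
  ff_at <- grep("^\\s*foot\\s*,", lines)
  if (length(ff_at)) {
    cop_lines <- lines[seq_len(ff_at[1] - 1)]
    cop_lines <- cop_lines[nzchar(trimws(cop_lines))]
    ff_lines <- lines[ff_at[1]:length(lines)]
  } else {
    cop_lines <- lines[nzchar(trimws(lines))]
    ff_lines <- character(0)
  }
  cop_df <- utils::read.csv(text = paste(cop_lines, collapse = "\n"),
                            stringsAsFactors = FALSE)
  if (!all(c("cop_ap_mm", "cop_ml_mm") %in% names(cop_df)))
    stop("mat export must have cop_ap_mm and cop_ml_mm columns")
  cop <- cbind(cop_df$cop_ap_mm, cop_df$cop_ml_mm)
  if (swap_axes) cop <- cop[, 2:1, drop = FALSE]
  footfalls <- NULL
  if (length(ff_lines)) {
    ff <- utils::read.csv(text = paste(ff_lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
    ok <- !is.na(ff$on_frame) & !is.na(ff$off_frame) & ff$foot %in% c("L", "R")
    if (any(!ok)) {
      warning(sprintf("skipping %d malformed footfall row(s)", sum(!ok)))
      ff <- ff[ok, , drop = FALSE]
    }
    footfalls <- ff
  }
  mat_recording(cop, footfalls, rate_hz = rate_hz)
}

#' Write a pressure-mat recording in the CSV export dialect
#'
#' @param mat A [mat_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaitmat_export <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cop_df <- data.frame(frame = seq_len(nrow(mat$cop)) - 1L,
                       cop_ap_mm = mat$cop[, 1], cop_ml_mm = mat$cop[, 2])
  utils::write.csv(cop_df, con, row.names = FALSE, quote = FALSE)
  if (nrow(mat$footfalls)) {
    writeLines("", con)
    ff <- mat$footfalls[, c("foot", "on_frame", "off_frame", "cx_mm", "cy_mm")]
    utils::write.csv(ff, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
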