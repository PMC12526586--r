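# Minimal C3D reader/writer.
#
# C3D is the interchange container for optical motion capture. This
# implementation covers the subset the pipeline needs: little-endian
# (Intel) files, 3D point data with residuals, no analog channels. Both
# 16-bit-integer and floating-point point storage are read; files are
# written in floating point with residuals. Positions are exposed in
# meters regardless of the file's POINT:UNITS ("mm" converted by 1/1000).
# Frames whose residual is negative are mapped to valid_mask = FALSE.

read_u8 <- function(con, n = 1) readBin(con, "integer", n, size = 1, signed = FALSE)
read_i8 <- function(con, n = 1) readBin(con, "integer", n, size = 1, signed = TRUE)
read_i16 <- function(con, n = 1) readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little")
read_f32 <- function(con, n = 1) readBin(con, "double", n, size = 4, endian = "little")

#' Read a C3D motion-capture trial
#'
#' Parses the point data of a little-endian C3D file into a
#' [trial_recording()]. Marker labels are matched against the segment
#' model's vocabulary; unknown labels are retained under their raw name
#' with a warning. Positions are converted to meters and occluded frames
#' (negative residuals) are masked invalid.
#'
#' @param path Path to a C3D file.
#' @param model A [segment_model()] providing the expected marker
#'   vocabulary; defaults to [default_segment_model()].
#' @param protocol,trial_index,subject_meta Passed to [trial_recording()].
#' @return A [trial_recording()].
#' @export
read_c3d_trial <- function(path, model = default_segment_model(),
                           protocol = "fmap", trial_index = 1L,
                           subject_meta = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  param_block <- read_u8(con)
  magic <- read_u8(con)
  if (!identical(magic, 80L)) stop("not a C3D file (missing 0x50 magic byte)")
  n_points <- read_i16(con)
  read_i16(con)                      # analog samples per frame (ignored)
  first_frame <- read_i16(con)
  last_frame <- read_i16(con)
  read_i16(con)                      # max interpolation gap
  hdr_scale <- read_f32(con)
  data_block <- read_i16(con)
  read_i16(con)                      # analog rate divisor
  hdr_rate <- read_f32(con)

  # --- parameter section ---
  seek(con, (param_block - 1) * 512)
  read_u8(con, 2)
  read_u8(con)                       # parameter block count
  proc <- read_u8(con)
  if (proc != 84) stop("only Intel (little-endian) C3D files are supported")
  params <- list()
  repeat {
    nl <- read_i8(con)
    if (length(nl) == 0) break
    id <- read_i8(con)
    if (length(id) == 0 || (nl == 0 && id == 0)) break
    name <- rawToChar(readBin(con, "raw", abs(nl)))
    offset <- read_i16(con)
    here <- seek(con)                # next entry = here + offset
    if (id < 0) {                    # group: skip description
      dl <- read_u8(con)
      if (dl > 0) readBin(con, "raw", dl)
    } else {                         # parameter
      type <- read_i8(con)
      ndim <- read_u8(con)
      dims <- if (ndim > 0) read_u8(con, ndim) else integer(0)
      count <- if (length(dims)) prod(dims) else 1L
      value <- switch(as.character(type),
        "-1" = rawToChar(readBin(con, "raw", count)),
        "1"  = read_i8(con, count),
        "2"  = read_i16(con, count),
        "4"  = read_f32(con, count),
        stop("unsupported C3D parameter type: ", type))
      params[[toupper(name)]] <- list(value = value, dims = dims, type = type)
    }
    if (offset == 0) break
    seek(con, here + offset)
  }

  p <- function(nm, default = NULL) {
    v <- params[[nm]]
    if (is.null(v)) default else v$value
  }
  n_points <- as.integer(p("USED", n_points))
  n_fr <- as.integer(p("FRAMES", last_frame - first_frame + 1L))
  rate <- as.numeric(p("RATE", hdr_rate))
  scale <- as.numeric(p("SCALE", hdr_scale))
  data_block <- as.integer(p("DATA_START", data_block))
  units <- trimws(p("UNITS", "mm"))
  units <- substr(units, 1, 2)
  labels <- character(n_points)
  lp <- params[["LABELS"]]
  if (!is.null(lp) && length(lp$dims) == 2) {
    w <- lp$dims[1]
    for (i in seq_len(min(n_points, lp$dims[2])))
      labels[i] <- trimws(substr(lp$value, (i - 1) * w + 1, i * w))
  }
  labels[labels == ""] <- paste0("PT", which(labels == ""))

  # --- point data ---
  seek(con, (data_block - 1) * 512)
  is_float <- scale < 0
  if (is_float) {
    raw <- read_f32(con, n_fr * n_points * 4)
  } else {
    raw <- as.numeric(read_i16(con, n_fr * n_points * 4))
  }
  if (length(raw) < n_fr * n_points * 4) stop("truncated C3D point data")
  arr <- array(raw, dim = c(4, n_points, n_fr))
  to_m <- if (identical(units, "m")) 1 else 1 / 1000
  pos_scale <- if (is_float) 1 else abs(scale)

  known <- unique(unlist(model$segments))
  markers <- list()
  for (i in seq_len(n_points)) {
    lbl <- labels[i]
    if (!lbl %in% known)
      warning(sprintf("unknown marker label '%s' retained with raw name", lbl))
    xyz <- t(arr[1:3, i, ]) * pos_scale * to_m
    resid <- arr[4, i, ]
    valid <- resid >= 0
    xyz[!valid, ] <- NA_real_
    markers[[lbl]] <- marker_series(lbl, xyz, valid, rate)
  }
  trial_recording(markers, mat = NULL, protocol = protocol,
                  trial_index = trial_index, subject_meta = subject_meta)
}

# --- writer helpers ---
w_u8 <- function(con, x) writeBin(as.raw(x), con)
w_i16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
w_f32 <- function(con, x) writeBin(as.numeric(x), con, size = 4, endian = "little")

w_param <- function(con, name, group_id, type, dims, payload_writer, last = FALSE) {
  w_u8(con, nchar(name)); w_u8(con, group_id)
  writeBin(charToRaw(name), con)
  sizes <- c("-1" = 1L, "1" = 1L, "2" = 2L, "4" = 4L)
  dlen <- sizes[[as.character(type)]] * max(1L, if (length(dims)) prod(dims) else 1L)
  body <- 1L + 1L + length(dims) + dlen + 1L        # type+ndim+dims+data+desclen
  w_i16(con, if (last) 0L else body)
  w_u8(con, bitwAnd(type, 255L))     # signed byte via two's complement
  w_u8(con, length(dims))
  if (length(dims)) w_u8(con, dims)
  payload_writer(con)
  w_u8(con, 0L)                      # empty description
}

#' Write a trial's markers to a C3D file
#'
#' Floating-point little-endian point data with residuals (-1 on invalid
#' frames), positions stored in millimeters with `POINT:UNITS = "mm"`.
#' Round-trips through [read_c3d_trial()] within 1e-6 m.
#'
#' @param trial A [trial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_c3d_trial <- function(trial, path) {
  labels <- names(trial$markers)
  n_pt <- length(labels)
  n_fr <- n_frames(trial)
  rate <- trial_rate(trial)
  if (n_fr > 32767) stop("C3D 16-bit frame counter limits trials to 32767 frames")

  lab_w <- max(4L, max(nchar(labels)))
  padded <- vapply(labels, function(l) formatC(l, width = lab_w, flag = "-"), "")

  con <- file(path, "wb")
  on.exit(close(con))
  # header block
  w_u8(con, 2); w_u8(con, 80)
  w_i16(con, n_pt); w_i16(con, 0)
  w_i16(con, 1); w_i16(con, n_fr)
  w_i16(con, 10)
  w_f32(con, -1)                     # negative scale: float data
  data_block <- 4L                   # header 1 + two parameter blocks
  w_i16(con, data_block); w_i16(con, 1)
  w_f32(con, rate)
  writeBin(raw(512 - seek(con)), con)

  # parameter section (2 blocks reserved)
  w_u8(con, 1); w_u8(con, 80); w_u8(con, 2); w_u8(con, 84)
  w_u8(con, 5); w_u8(con, 256 - 1)   # group POINT, id -1
  writeBin(charToRaw("POINT"), con)
  w_i16(con, 1); w_u8(con, 0)        # offset past the empty description
  w_param(con, "USED", 1, 2, integer(0), function(c) w_i16(c, n_pt))
  w_param(con, "FRAMES", 1, 2, integer(0), function(c) w_i16(c, n_fr))
  w_param(con, "RATE", 1, 4, integer(0), function(c) w_f32(c, rate))
  w_param(con, "SCALE", 1, 4, integer(0), function(c) w_f32(c, -1))
  w_param(con, "DATA_START", 1, 2, integer(0), function(c) w_i16(c, data_block))
  w_param(con, "UNITS", 1, -1, 2L, function(c) writeBin(charToRaw("mm"), c))
  w_param(con, "LABELS", 1, -1, c(lab_w, n_pt),
          function(c) writeBin(charToRaw(paste(padded, collapse = "")), c),
          last = TRUE)
  pad <- 3L * 512L - seek(con)
  if (pad < 0) stop("parameter section overflow")
  writeBin(raw(pad), con)

  # point data, frame-major
  arr <- array(0, dim = c(4, n_pt, n_fr))
  for (i in seq_len(n_pt)) {
    m <- trial$markers[[i]]
    xyz <- t(m$positions) * 1000     # meters -> mm
    xyz[, !m$valid_mask] <- 0
    arr[1:3, i, ] <- xyz
    arr[4, i, ] <- ifelse(m$valid_mask, 0, -1)
  }
  w_f32(con, as.numeric(arr))
  invisible(path)
}
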