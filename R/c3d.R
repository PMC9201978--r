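# Minimal C3D support (Intel/PC processor type, the overwhelmingly common
# variant). Covers what a marker-only gait trial needs: the POINT group
# (LABELS, RATE, SCALE, UNITS, DATA_START), float or scaled-integer 3D
# samples, and per-sample residuals (negative residual = invalid/occluded).
# Analog channels, multi-byte-order files and EMG/force data are ignored.

.c3d_block <- 512L

.read_c3d_raw <- function(path) readBin(path, "raw", n = file.info(path)$size)

.raw_int16 <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L, endian = "little")
}
.raw_uint8 <- function(raw, off) as.integer(raw[off + 1L])
.raw_int8 <- function(raw, off) {
  v <- as.integer(raw[off + 1L]); if (v > 127L) v - 256L else v
}
.raw_float <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 4L)], "double", size = 4L, endian = "little")
}
.raw_string <- function(raw, off, n) {
  if (n <= 0L) return("")
  rawToChar(raw[(off + 1L):(off + n)])
}

# Parse the parameter section into list(groups = name->id, params =
# list("GROUP:PARAM" -> value)). Only char/int16/float scalars and arrays
# are materialized.
.parse_c3d_params <- function(raw, start_off) {
  proc <- .raw_uint8(raw, start_off + 3L)
  if (proc != 84L) stop("unsupported C3D processor type ", proc,
                        " (only Intel/PC = 84 supported)")
  groups <- list()
  params <- list()
  off <- start_off + 4L
  repeat {
    nname <- .raw_int8(raw, off)
    if (nname == 0L) break
    id <- .raw_int8(raw, off + 1L)
    if (id == 0L) break
    name <- toupper(.raw_string(raw, off + 2L, abs(nname)))
    p <- off + 2L + abs(nname)
    next_off <- .raw_int16(raw, p)
    body <- p + 2L
    if (id < 0L) {
      groups[[name]] <- -id
    } else {
      type <- .raw_int8(raw, body)
      ndim <- .raw_uint8(raw, body + 1L)
      dims <- integer(0)
      if (ndim > 0L) {
        dims <- vapply(seq_len(ndim) - 1L,
                       function(k) .raw_uint8(raw, body + 2L + k), integer(1))
      }
      dat_off <- body + 2L + ndim
      nel <- if (length(dims)) prod(dims) else 1L
      value <- switch(as.character(type),
        "-1" = {
          s <- .raw_string(raw, dat_off, nel)
          if (length(dims) >= 2L) {
            substring(s, seq(1L, nel, by = dims[1]),
                      seq(dims[1], nel, by = dims[1]))
          } else s
        },
        "1" = vapply(seq_len(nel) - 1L,
                     function(k) .raw_int8(raw, dat_off + k), integer(1)),
        "2" = vapply(seq_len(nel) - 1L,
                     function(k) .raw_int16(raw, dat_off + 2L * k), integer(1)),
        "4" = vapply(seq_len(nel) - 1L,
                     function(k) .raw_float(raw, dat_off + 4L * k), numeric(1)),
        stop("unknown C3D parameter type ", type))
      params[[paste0("G", id, ":", name)]] <- value
    }
    if (next_off == 0L) break
    off <- p + next_off
  }
  list(groups = groups, params = params)
}

#' Read a C3D motion-capture file
#'
#' Reads the 3D point section of a C3D file into a [marker_trial()].
#' Positions are converted to meters using the declared `POINT:UNITS`
#' (defaulting to millimeters when absent, the usual C3D convention).
#' Samples with a negative residual are flagged invalid. Analog/EMG/force
#' channels are ignored. Only Intel-byte-order files are supported.
#'
#' @param path path to the `.c3d` file.
#' @param trial_id identifier (defaults to the file name).
#' @param vertical laboratory up direction of the stored coordinates.
#' @return a [marker_trial()].
#' @export
read_c3d_trial <- function(path, trial_id = NULL, vertical = c(0, 0, 1)) {
  if (is.null(trial_id)) trial_id <- sub("\\.[^.]+$", "", basename(path))
  raw <- .read_c3d_raw(path)
  param_block <- .raw_uint8(raw, 0L)
  if (.raw_uint8(raw, 1L) != 80L) stop("'", path, "' is not a C3D file")
  n_points <- .raw_int16(raw, 2L)
  n_analog <- .raw_int16(raw, 4L)
  first_frame <- .raw_int16(raw, 6L)
  last_frame <- .raw_int16(raw, 8L)
  scale <- .raw_float(raw, 12L)
  data_block <- .raw_int16(raw, 16L)
  analog_per_frame <- .raw_int16(raw, 18L)
  rate <- .raw_float(raw, 20L)
  pp <- .parse_c3d_params(raw, (param_block - 1L) * .c3d_block)
  pid <- pp$groups[["POINT"]]
  gp <- function(name, default = NULL) {
    v <- pp$params[[paste0("G", pid, ":", name)]]
    if (is.null(v)) default else v
  }
  if (!is.null(pid)) {
    scale <- gp("SCALE", scale)[1]
    rate <- gp("RATE", rate)[1]
    data_block <- gp("DATA_START", data_block)[1]
    n_points <- gp("USED", n_points)[1]
  }
  labels <- if (!is.null(pid)) trimws(gp("LABELS", character(0))) else character(0)
  if (length(labels) < n_points) {
    labels <- c(labels, paste0("PT", seq_len(n_points - length(labels))))
  }
  labels <- labels[seq_len(n_points)]
  units <- if (!is.null(pid)) trimws(gp("UNITS", "mm")[1]) else "mm"
  to_m <- switch(tolower(units), m = 1, mm = 1e-3, cm = 1e-2, 1e-3)
  n_frames <- last_frame - first_frame + 1L
  off <- (data_block - 1L) * .c3d_block
  # analog channels are ignored but still occupy space in each frame record
  analog_words <- n_analog * max(1L, analog_per_frame)
  if (scale < 0) {
    total <- n_frames * (4L * n_points + analog_words)
    v <- readBin(raw[(off + 1L):(off + 4L * total)], "double", n = total,
                 size = 4L, endian = "little")
    stride <- 4L * n_points + analog_words
  } else {
    total <- n_frames * (4L * n_points + analog_words)
    v <- readBin(raw[(off + 1L):(off + 2L * total)], "integer", n = total,
                 size = 2L, endian = "little")
    stride <- 4L * n_points + analog_words
  }
  trajectories <- list()
  valid <- list()
  for (j in seq_len(n_points)) {
    base <- (j - 1L) * 4L
    idx <- rep(seq(0L, by = stride, length.out = n_frames), each = 1L)
    xyz <- cbind(v[idx + base + 1L], v[idx + base + 2L], v[idx + base + 3L])
    res <- v[idx + base + 4L]
    if (scale >= 0) {
      xyz <- xyz * scale
      res <- res * abs(scale)
    }
    ok <- res >= 0
    xyz <- xyz * to_m
    xyz[!ok, ] <- NA_real_
    nm <- labels[j]
    if (nm %in% names(trajectories)) nm <- paste0(nm, "_", j)
    trajectories[[nm]] <- xyz
    valid[[nm]] <- ok
  }
  keep <- intersect(.known_markers, names(trajectories))
  extra <- setdiff(names(trajectories), keep)
  trajectories <- trajectories[c(keep, extra)]
  valid <- valid[c(keep, extra)]
  time <- (seq_len(n_frames) - 1L) / rate
  marker_trial(trial_id, rate, time, trajectories, valid = valid,
               vertical = vertical)
}

#' Write a marker trial as a minimal C3D file
#'
#' Writes an Intel-byte-order, float-data C3D with a single POINT parameter
#' group. Mainly intended for interoperability checks and for generating
#' fixtures; occluded samples get residual -1.
#'
#' @param trial a [marker_trial()].
#' @param path output path.
#' @param units `"mm"` (default, positions multiplied by 1000 on disk) or
#'   `"m"`.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(trial, path, units = c("mm", "m")) {
  units <- match.arg(units)
  mult <- if (units == "mm") 1000 else 1
  markers <- names(trial$trajectories)
  n_points <- length(markers)
  n_frames <- length(trial$time)
  lab_w <- max(nchar(markers), 4L)
  labels_flat <- paste0(vapply(markers, function(s)
    formatC(s, width = lab_w, flag = "-"), character(1)), collapse = "")

  con <- file(path, "wb")
  on.exit(close(con))
  w8 <- function(x) writeBin(as.integer(x), con, size = 1L)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wchar <- function(s) writeBin(charToRaw(s), con)

  data_block <- 3L  # header=1, params=2 (assume params fit in one block)
  # --- header block
  w8(2L); w8(80L)           # param pointer, magic
  w16(n_points); w16(0L)    # points, analog per frame
  w16(1L); w16(n_frames)    # first, last frame
  w16(10L)                  # max gap
  wf(-1.0)                  # scale (negative -> float data)
  w16(data_block); w16(0L)  # data start, analog samples/frame
  wf(trial$sampling_rate)
  pad <- .c3d_block - 24L
  writeBin(raw(pad), con)

  # --- parameter section (block 2)
  psec <- local({
    buf <- raw(0)
    add8 <- function(x) { r <- as.raw(bitwAnd(as.integer(x) + 256L, 255L)); buf <<- c(buf, r) }
    add16 <- function(x) buf <<- c(buf, writeBin(as.integer(x), raw(), size = 2L, endian = "little"))
    addf <- function(x) buf <<- c(buf, writeBin(as.numeric(x), raw(), size = 4L, endian = "little"))
    addstr <- function(s) buf <<- c(buf, charToRaw(s))
    group <- function(name, id) {
      add8(nchar(name)); add8(-id); addstr(name)
      add16(3L); add8(0L)  # offset to next record, empty description
    }
    param <- function(name, id, type, dims, writer) {
      add8(nchar(name)); add8(id); addstr(name)
      elsize <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)[[as.character(type)]]
      ndata <- if (length(dims)) prod(dims) * elsize else elsize
      add16(2L + 1L + 1L + length(dims) + ndata + 1L)
      add8(type); add8(length(dims))
      for (d in dims) add8(d)
      writer()
      add8(0L)  # description length
    }
    add8(1L); add8(80L)  # section header
    add8(1L)             # parameter blocks
    add8(84L)            # processor: Intel
    group("POINT", 1L)
    param("USED", 1L, 2L, integer(0), function() add16(n_points))
    param("FRAMES", 1L, 2L, integer(0), function() add16(n_frames))
    param("RATE", 1L, 4L, integer(0), function() addf(trial$sampling_rate))
    param("SCALE", 1L, 4L, integer(0), function() addf(-1.0))
    param("DATA_START", 1L, 2L, integer(0), function() add16(data_block))
    param("UNITS", 1L, -1L, nchar(units), function() addstr(units))
    param("LABELS", 1L, -1L, c(lab_w, n_points),
          function() addstr(labels_flat))
    add8(0L); add8(0L)   # terminator
    buf
  })
  if (length(psec) > .c3d_block) stop("parameter section exceeds one block")
  writeBin(psec, con)
  writeBin(raw(.c3d_block - length(psec)), con)

  # --- point data
  frame_vals <- matrix(0, nrow = 4L * n_points, ncol = n_frames)
  for (j in seq_len(n_points)) {
    pos <- trial$trajectories[[markers[j]]] * mult
    ok <- trial$valid[[markers[j]]]
    pos[!ok, ] <- 0
    frame_vals[(j - 1L) * 4L + 1L, ] <- pos[, 1]
    frame_vals[(j - 1L) * 4L + 2L, ] <- pos[, 2]
    frame_vals[(j - 1L) * 4L + 3L, ] <- pos[, 3]
    frame_vals[(j - 1L) * 4L + 4L, ] <- ifelse(ok, 0, -1)
  }
  wf(as.numeric(frame_vals))
  invisible(path)
}
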