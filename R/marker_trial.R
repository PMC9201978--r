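#' Marker-trial container
#'
#' A `marker_trial` holds time-stamped 3D trajectories for the bilateral
#' heel/toe marker set (`LHEEL`, `RHEEL`, `LTOE`, `RTOE`) and, optionally,
#' the four pelvis cluster markers `P0`--`P3`, together with per-marker
#' validity masks (FALSE = occluded/missing sample). Positions are in
#' meters, time in seconds, sampled uniformly.
#'
#' @param trial_id character scalar identifying the trial.
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param time numeric vector of sample times (seconds), strictly increasing
#'   with constant step `1/sampling_rate`.
#' @param trajectories named list of N x 3 numeric matrices (meters), one per
#'   marker. Foot markers are mandatory; pelvis markers optional.
#' @param valid named list of logical vectors (length N), one per marker;
#'   if omitted, derived from finiteness of the positions.
#' @param vertical unit 3-vector giving the laboratory vertical (up)
#'   direction of the coordinate data; defaults to `c(0, 0, 1)`.
#' @return an object of class `marker_trial`.
#' @export
marker_trial <- function(trial_id, sampling_rate, time, trajectories,
                         valid = NULL, vertical = c(0, 0, 1)) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L,
            is.numeric(sampling_rate), sampling_rate > 0)
  n <- length(time)
  trajectories <- lapply(trajectories, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  if (is.null(valid)) {
    valid <- lapply(trajectories, function(m) apply(is.finite(m), 1L, all))
  }
  x <- structure(list(trial_id = trial_id,
                      sampling_rate = as.numeric(sampling_rate),
                      time = as.numeric(time),
                      trajectories = trajectories,
                      valid = valid,
                      vertical = vertical / sqrt(sum(vertical^2))),
                 class = "marker_trial")
  validate_marker_trial(x)
}

#' Validate a marker trial
#'
#' Checks the structural invariants: shared length N, uniform time base,
#' finite positions wherever marked valid, and presence of the four foot
#' markers.
#'
#' @param x a `marker_trial`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_marker_trial <- function(x) {
  n <- length(x$time)
  foot <- c("LHEEL", "RHEEL", "LTOE", "RTOE")
  missing_foot <- setdiff(foot, names(x$trajectories))
  if (length(missing_foot)) {
    stop("missing required foot marker(s): ", paste(missing_foot, collapse = ", "))
  }
  for (nm in names(x$trajectories)) {
    m <- x$trajectories[[nm]]
    if (nrow(m) != n || ncol(m) != 3L) {
      stop("trajectory '", nm, "' must be N x 3 with N = length(time)")
    }
    v <- x$valid[[nm]]
    if (length(v) != n) stop("valid mask for '", nm, "' has wrong length")
    if (any(v & !apply(is.finite(m), 1L, all))) {
      stop("non-finite position marked valid for marker '", nm, "'")
    }
  }
  if (n > 1L) {
    dt <- diff(x$time)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (any(abs(dt - 1 / x$sampling_rate) > 1e-6)) {
      stop("time step inconsistent with sampling_rate (tolerance 1e-6 s)")
    }
  }
  x
}

#' @export
print.marker_trial <- function(x, ...) {
  cat("marker_trial '", x$trial_id, "': ", length(x$time), " frames @ ",
      x$sampling_rate, " Hz, markers: ",
      paste(names(x$trajectories), collapse = ", "), "\n", sep = "")
  occl <- vapply(x$valid, function(v) sum(!v), integer(1))
  if (any(occl > 0)) {
    cat("  occluded samples:",
        paste(sprintf("%s=%d", names(occl)[occl > 0], occl[occl > 0]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Does the trial carry a usable pelvis cluster?
#' @param trial a `marker_trial`.
#' @return TRUE if P0, P1 and P3 are present.
#' @export
has_pelvis <- function(trial) {
  all(c("P0", "P1", "P3") %in% names(trial$trajectories))
}

.known_markers <- c("LHEEL", "RHEEL", "LTOE", "RTOE", "P0", "P1", "P2", "P3")

#' Read a marker trial from file
#'
#' Reads 3D marker trajectories from either a C3D file or the package's CSV
#' dialect (one row per frame; a `time_s` column followed by
#' `<MARKER>_x/_y/_z` columns in meters; missing samples as empty cells or
#' NaN). C3D positions are converted to meters using the file's declared
#' `POINT:UNITS` (defaulting to millimeters, the common C3D convention);
#' CSV files are taken to be in meters already.
#'
#' @param path path to the file.
#' @param format `"c3d"` or `"csv"`; guessed from the file extension by
#'   default.
#' @param trial_id identifier; defaults to the file name without extension.
#' @param vertical laboratory up direction of the stored coordinates.
#' @return a [marker_trial()].
#' @export
read_trial <- function(path, format = c("auto", "csv", "c3d"),
                       trial_id = NULL, vertical = c(0, 0, 1)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.c3d$", path, ignore.case = TRUE)) "c3d" else "csv"
  }
  if (is.null(trial_id)) trial_id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "c3d") return(read_c3d_trial(path, trial_id = trial_id,
                                             vertical = vertical))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("unparseable CSV '", path, "': ",
                                          conditionMessage(e)))
  if (!"time_s" %in% names(df)) stop("CSV '", path, "' lacks a time_s column")
  time <- as.numeric(df$time_s)
  cols <- names(df)
  markers <- unique(sub("_[xyz]$", "", grep("_[xyz]$", cols, value = TRUE)))
  trajectories <- list()
  for (m in markers) {
    need <- paste0(m, "_", c("x", "y", "z"))
    if (!all(need %in% cols)) {
      stop("CSV '", path, "': marker ", m, " lacks one of ",
           paste(need, collapse = "/"))
    }
    trajectories[[m]] <- cbind(as.numeric(df[[need[1]]]),
                               as.numeric(df[[need[2]]]),
                               as.numeric(df[[need[3]]]))
  }
  fs <- 1 / stats::median(diff(time))
  marker_trial(trial_id, round(fs, 6), time, trajectories,
               vertical = vertical)
}

#' Write a marker trial in the CSV dialect
#'
#' @param trial a [marker_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(time_s = trial$time)
  for (m in names(trial$trajectories)) {
    pos <- trial$trajectories[[m]]
    pos[!trial$valid[[m]], ] <- NA_real_
    df[[paste0(m, "_x")]] <- pos[, 1]
    df[[paste0(m, "_y")]] <- pos[, 2]
    df[[paste0(m, "_z")]] <- pos[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NaN")
  invisible(path)
}

#' Gait-event tables
#'
#' Construct an ordered, side/type-labeled gait-event table. Events carry
#' the contact time (seconds), the 0-based frame index
#' (`round(time * sampling_rate)`), the side (`L`/`R`), the type (`IC`
#' initial contact / `FC` final contact), the foot-strike pattern where the
#' detector can tell (`rearfoot`/`forefoot`/`unknown`), the walking
#' condition label (`SW`/`CW`/`SN`/`unlabeled`) and the producing method.
#'
#' @param time event times in seconds.
#' @param side `"L"` or `"R"` per event.
#' @param type `"IC"` or `"FC"` per event.
#' @param sampling_rate Hz, used to derive the frame index.
#' @param foot_strike,condition,method optional per-event annotations.
#' @param frame optional explicit 0-based frame indices.
#' @return a `data.frame` of class `gait_events`, ordered by time.
#' @export
gait_events <- function(time = numeric(0), side = character(0),
                        type = character(0), sampling_rate = 100,
                        foot_strike = "unknown", condition = "unlabeled",
                        method = NA_character_, frame = NULL) {
  n <- length(time)
  if (is.null(frame)) frame <- as.integer(round(time * sampling_rate))
  df <- data.frame(side = rep_len(as.character(side), n),
                   type = rep_len(as.character(type), n),
                   time = as.numeric(time),
                   frame = as.integer(rep_len(frame, n)),
                   foot_strike = rep_len(as.character(foot_strike), n),
                   condition = rep_len(as.character(condition), n),
                   method = rep_len(as.character(method), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time, df$side, df$type), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gait_events", "data.frame")
  df
}

#' Write / read gait-event tables
#'
#' The CSV has columns `side,type,time_s,frame,condition,foot_strike,method`
#' with times printed to microsecond precision; `read_events(write_events(x))`
#' reproduces the table (times to 1e-6 s, other fields exactly).
#'
#' @param events a [gait_events()] table.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `gait_events` table.
#' @export
write_events <- function(events, path) {
  df <- data.frame(side = events$side, type = events$type,
                   time_s = sprintf("%.6f", events$time),
                   frame = events$frame, condition = events$condition,
                   foot_strike = events$foot_strike, method = events$method)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write events to '", path, "'")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(side = "character",
                                       type = "character",
                                       method = "character"))
  gait_events(time = df$time_s, side = df$side, type = df$type,
              foot_strike = df$foot_strike, condition = df$condition,
              method = df$method, frame = df$frame)
}

#' Read a reference gait-event file
#'
#' Reference events (for example from a pressure-insole gold standard) are
#' consumed as input for validation, never computed. The file must have
#' columns `side` (L/R), `type` (IC/FC) and `time_s` (seconds).
#'
#' @param path CSV path.
#' @param method label recorded in the returned table (default `"reference"`).
#' @return a [gait_events()] table.
#' @export
read_reference_events <- function(path, method = "reference") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("side", "type", "time_s")
  if (!all(need %in% names(df))) {
    stop("reference event file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  }
  ev <- gait_events(time = df$time_s, side = df$side, type = df$type,
                    method = method)
  for (s in c("L", "R")) for (ty in c("IC", "FC")) {
    tt <- ev$time[ev$side == s & ev$type == ty]
    if (length(tt) > 1L && any(diff(tt) <= 0)) {
      stop("reference events not strictly increasing for side ", s,
           " type ", ty)
    }
  }
  ev
}

#' Write / read stride-parameter tables
#'
#' @param strides a stride table as produced by [compute_stride_params()].
#' @param path file path.
#' @return `write_strides` returns `path` invisibly; `read_strides` a
#'   stride `data.frame`.
#' @export
write_strides <- function(strides, path) {
  df <- strides
  for (col in c("t_ic_start", "t_fc", "t_ic_end", "duration", "stance",
                "swing", "length", "speed")) {
    if (col %in% names(df)) df[[col]] <- sprintf("%.6f", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_strides
#' @export
read_strides <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("t_ic_start", "t_fc", "t_ic_end", "duration", "stance", "swing",
           "length", "speed")
  for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}
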