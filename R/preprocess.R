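#' Fill short marker gaps by cubic-spline interpolation
#'
#' Interior runs of invalid samples strictly shorter than `max_gap` seconds
#' are interpolated per coordinate with a cubic spline through the valid
#' samples and marked valid. Longer runs and leading/trailing runs are left
#' untouched.
#'
#' @param trial a [marker_trial()].
#' @param max_gap maximum fillable gap, seconds (default 0.5).
#' @return the gap-filled `marker_trial`.
#' @export
fill_gaps <- function(trial, max_gap = 0.5) {
  fs <- trial$sampling_rate
  n <- length(trial$time)
  for (m in names(trial$trajectories)) {
    v <- trial$valid[[m]]
    if (all(v) || !any(v)) next
    runs <- .true_runs(!v)
    pos <- trial$trajectories[[m]]
    for (r in seq_len(nrow(runs))) {
      s <- runs$start[r]; e <- runs$end[r]
      if (s == 1L || e == n) next                  # leading/trailing: keep
      if (runs$length[r] / fs >= max_gap) next     # too long: keep
      idx <- s:e
      for (k in 1:3) {
        pos[idx, k] <- stats::spline(x = trial$time[v], y = pos[v, k],
                                     xout = trial$time[idx],
                                     method = "natural")$y
      }
      trial$valid[[m]][idx] <- TRUE
    }
    trial$trajectories[[m]] <- pos
  }
  trial
}

#' Zero-lag low-pass Butterworth filtering
#'
#' Applies a forward-backward (zero phase lag) Butterworth low-pass filter
#' per coordinate and per contiguous valid segment. Segments too short to
#' support the edge padding are left unfiltered with a warning.
#'
#' @param x numeric vector, N x 3 matrix, or [marker_trial()].
#' @param sampling_rate Hz (taken from the trial when `x` is one).
#' @param cutoff cut-off frequency, Hz (default 7).
#' @param order filter order of each pass (default 4).
#' @param type `"low"` or `"high"`.
#' @param min_segment minimum number of contiguous valid samples a segment
#'   needs to be filtered (default 30).
#' @return object of the same shape as `x`, filtered.
#' @export
lowpass_filter <- function(x, sampling_rate, cutoff = 7, order = 4,
                           type = c("low", "high"), min_segment = 30L) {
  type <- match.arg(type)
  if (inherits(x, "marker_trial")) {
    for (m in names(x$trajectories)) {
      pos <- x$trajectories[[m]]
      pos[!x$valid[[m]], ] <- NA_real_
      x$trajectories[[m]] <- lowpass_filter(pos, x$sampling_rate, cutoff,
                                            order, type, min_segment)
    }
    return(x)
  }
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = type)
  filt1 <- function(vec) {
    out <- vec
    runs <- .true_runs(is.finite(vec))
    for (r in seq_len(nrow(runs))) {
      idx <- runs$start[r]:runs$end[r]
      if (length(idx) < max(min_segment, 3L * order + 4L)) {
        warning("segment of ", length(idx),
                " samples too short to filter; left unfiltered")
        next
      }
      out[idx] <- .filtfilt(bf$b, bf$a, vec[idx])
    }
    out
  }
  if (is.matrix(x)) apply(x, 2L, filt1) else filt1(x)
}

#' Numerical differentiation
#'
#' Central differences in the interior of each contiguous valid segment,
#' one-sided differences at segment edges; exact for polynomials up to
#' degree 2 at interior samples. Apply twice for acceleration, three times
#' for jerk.
#'
#' @param x numeric vector or N x 3 matrix (positions, velocities, ...).
#' @param sampling_rate Hz.
#' @return derivative of `x`, same shape; segments with fewer than 3 valid
#'   samples become all-NA.
#' @export
differentiate <- function(x, sampling_rate) {
  dt <- 1 / sampling_rate
  d1 <- function(vec) {
    out <- rep(NA_real_, length(vec))
    runs <- .true_runs(is.finite(vec))
    for (r in seq_len(nrow(runs))) {
      s <- runs$start[r]; e <- runs$end[r]
      if (e - s + 1L < 3L) next
      idx <- (s + 1L):(e - 1L)
      out[idx] <- (vec[idx + 1L] - vec[idx - 1L]) / (2 * dt)
      out[s] <- (vec[s + 1L] - vec[s]) / dt
      out[e] <- (vec[e] - vec[e - 1L]) / dt
    }
    out
  }
  if (is.matrix(x)) apply(x, 2L, d1) else d1(x)
}

#' Build the per-frame pelvis anatomical frame
#'
#' The medio-lateral axis (ML) is the unit vector from P0 to P1 (pointing
#' right); the anterior-posterior axis (AP) is the unit normal of the plane
#' through P0, P1 and P3, its sign disambiguated by positive projection on
#' the smoothed pelvis-origin velocity (with a 0.05 m/s hysteresis so the
#' sign cannot flutter when the subject is nearly stationary); the vertical
#' axis V = ML x AP is sign-fixed to point cranially (positive projection on
#' the trial's vertical hint). Frames with any of P0/P1/P3 occluded, or with
#' collinear markers, are invalid.
#'
#' @param trial a [marker_trial()] carrying P0, P1 and P3.
#' @param speed_hysteresis m/s; below this origin speed the previous forward
#'   sign is kept.
#' @return an object of class `pelvis_frames`: list with `time`, N x 3
#'   matrices `origin`, `ml`, `ap`, `v`, logical `valid`, the sampling rate
#'   and the vertical hint.
#' @export
build_pelvis_frames <- function(trial, speed_hysteresis = 0.05) {
  if (!has_pelvis(trial)) stop("trial lacks pelvis markers P0, P1, P3")
  n <- length(trial$time)
  fs <- trial$sampling_rate
  p0 <- trial$trajectories$P0
  p1 <- trial$trajectories$P1
  p3 <- trial$trajectories$P3
  valid <- trial$valid$P0 & trial$valid$P1 & trial$valid$P3
  origin <- (p0 + p1) / 2
  ml <- .unit_rows(p1 - p0)
  nrm <- .cross_rows(p1 - p0, p3 - p0)
  nn <- .norm3(nrm)
  degen <- !is.na(nn) & nn < 1e-9
  valid <- valid & !is.na(nn) & !degen
  ap0 <- .unit_rows(nrm)

  # smoothed origin velocity for the forward-sign disambiguation
  vel <- matrix(NA_real_, n, 3L)
  if (any(valid)) {
    runs <- .true_runs(valid)
    osm <- origin
    osm[!valid, ] <- NA_real_
    osm <- suppressWarnings(lowpass_filter(osm, fs, cutoff = 1,
                                           min_segment = 30L))
    vel <- differentiate(osm, fs)
  }
  proj <- rowSums(vel * ap0)
  sgn <- rep(NA_real_, n)
  last <- NA_real_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(proj[i]) && abs(proj[i]) > speed_hysteresis) last <- sign(proj[i])
    sgn[i] <- last
  }
  if (any(valid & is.na(sgn))) {
    # stationary (or short) trial: fall back to the majority confident sign,
    # else assume the stored axis order already points forward
    conf <- proj[valid & !is.na(proj) & abs(proj) > speed_hysteresis]
    fallback <- if (length(conf)) sign(sum(sign(conf))) else 1
    if (fallback == 0) fallback <- 1
    # also backfill frames before the first confident sign
    first_known <- sgn[valid & !is.na(sgn)]
    fill <- if (length(first_known)) first_known[1] else fallback
    sgn[valid & is.na(sgn)] <- fill
  }
  ap <- ap0 * sgn
  v <- .cross_rows(ml, ap)
  up <- matrix(trial$vertical, n, 3L, byrow = TRUE)
  vdot <- rowSums(v * up)
  flip <- stats::median(vdot[valid], na.rm = TRUE) < 0
  if (isTRUE(flip)) v <- -v
  origin[!valid, ] <- NA_real_
  ml[!valid, ] <- NA_real_; ap[!valid, ] <- NA_real_; v[!valid, ] <- NA_real_
  structure(list(time = trial$time, origin = origin, ml = ml, ap = ap, v = v,
                 valid = valid, sampling_rate = fs,
                 vertical = trial$vertical),
            class = "pelvis_frames")
}

#' @export
print.pelvis_frames <- function(x, ...) {
  cat("pelvis_frames: ", length(x$time), " frames, ",
      sum(x$valid), " valid\n", sep = "")
  invisible(x)
}

#' Decompose a 3D series in the pelvis frame
#'
#' Positions are expressed relative to the pelvis origin; velocities and
#' accelerations (already global derivatives) are projected on the frame
#' axes at the same instant, so no spurious terms arise from frame rotation
#' during turns.
#'
#' @param x N x 3 matrix (position, velocity, ...).
#' @param frames a [build_pelvis_frames()] result.
#' @param relative subtract the pelvis origin first (use TRUE for positions,
#'   FALSE for derivatives).
#' @return data.frame with columns `AP`, `ML`, `V` (NA where the frame is
#'   invalid).
#' @export
decompose <- function(x, frames, relative = TRUE) {
  y <- if (relative) x - frames$origin else x
  out <- data.frame(AP = rowSums(y * frames$ap),
                    ML = rowSums(y * frames$ml),
                    V = rowSums(y * frames$v))
  out[!frames$valid, ] <- NA_real_
  out
}
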