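#' Detector parameters
#'
#' Collects every tunable of the ten gait-event detectors. Velocity
#' thresholds are resolved per method: fixed values for M4 (0.5 m/s heel IC,
#' 0.5 m/s toe FC) and M5 (0.5 m/s heel and toe IC, 1.0 m/s toe FC);
#' walking-speed multiples for M6 (0.78 IC, 0.66 FC) and M7 (0.5 heel IC,
#' 0.8 toe IC, 0.8 toe FC). Explicit `th_*` values override the rule.
#'
#' @param method one of `"M1"`..`"M10"`.
#' @param walking_speed m/s, required by M6/M7/M10 (see
#'   [estimate_walking_speed()]).
#' @param th_heel,th_toe_ic,th_toe_fc explicit thresholds in m/s
#'   (overrides).
#' @param fc_window final-contact refinement window, seconds (default 0.1,
#'   centered on the toe-velocity crossing).
#' @param min_event_separation debounce time, seconds (default 0.2).
#' @param m10_match_window fusion matching half window for M10, seconds
#'   (default 0.25).
#' @param m2_highpass high-pass cut-off for M2, Hz.
#' @param m3_height_factor vertical-position gate for M3 (multiple of the
#'   stance-phase baseline height).
#' @param peak_prominence_frac prominence floor for peak-based detectors,
#'   fraction of the signal range.
#' @param jerk_tol_frac M8 jerk gate, fraction of the trial's jerk RMS.
#' @return a list of class `detector_params`.
#' @export
detector_params <- function(method = "M10", walking_speed = NULL,
                            th_heel = NULL, th_toe_ic = NULL,
                            th_toe_fc = NULL, fc_window = 0.1,
                            min_event_separation = 0.2,
                            m10_match_window = 0.25, m2_highpass = 0.5,
                            m3_height_factor = 1.3,
                            peak_prominence_frac = 0.01,
                            jerk_tol_frac = 0.05) {
  method <- match.arg(method, paste0("M", 1:10))
  ws <- walking_speed
  # unresolved adaptive thresholds stay NA here; detectors raise the error
  # at run time once estimate_walking_speed() has had its chance
  resolve <- function(given, fixed, mult) {
    if (!is.null(given)) return(given)
    if (!is.null(fixed)) return(fixed)
    if (is.null(ws)) return(NA_real_)
    mult * ws
  }
  th <- switch(method,
    M4 = list(heel = resolve(th_heel, 0.5, NA), toe_ic = NA_real_,
              toe_fc = resolve(th_toe_fc, 0.5, NA)),
    M5 = list(heel = resolve(th_heel, 0.5, NA),
              toe_ic = resolve(th_toe_ic, 0.5, NA),
              toe_fc = resolve(th_toe_fc, 1.0, NA)),
    M6 = list(heel = resolve(th_heel, NULL, 0.78), toe_ic = NA_real_,
              toe_fc = resolve(th_toe_fc, NULL, 0.66)),
    M7 = list(heel = resolve(th_heel, NULL, 0.5),
              toe_ic = resolve(th_toe_ic, NULL, 0.8),
              toe_fc = resolve(th_toe_fc, NULL, 0.8)),
    list(heel = th_heel %||% NA_real_, toe_ic = th_toe_ic %||% NA_real_,
         toe_fc = th_toe_fc %||% NA_real_))
  structure(list(method = method, walking_speed = ws,
                 th_heel = th$heel, th_toe_ic = th$toe_ic,
                 th_toe_fc = th$toe_fc, fc_window = fc_window,
                 min_event_separation = min_event_separation,
                 m10_match_window = m10_match_window,
                 m2_highpass = m2_highpass,
                 m3_height_factor = m3_height_factor,
                 peak_prominence_frac = peak_prominence_frac,
                 jerk_tol_frac = jerk_tol_frac),
            class = "detector_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precompute filtered kinematics shared by the detectors
#'
#' Gap-fills, low-pass filters (7 Hz zero-lag Butterworth), differentiates
#' the foot markers up to jerk, and builds the pelvis frames when the
#' pelvis cluster is present. Detectors accept the result through their
#' `prep` argument so repeated calls on one trial do not recompute it.
#'
#' @param trial a [marker_trial()].
#' @param cutoff low-pass cut-off, Hz.
#' @return a list of class `trial_prep`.
#' @export
prepare_trial <- function(trial, cutoff = 7) {
  trial <- fill_gaps(trial)
  fs <- trial$sampling_rate
  filtered <- suppressWarnings(lowpass_filter(trial, cutoff = cutoff))
  feet <- c("LHEEL", "RHEEL", "LTOE", "RTOE")
  fpos <- vel <- acc <- jerk <- speed <- list()
  for (m in feet) {
    fpos[[m]] <- filtered$trajectories[[m]]
    vel[[m]] <- differentiate(fpos[[m]], fs)
    acc[[m]] <- differentiate(vel[[m]], fs)
    jerk[[m]] <- differentiate(acc[[m]], fs)
    speed[[m]] <- .norm3(vel[[m]])
  }
  frames <- if (has_pelvis(trial)) {
    tryCatch(build_pelvis_frames(filtered), error = function(e) NULL)
  } else NULL
  structure(list(trial = trial, fs = fs, time = trial$time, fpos = fpos,
                 vel = vel, acc = acc, jerk = jerk, speed = speed,
                 frames = frames, vertical = trial$vertical),
            class = "trial_prep")
}

.as_prep <- function(trial, prep) {
  if (!is.null(prep)) prep else prepare_trial(trial)
}

.height <- function(prep, marker) {
  drop(prep$fpos[[marker]] %*% prep$vertical)
}

# horizontal-plane projection of an N x 3 matrix
.horizontal <- function(m, vertical) {
  m - outer(drop(m %*% vertical), vertical)
}

# sagittal (AP-V plane) speed = velocity magnitude after removing the ML
# component; requires valid pelvis frames
.sagittal_speed <- function(prep, marker) {
  if (is.null(prep$frames)) stop("sagittal decomposition requires pelvis frames")
  vml <- rowSums(prep$vel[[marker]] * prep$frames$ml)
  v2 <- rowSums(prep$vel[[marker]]^2) - vml^2
  out <- sqrt(pmax(v2, 0))
  out[!prep$frames$valid] <- NA_real_
  out
}

# peak search tolerant of NA holes: runs .find_peaks per contiguous segment
.peaks_na <- function(x, min_distance = 1L, prominence = 0) {
  runs <- .true_runs(is.finite(x))
  out <- integer(0)
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    p <- .find_peaks(x[idx], min_distance = min_distance,
                     prominence = prominence)
    out <- c(out, idx[p])
  }
  sort(out)
}

.side_markers <- function(side) {
  list(heel = paste0(side, "HEEL"), toe = paste0(side, "TOE"))
}

.events_from_idx <- function(prep, idx, side, type, method,
                             foot_strike = "unknown") {
  gait_events(time = prep$time[idx], side = side, type = type,
              sampling_rate = prep$fs, foot_strike = foot_strike,
              method = method,
              frame = as.integer(round(prep$time[idx] * prep$fs)))
}

.bind_events <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (!length(parts)) {
    return(gait_events())
  }
  df <- do.call(rbind, lapply(parts, as.data.frame))
  gait_events(time = df$time, side = df$side, type = df$type,
              foot_strike = df$foot_strike, condition = df$condition,
              method = df$method, frame = df$frame)
}

#' Estimate the trial walking speed
#'
#' Average stride speed over both sides: heel-marker horizontal displacement
#' between consecutive same-side initial contacts divided by the elapsed
#' time, averaged over all strides. Initial contacts are detected with the
#' fixed-threshold 3D-velocity method (M5), matching how the adaptive
#' detectors (M6/M7/M10) bootstrap their thresholds.
#'
#' @param trial a [marker_trial()].
#' @param ic_events optional precomputed IC event table; defaults to M5.
#' @param prep optional [prepare_trial()] result.
#' @return walking speed in m/s.
#' @export
estimate_walking_speed <- function(trial, ic_events = NULL, prep = NULL) {
  prep <- .as_prep(trial, prep)
  if (is.null(ic_events)) {
    ic_events <- detect_ic_velocity3d(trial, detector_params("M5"),
                                      prep = prep)
  }
  speeds <- numeric(0)
  for (side in c("L", "R")) {
    tt <- sort(ic_events$time[ic_events$side == side &
                              ic_events$type == "IC"])
    if (length(tt) < 2L) next
    heel <- prep$trial$trajectories[[.side_markers(side)$heel]]
    hh <- .horizontal(heel, prep$vertical)
    idx <- pmin(pmax(round(tt * prep$fs) + 1L, 1L), length(prep$time))
    d <- sqrt(rowSums((hh[idx[-1], , drop = FALSE] -
                       hh[idx[-length(idx)], , drop = FALSE])^2))
    speeds <- c(speeds, d / diff(tt))
  }
  if (!length(speeds)) {
    stop("walking speed undefined: fewer than 2 initial contacts per side")
  }
  mean(speeds)
}

#' M1: position peaks relative to the pelvis
#'
#' Initial contacts are local maxima of the heel anterior-posterior position
#' relative to the pelvis origin; final contacts are local minima of the
#' relative toe AP position. Peaks are subject to a prominence floor and the
#' debounce separation.
#'
#' @param trial a [marker_trial()] with pelvis markers.
#' @param params a [detector_params()].
#' @param prep optional [prepare_trial()] result.
#' @return a [gait_events()] table.
#' @export
detect_m1 <- function(trial, params = detector_params("M1"), prep = NULL) {
  prep <- .as_prep(trial, prep)
  if (is.null(prep$frames) || !any(prep$frames$valid)) {
    warning("M1: no valid pelvis frames; returning empty event set")
    return(gait_events())
  }
  dist <- max(1L, round(params$min_event_separation * prep$fs))
  out <- list()
  for (side in c("L", "R")) {
    mk <- .side_markers(side)
    rel_h <- decompose(prep$fpos[[mk$heel]], prep$frames)$AP
    rel_t <- decompose(prep$fpos[[mk$toe]], prep$frames)$AP
    prom_h <- params$peak_prominence_frac * diff(range(rel_h, na.rm = TRUE))
    prom_t <- params$peak_prominence_frac * diff(range(rel_t, na.rm = TRUE))
    ic <- .peaks_na(rel_h, min_distance = dist, prominence = prom_h)
    fc <- .peaks_na(-rel_t, min_distance = dist, prominence = prom_t)
    out[[paste0(side, "IC")]] <- .events_from_idx(prep, ic, side, "IC", "M1")
    out[[paste0(side, "FC")]] <- .events_from_idx(prep, fc, side, "FC", "M1")
  }
  do.call(.bind_events, out)
}

#' M2: peaks of high-pass-filtered foot AP positions
#'
#' Per gait cycle the initial contact is the earlier of the maxima of the
#' high-pass-filtered heel and toe AP positions, and the final contact the
#' later of the two minima. Candidates from the two signals are clustered
#' in time; the high-pass cut-off defaults to 0.5 Hz.
#'
#' @inheritParams detect_m1
#' @return a [gait_events()] table.
#' @export
detect_m2 <- function(trial, params = detector_params("M2"), prep = NULL) {
  prep <- .as_prep(trial, prep)
  dist <- max(1L, round(params$min_event_separation * prep$fs))
  ap <- function(marker) .ap_signal(prep, marker)
  out <- list()
  for (side in c("L", "R")) {
    mk <- .side_markers(side)
    h <- suppressWarnings(lowpass_filter(ap(mk$heel), prep$fs,
                                         cutoff = params$m2_highpass,
                                         type = "high"))
    t2 <- suppressWarnings(lowpass_filter(ap(mk$toe), prep$fs,
                                          cutoff = params$m2_highpass,
                                          type = "high"))
    prom <- function(x) params$peak_prominence_frac *
      diff(range(x, na.rm = TRUE))
    cand_ic <- sort(c(.peaks_na(h, dist, prom(h)),
                      .peaks_na(t2, dist, prom(t2))))
    cand_fc <- sort(c(.peaks_na(-h, dist, prom(h)),
                      .peaks_na(-t2, dist, prom(t2))))
    pick <- function(cand, take_first) {
      if (!length(cand)) return(integer(0))
      groups <- cumsum(c(1L, diff(cand) > dist))
      vapply(split(cand, groups),
             function(g) if (take_first) min(g) else max(g), integer(1))
    }
    out[[paste0(side, "IC")]] <-
      .events_from_idx(prep, pick(cand_ic, TRUE), side, "IC", "M2")
    out[[paste0(side, "FC")]] <-
      .events_from_idx(prep, pick(cand_fc, FALSE), side, "FC", "M2")
  }
  do.call(.bind_events, out)
}

# AP coordinate for detectors that tolerate missing pelvis markers: pelvis
# frame when available, otherwise projection on the net horizontal
# progression direction of the heel markers.
.ap_signal <- function(prep, marker) {
  if (!is.null(prep$frames) && any(prep$frames$valid)) {
    return(decompose(prep$fpos[[marker]], prep$frames)$AP)
  }
  heel <- prep$fpos[[sub("TOE", "HEEL", marker)]]
  hh <- .horizontal(heel, prep$vertical)
  ok <- which(apply(is.finite(hh), 1L, all))
  dir <- hh[ok[length(ok)], ] - hh[ok[1L], ]
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9) dir <- c(1, 0, 0) else dir <- dir / nd
  drop(.horizontal(prep$fpos[[marker]], prep$vertical) %*% dir)
}

#' M3: vertical velocity extrema of the mid-foot point
#'
#' Uses the midpoint of the heel and toe markers: initial contacts are local
#' minima of its vertical velocity, final contacts local maxima. Candidates
#' are rejected when the midpoint height exceeds a multiple (default 1.3x)
#' of its stance-phase baseline, and debounced.
#'
#' @inheritParams detect_m1
#' @return a [gait_events()] table.
#' @export
detect_m3 <- function(trial, params = detector_params("M3"), prep = NULL) {
  prep <- .as_prep(trial, prep)
  dist <- max(1L, round(params$min_event_separation * prep$fs))
  out <- list()
  for (side in c("L", "R")) {
    mk <- .side_markers(side)
    mid <- (prep$fpos[[mk$heel]] + prep$fpos[[mk$toe]]) / 2
    h <- drop(mid %*% prep$vertical)
    vv <- drop(differentiate(mid, prep$fs) %*% prep$vertical)
    prom <- params$peak_prominence_frac * diff(range(vv, na.rm = TRUE))
    baseline <- stats::quantile(h, 0.1, na.rm = TRUE, names = FALSE)
    gate <- function(idx) idx[h[idx] <= params$m3_height_factor * baseline]
    ic <- gate(.peaks_na(-vv, dist, prom))
    fc <- gate(.peaks_na(vv, dist, prom))
    out[[paste0(side, "IC")]] <- .events_from_idx(prep, ic, side, "IC", "M3")
    out[[paste0(side, "FC")]] <- .events_from_idx(prep, fc, side, "FC", "M3")
  }
  do.call(.bind_events, out)
}

#' M4/M6: sagittal-plane velocity thresholding
#'
#' Initial contact at the first frame of each debounced downward crossing of
#' the heel sagittal (AP-V plane) speed below the threshold; final contact
#' at the first frame of each upward crossing of the toe sagittal speed
#' above its threshold. M4 uses fixed 0.5 m/s thresholds; M6 adapts them to
#' the walking speed (0.78x for IC, 0.66x for FC).
#'
#' @param trial a [marker_trial()] with pelvis markers (the sagittal plane
#'   is defined by the pelvis frame).
#' @param params a [detector_params()] for `"M4"` or `"M6"`.
#' @param prep optional [prepare_trial()] result.
#' @return a [gait_events()] table.
#' @export
detect_sagittal_velocity <- function(trial, params = detector_params("M4"),
                                     prep = NULL) {
  prep <- .as_prep(trial, prep)
  if (params$method == "M6" && (!is.finite(params$th_heel) ||
                                !is.finite(params$th_toe_fc))) {
    stop("M6 requires walking_speed (or explicit thresholds)")
  }
  out <- list()
  for (side in c("L", "R")) {
    mk <- .side_markers(side)
    sh <- .sagittal_speed(prep, mk$heel)
    st <- .sagittal_speed(prep, mk$toe)
    ic <- .threshold_crossings(sh, prep$fs, params$th_heel, "below",
                               params$min_event_separation)
    fc <- .threshold_crossings(st, prep$fs, params$th_toe_fc, "above",
                               params$min_event_separation)
    out[[paste0(side, "IC")]] <-
      .events_from_idx(prep, ic, side, "IC", params$method)
    out[[paste0(side, "FC")]] <-
      .events_from_idx(prep, fc, side, "FC", params$method)
  }
  do.call(.bind_events, out)
}

#' M5/M7 initial contacts from 3D marker speeds
#'
#' Candidate instants are debounced downward crossings of the 3D heel speed
#' (`tIC_H`) and 3D toe speed (`tIC_T`) below their thresholds. Candidates
#' are grouped by gait cycle (the interval between consecutive upward
#' toe-speed crossings of the final-contact threshold) and resolved per the
#' rearfoot/forefoot rule: if `tIC_H <= tIC_T` the contact is rearfoot at
#' `tIC_H`; otherwise, if the toe marker is lower than the heel marker at
#' `tIC_T`, the contact is forefoot at `tIC_T`; else rearfoot at `tIC_H`.
#'
#' @param trial a [marker_trial()].
#' @param params a [detector_params()] for `"M5"` (fixed thresholds) or
#'   `"M7"` (walking-speed-adaptive).
#' @param prep optional [prepare_trial()] result.
#' @return IC events with `foot_strike` filled in.
#' @export
detect_ic_velocity3d <- function(trial, params = detector_params("M5"),
                                 prep = NULL) {
  prep <- .as_prep(trial, prep)
  if (!is.finite(params$th_heel) || !is.finite(params$th_toe_ic)) {
    stop(params$method, " requires resolved thresholds (walking_speed?)")
  }
  out <- list()
  for (side in c("L", "R")) {
    mk <- .side_markers(side)
    sh <- prep$speed[[mk$heel]]
    st <- prep$speed[[mk$toe]]
    hz <- .height(prep, mk$heel)
    tz <- .height(prep, mk$toe)
    ich <- .threshold_crossings(sh, prep$fs, params$th_heel, "below",
                                params$min_event_separation)
    ict <- .threshold_crossings(st, prep$fs, params$th_toe_ic, "below",
                                params$min_event_separation)
    fct <- .threshold_crossings(st, prep$fs, params$th_toe_fc, "above",
                                params$min_event_separation)
    bounds <- c(0L, fct, length(prep$time) + 1L)
    idx <- integer(0); strike <- character(0)
    for (k in seq_len(length(bounds) - 1L)) {
      inwin <- function(v) v[v > bounds[k] & v <= bounds[k + 1L]]
      h <- inwin(ich); tt <- inwin(ict)
      h <- if (length(h)) h[1L] else NA_integer_
      tt <- if (length(tt)) tt[1L] else NA_integer_
      if (is.na(h) && is.na(tt)) next
      if (!is.na(h) && (is.na(tt) || h <= tt)) {
        idx <- c(idx, h); strike <- c(strike, "rearfoot")
      } else if (!is.na(tt) && isTRUE(tz[tt] < hz[tt])) {
        idx <- c(idx, tt); strike <- c(strike, "forefoot")
      } else if (!is.na(h)) {
        idx <- c(idx, h); strike <- c(strike, "rearfoot")
      }
    }
    out[[side]] <- .events_from_idx(prep, idx, side, "IC", params$method,
                                    foot_strike = strike)
  }
  do.call(.bind_events, out)
}

#' M5/M7 final contacts from 3D marker speeds
#'
#' Each debounced upward crossing of the 3D toe speed above the threshold
#' (`tFC_T`) centers a 100 ms window in which a local peak of the 3D heel
#' speed is sought (the initiation of foot lift, rotation about the ankle).
#' If found, the final contact is placed at the sample following the peak
#' (the discrete zero-acceleration instant); otherwise at `tFC_T` itself.
#'
#' @inheritParams detect_ic_velocity3d
#' @return FC events.
#' @export
detect_fc_velocity3d <- function(trial, params = detector_params("M5"),
                                 prep = NULL) {
  prep <- .as_prep(trial, prep)
  if (!is.finite(params$th_toe_fc)) {
    stop(params$method, " requires resolved thresholds (walking_speed?)")
  }
  half <- round(params$fc_window / 2 * prep$fs)
  n <- length(prep$time)
  out <- list()
  for (side in c("L", "R")) {
    mk <- .side_markers(side)
    st <- prep$speed[[mk$toe]]
    sh <- prep$speed[[mk$heel]]
    fct <- .threshold_crossings(st, prep$fs, params$th_toe_fc, "above",
                                params$min_event_separation)
    idx <- integer(0)
    for (i in fct) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      p <- .find_peaks(sh[lo:hi])
      if (length(p)) {
        pk <- lo - 1L + p[which.max(sh[lo:hi][p])]
        idx <- c(idx, min(pk + 1L, n))
      } else {
        idx <- c(idx, i)
      }
    }
    idx <- sort(unique(idx))
    out[[side]] <- .events_from_idx(prep, idx, side, "FC", params$method)
  }
  do.call(.bind_events, out)
}

# convenience: full M5/M7 event set (ICs + FCs)
.detect_velocity3d <- function(trial, params, prep) {
  .bind_events(detect_ic_velocity3d(trial, params, prep),
               detect_fc_velocity3d(trial, params, prep))
}

#' M8/M9: acceleration-extremum detectors
#'
#' M8 places initial contacts at local maxima of the heel vertical
#' acceleration at which the jerk is (numerically) null, and final contacts
#' at local maxima of the toe AP acceleration under the same jerk gate.
#' M9 places initial contacts at local minima of the heel AP acceleration
#' and final contacts at local maxima of the toe AP acceleration.
#'
#' @param trial a [marker_trial()] with pelvis markers.
#' @param method `"M8"` or `"M9"`.
#' @param params a [detector_params()].
#' @param prep optional [prepare_trial()] result.
#' @return a [gait_events()] table.
#' @export
detect_accel <- function(trial, method = c("M8", "M9"),
                         params = detector_params(method[1]), prep = NULL) {
  method <- match.arg(method)
  prep <- .as_prep(trial, prep)
  if (is.null(prep$frames) || !any(prep$frames$valid)) {
    warning(method, ": no valid pelvis frames; returning empty event set")
    return(gait_events())
  }
  dist <- max(1L, round(params$min_event_separation * prep$fs))
  jerk_ok <- function(a) {
    j <- differentiate(a, prep$fs)
    eps <- params$jerk_tol_frac * sqrt(mean(j^2, na.rm = TRUE))
    function(idx) {
      idx[vapply(idx, function(i) {
        nb <- j[max(1L, i - 1L):min(length(j), i + 1L)]
        any(is.finite(nb) & abs(nb) <= eps) ||
          (length(nb) >= 2L && any(diff(sign(nb[is.finite(nb)])) != 0))
      }, logical(1))]
    }
  }
  out <- list()
  for (side in c("L", "R")) {
    mk <- .side_markers(side)
    a_heel <- decompose(prep$acc[[mk$heel]], prep$frames, relative = FALSE)
    a_toe <- decompose(prep$acc[[mk$toe]], prep$frames, relative = FALSE)
    prom <- function(x) params$peak_prominence_frac *
      diff(range(x, na.rm = TRUE))
    if (method == "M8") {
      gate_h <- jerk_ok(a_heel$V)
      gate_t <- jerk_ok(a_toe$AP)
      ic <- gate_h(.peaks_na(a_heel$V, dist, prom(a_heel$V)))
      fc <- gate_t(.peaks_na(a_toe$AP, dist, prom(a_toe$AP)))
    } else {
      ic <- .peaks_na(-a_heel$AP, dist, prom(a_heel$AP))
      fc <- .peaks_na(a_toe$AP, dist, prom(a_toe$AP))
    }
    out[[paste0(side, "IC")]] <- .events_from_idx(prep, ic, side, "IC", method)
    out[[paste0(side, "FC")]] <- .events_from_idx(prep, fc, side, "FC", method)
  }
  do.call(.bind_events, out)
}

#' M10: pelvis-anchored fusion of M1 and M7
#'
#' Both contacts are first estimated with M1 (reducing false positives by
#' exploiting the pelvis markers) and then refined with the matching M7
#' event: each M1 event is replaced by the nearest same-side, same-type M7
#' event within the match window (default 0.25 s), inheriting its time and
#' foot-strike label. Unmatched M1 events are kept with unknown strike;
#' unmatched M7 events are discarded unless they fall where the pelvis
#' markers are occluded, in which case they are emitted directly (the
#' pelvis-occlusion fallback). When the pelvis is absent or fully occluded
#' the output equals the M7 output. If the walking speed cannot be
#' estimated, refinement falls back to M5 with a warning.
#'
#' @param trial a [marker_trial()].
#' @param params a [detector_params()] (`m10_match_window` is the matching
#'   half-window).
#' @param prep optional [prepare_trial()] result.
#' @return a [gait_events()] table with `method = "M10"`.
#' @export
detect_m10 <- function(trial, params = detector_params("M10"), prep = NULL) {
  prep <- .as_prep(trial, prep)
  pelvis_ok <- !is.null(prep$frames) && any(prep$frames$valid)
  m1 <- if (pelvis_ok) {
    detect_m1(trial, detector_params("M1",
              min_event_separation = params$min_event_separation,
              peak_prominence_frac = params$peak_prominence_frac),
              prep = prep)
  } else gait_events()
  ws <- params$walking_speed
  refine <- tryCatch({
    if (is.null(ws)) ws <- estimate_walking_speed(trial, prep = prep)
    .detect_velocity3d(trial, detector_params("M7", walking_speed = ws,
                       min_event_separation = params$min_event_separation,
                       fc_window = params$fc_window), prep)
  }, error = function(e) {
    warning("M10: walking speed unavailable (", conditionMessage(e),
            "); refining with M5")
    .detect_velocity3d(trial, detector_params("M5",
                       min_event_separation = params$min_event_separation,
                       fc_window = params$fc_window), prep)
  })
  frame_occluded <- function(times) {
    if (!pelvis_ok) return(rep(TRUE, length(times)))
    idx <- pmin(pmax(round(times * prep$fs) + 1L, 1L), length(prep$time))
    !prep$frames$valid[idx]
  }
  pieces <- list()
  for (side in c("L", "R")) for (ty in c("IC", "FC")) {
    a <- m1[m1$side == side & m1$type == ty, , drop = FALSE]
    b <- refine[refine$side == side & refine$type == ty, , drop = FALSE]
    used_b <- rep(FALSE, nrow(b))
    keep <- list()
    if (nrow(a)) {
      for (i in seq_len(nrow(a))) {
        if (nrow(b)) {
          d <- abs(b$time - a$time[i])
          d[used_b] <- Inf
          j <- which.min(d)
        } else j <- integer(0)
        if (length(j) && is.finite(d[j]) && d[j] <= params$m10_match_window) {
          used_b[j] <- TRUE
          keep[[length(keep) + 1L]] <- b[j, , drop = FALSE]
        } else {
          row <- a[i, , drop = FALSE]
          row$foot_strike <- "unknown"
          keep[[length(keep) + 1L]] <- row
        }
      }
    }
    if (nrow(b)) {
      direct <- !used_b & frame_occluded(b$time)
      if (any(direct)) keep[[length(keep) + 1L]] <- b[direct, , drop = FALSE]
    }
    if (length(keep)) {
      kk <- do.call(rbind, keep)
      kk <- kk[!duplicated(kk$time), , drop = FALSE]
      pieces[[paste0(side, ty)]] <- kk
    }
  }
  ev <- do.call(.bind_events, pieces)
  if (nrow(ev)) ev$method <- "M10"
  ev
}

#' Run any of the ten detectors
#'
#' Thin dispatcher over the per-method functions; resolves adaptive
#' thresholds by estimating the walking speed when needed.
#'
#' @param trial a [marker_trial()].
#' @param method `"M1"` ... `"M10"`.
#' @param params optional [detector_params()]; constructed from `method`
#'   when omitted.
#' @param prep optional [prepare_trial()] result.
#' @return a [gait_events()] table.
#' @export
detect_events <- function(trial, method = "M10", params = NULL, prep = NULL) {
  method <- match.arg(method, paste0("M", 1:10))
  prep <- .as_prep(trial, prep)
  if (is.null(params)) {
    if (method %in% c("M6", "M7")) {
      ws <- estimate_walking_speed(trial, prep = prep)
      params <- detector_params(method, walking_speed = ws)
    } else {
      params <- detector_params(method)
    }
  }
  switch(method,
    M1 = detect_m1(trial, params, prep),
    M2 = detect_m2(trial, params, prep),
    M3 = detect_m3(trial, params, prep),
    M4 = detect_sagittal_velocity(trial, params, prep),
    M5 = .detect_velocity3d(trial, params, prep),
    M6 = detect_sagittal_velocity(trial, params, prep),
    M7 = .detect_velocity3d(trial, params, prep),
    M8 = detect_accel(trial, "M8", params, prep),
    M9 = detect_accel(trial, "M9", params, prep),
    M10 = detect_m10(trial, params, prep))
}
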