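# Walking-condition segmentation: curvilinear walking (CW) from pelvis yaw,
# step negotiation (SN) from heel height at consecutive ipsilateral initial
# contacts, straight walking (SW) as the default stratum.

#' Evaluate the curvilinear-walking rule on a yaw series
#'
#' Shared rule evaluator used both on marker-derived pelvis yaw and on the
#' simulator's analytic yaw profile. Candidate cores are maximal intervals
#' with |yaw rate| >= `rate_core` (deg/s), widened while |yaw rate| stays
#' above `rate_ext`, merged across gaps shorter than `merge_gap`, and
#' accepted when the net rotation |yaw(end) - yaw(start)| is at least
#' `min_rotation` degrees, the duration lies in `[min_duration,
#' max_duration]`, and the peak |yaw rate| is at least `rate_core`.
#'
#' @param yaw unwrapped yaw angle, degrees.
#' @param time time vector, seconds.
#' @param sampling_rate Hz.
#' @param min_rotation,rate_core,min_duration,max_duration the acceptance
#'   thresholds (45 deg, 15 deg/s, 0.5 s, 10 s).
#' @param rate_ext widening threshold, deg/s.
#' @param merge_gap segments closer than this are merged, seconds.
#' @param smooth low-pass the yaw rate at 7 Hz before thresholding.
#' @return data.frame of segments: `label`, `start`, `end`, `total_yaw`
#'   (net, degrees), `peak_yaw_rate` (deg/s); attribute `"rejected"` holds
#'   the rejected candidates with a `reason` column.
#' @export
curvilinear_segments_from_yaw <- function(yaw, time, sampling_rate,
                                          min_rotation = 45,
                                          rate_core = 15,
                                          min_duration = 0.5,
                                          max_duration = 10,
                                          rate_ext = 1,
                                          merge_gap = 0.2,
                                          smooth = TRUE) {
  fs <- sampling_rate
  rate <- differentiate(yaw, fs)
  if (smooth) {
    rate <- suppressWarnings(lowpass_filter(rate, fs, cutoff = 7))
  }
  ok <- is.finite(rate)
  core <- .true_runs(ok & abs(rate) >= rate_core)
  if (!nrow(core)) {
    return(.empty_cw())
  }
  # widen cores while the yaw keeps rotating
  segs <- lapply(seq_len(nrow(core)), function(r) {
    s <- core$start[r]; e <- core$end[r]
    while (s > 1L && isTRUE(ok[s - 1L]) && abs(rate[s - 1L]) >= rate_ext)
      s <- s - 1L
    while (e < length(rate) && isTRUE(ok[e + 1L]) && abs(rate[e + 1L]) >= rate_ext)
      e <- e + 1L
    c(s, e)
  })
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  # merge overlapping/nearby segments
  merged <- list(segs[1, ])
  for (r in seq_len(nrow(segs))[-1]) {
    last <- merged[[length(merged)]]
    if ((segs[r, 1] - last[2]) / fs < merge_gap) {
      merged[[length(merged)]] <- c(last[1], max(last[2], segs[r, 2]))
    } else {
      merged[[length(merged) + 1L]] <- segs[r, ]
    }
  }
  res <- lapply(merged, function(se) {
    s <- se[1]; e <- se[2]
    data.frame(label = "CW", start = time[s], end = time[e],
               total_yaw = yaw[e] - yaw[s],
               peak_yaw_rate = max(abs(rate[s:e]), na.rm = TRUE),
               duration = time[e] - time[s])
  })
  res <- do.call(rbind, res)
  reason <- rep(NA_character_, nrow(res))
  reason[res$duration > max_duration] <- "duration"
  reason[res$duration < min_duration & is.na(reason)] <- "duration"
  reason[abs(res$total_yaw) < min_rotation & is.na(reason)] <- "rotation"
  reason[res$peak_yaw_rate < rate_core & is.na(reason)] <- "rate"
  accepted <- res[is.na(reason), setdiff(names(res), "duration"),
                  drop = FALSE]
  rejected <- res[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  rownames(accepted) <- NULL
  attr(accepted, "rejected") <- rejected
  accepted
}

.empty_cw <- function() {
  out <- data.frame(label = character(0), start = numeric(0),
                    end = numeric(0), total_yaw = numeric(0),
                    peak_yaw_rate = numeric(0))
  attr(out, "rejected") <- out
  out
}

#' Detect curvilinear-walking segments from the pelvis
#'
#' Pelvis yaw is the heading of the AP axis projected on the horizontal
#' plane, unwrapped; its rate is the smoothed central difference. Segments
#' satisfying the simultaneous thresholds (net rotation >= 45 degrees, peak
#' yaw rate >= 15 deg/s, duration between 0.5 and 10 s) are returned.
#'
#' @param frames a [build_pelvis_frames()] result.
#' @param ... thresholds passed to [curvilinear_segments_from_yaw()].
#' @return segment data.frame (see [curvilinear_segments_from_yaw()]).
#' @export
detect_curvilinear <- function(frames, ...) {
  if (!any(frames$valid)) return(.empty_cw())
  up <- frames$vertical
  # horizontal basis
  ref <- if (abs(up[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * up) * up
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(up[2] * e1[3] - up[3] * e1[2],
          up[3] * e1[1] - up[1] * e1[3],
          up[1] * e1[2] - up[2] * e1[1])
  x <- drop(frames$ap %*% e1)
  y <- drop(frames$ap %*% e2)
  yaw <- rep(NA_real_, length(x))
  ok <- frames$valid & is.finite(x) & is.finite(y)
  yaw[ok] <- atan2(y[ok], x[ok])
  # unwrap per valid run
  runs <- .true_runs(ok)
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    yaw[idx] <- .unwrap(yaw[idx])
  }
  curvilinear_segments_from_yaw(yaw * 180 / pi, frames$time,
                                frames$sampling_rate, ...)
}

#' Detect step-negotiation segments
#'
#' For each pair of consecutive same-side initial contacts, the heel
#' vertical (laboratory up) position difference between the two instants is
#' computed from the unfiltered trajectories; pairs with |difference|
#' strictly greater than `min_height` emit an SN segment spanning the two
#' contacts.
#'
#' @param trial a [marker_trial()].
#' @param ic_events an event table; only `type == "IC"` rows are used.
#' @param min_height threshold in meters (default 0.15, strict inequality).
#' @return data.frame of segments: `label`, `start`, `end`, `height_change`
#'   (signed, meters), `side`.
#' @export
detect_step_negotiation <- function(trial, ic_events, min_height = 0.15) {
  out <- list()
  n <- length(trial$time)
  for (side in c("L", "R")) {
    tt <- sort(ic_events$time[ic_events$side == side &
                              ic_events$type == "IC"])
    if (length(tt) < 2L) next
    heel <- trial$trajectories[[paste0(side, "HEEL")]]
    hz <- drop(heel %*% trial$vertical)
    idx <- pmin(pmax(round(tt * trial$sampling_rate) + 1L, 1L), n)
    z <- hz[idx]
    for (k in seq_len(length(tt) - 1L)) {
      dz <- z[k + 1L] - z[k]
      # strict inequality, guarded against representation error at the
      # printed threshold (a nanometer is far below any marker resolution)
      if (is.finite(dz) && abs(dz) - min_height > 1e-9) {
        out[[length(out) + 1L]] <-
          data.frame(label = "SN", start = tt[k], end = tt[k + 1L],
                     height_change = dz, side = side)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(label = character(0), start = numeric(0),
                      end = numeric(0), height_change = numeric(0),
                      side = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Label events by walking condition
#'
#' Each event receives exactly one label: `SN` if it lies inside any
#' step-negotiation segment (SN takes precedence), else `CW` if inside any
#' curvilinear segment, else `SW`.
#'
#' @param events a [gait_events()] table.
#' @param cw_segments,sn_segments segment data.frames (may be empty or
#'   NULL).
#' @return the event table with `condition` filled in.
#' @export
label_events <- function(events, cw_segments = NULL, sn_segments = NULL) {
  inside <- function(t, segs) {
    if (is.null(segs) || !nrow(segs)) return(rep(FALSE, length(t)))
    vapply(t, function(ti) any(ti >= segs$start & ti <= segs$end),
           logical(1))
  }
  lab <- rep("SW", nrow(events))
  lab[inside(events$time, cw_segments)] <- "CW"
  lab[inside(events$time, sn_segments)] <- "SN"
  events$condition <- lab
  events
}
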