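# Stride assembly and spatio-temporal parameters. A stride runs between
# consecutive same-side initial contacts; the intervening same-side final
# contact splits it into stance and swing.

#' Assemble strides from a gait-event table
#'
#' One stride per consecutive same-side IC pair. The stride's final contact
#' is the unique same-side FC strictly inside the interval; when absent or
#' ambiguous (several FCs), stance and swing stay NA and the stride is
#' flagged.
#'
#' @param events a [gait_events()] table.
#' @return data.frame with one row per stride: `side`, `t_ic_start`,
#'   `t_fc`, `t_ic_end`, `duration`, `stance`, `swing`, `fc_flag`
#'   (`"ok"`, `"missing"`, `"multiple"`).
#' @export
assemble_strides <- function(events) {
  out <- list()
  for (side in c("L", "R")) {
    ics <- sort(events$time[events$side == side & events$type == "IC"])
    fcs <- sort(events$time[events$side == side & events$type == "FC"])
    if (length(ics) < 2L) next
    for (k in seq_len(length(ics) - 1L)) {
      t0 <- ics[k]; t1 <- ics[k + 1L]
      inside <- fcs[fcs > t0 & fcs < t1]
      fc <- if (length(inside) == 1L) inside else NA_real_
      flag <- if (length(inside) == 1L) "ok"
              else if (length(inside) == 0L) "missing" else "multiple"
      out[[length(out) + 1L]] <- data.frame(
        side = side, t_ic_start = t0, t_fc = fc, t_ic_end = t1,
        duration = t1 - t0,
        stance = if (is.na(fc)) NA_real_ else fc - t0,
        swing = if (is.na(fc)) NA_real_ else t1 - fc,
        fc_flag = flag)
    }
  }
  if (!length(out)) {
    return(data.frame(side = character(0), t_ic_start = numeric(0),
                      t_fc = numeric(0), t_ic_end = numeric(0),
                      duration = numeric(0), stance = numeric(0),
                      swing = numeric(0), fc_flag = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$t_ic_start, res$side), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compute stride length and speed from the heel trajectory
#'
#' Stride length is the Euclidean norm of the horizontal-plane heel
#' displacement between the two bounding initial contacts (vertical motion
#' excluded so step negotiation does not inflate length; set
#' `projection = "3d"` for the full displacement); speed is length divided
#' by duration. Unfiltered (gap-filled) heel positions anchor the
#' computation. Strides whose heel is occluded at an endpoint are dropped
#' and counted missing.
#'
#' @param strides an [assemble_strides()] table.
#' @param trial the [marker_trial()] the events came from.
#' @param projection `"horizontal"` (default) or `"3d"`.
#' @param trial_id,method provenance columns for the returned table.
#' @return the stride table with `length`, `speed`, `trial_id`, `method`
#'   columns; attribute `"n_missing"` counts dropped strides.
#' @export
compute_stride_params <- function(strides, trial,
                                  projection = c("horizontal", "3d"),
                                  trial_id = trial$trial_id,
                                  method = NA_character_) {
  projection <- match.arg(projection)
  n <- length(trial$time)
  len <- rep(NA_real_, nrow(strides))
  keep <- rep(TRUE, nrow(strides))
  for (i in seq_len(nrow(strides))) {
    side <- strides$side[i]
    heel <- trial$trajectories[[paste0(side, "HEEL")]]
    vmask <- trial$valid[[paste0(side, "HEEL")]]
    idx <- pmin(pmax(round(c(strides$t_ic_start[i], strides$t_ic_end[i]) *
                             trial$sampling_rate) + 1L, 1L), n)
    if (!all(vmask[idx])) { keep[i] <- FALSE; next }
    d <- heel[idx[2L], ] - heel[idx[1L], ]
    if (projection == "horizontal") {
      d <- d - sum(d * trial$vertical) * trial$vertical
    }
    len[i] <- sqrt(sum(d^2))
  }
  out <- strides[keep, , drop = FALSE]
  out$length <- len[keep]
  out$speed <- out$length / out$duration
  out$trial_id <- rep(trial_id, nrow(out))
  out$method <- rep(method, nrow(out))
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(!keep)
  out
}

#' Identify walking bouts
#'
#' Maximal episodes of continuous stepping (gap between consecutive initial
#' contacts of either side below `max_gap` seconds) containing at least two
#' left and two right strides. Strides outside bouts are excluded from
#' validation.
#'
#' @param strides an [assemble_strides()] table.
#' @param max_gap bout-breaking gap between consecutive ICs, seconds.
#' @return data.frame of bouts: `start`, `end`, `n_left`, `n_right`; plus a
#'   logical attribute-free helper column is not added -- use
#'   [strides_in_bouts()] to filter.
#' @export
identify_bouts <- function(strides, max_gap = 3) {
  ics <- sort(unique(c(strides$t_ic_start, strides$t_ic_end)))
  if (!length(ics)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_left = integer(0), n_right = integer(0)))
  }
  brk <- which(diff(ics) >= max_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(ics))
  out <- list()
  for (k in seq_along(starts)) {
    t0 <- ics[starts[k]]; t1 <- ics[ends[k]]
    inb <- strides$t_ic_start >= t0 & strides$t_ic_end <= t1
    nl <- sum(inb & strides$side == "L")
    nr <- sum(inb & strides$side == "R")
    if (nl >= 2L && nr >= 2L) {
      out[[length(out) + 1L]] <- data.frame(start = t0, end = t1,
                                            n_left = nl, n_right = nr)
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_left = integer(0), n_right = integer(0)))
  }
  do.call(rbind, out)
}

#' Filter strides to those inside walking bouts
#'
#' @param strides a stride table.
#' @param bouts an [identify_bouts()] table.
#' @return the subset of `strides` fully inside a bout.
#' @export
strides_in_bouts <- function(strides, bouts) {
  if (!nrow(bouts)) return(strides[0, , drop = FALSE])
  keep <- vapply(seq_len(nrow(strides)), function(i) {
    any(strides$t_ic_start[i] >= bouts$start &
        strides$t_ic_end[i] <= bouts$end)
  }, logical(1))
  strides[keep, , drop = FALSE]
}

#' Label strides by walking condition
#'
#' A stride is labeled `SN` if at least one of its bounding initial
#' contacts is SN-labeled, else `CW` if at least one is CW-labeled, else
#' `SW`.
#'
#' @param strides a stride table.
#' @param labeled_events a [label_events()] result (IC rows are used).
#' @param tol time tolerance when matching stride endpoints to events,
#'   seconds.
#' @return the stride table with a `condition` column.
#' @export
label_strides <- function(strides, labeled_events, tol = 1e-6) {
  ics <- labeled_events[labeled_events$type == "IC", , drop = FALSE]
  lab_at <- function(side, t) {
    j <- which(ics$side == side & abs(ics$time - t) <= tol)
    if (!length(j)) return("SW")
    ics$condition[j[1L]]
  }
  cond <- vapply(seq_len(nrow(strides)), function(i) {
    l1 <- lab_at(strides$side[i], strides$t_ic_start[i])
    l2 <- lab_at(strides$side[i], strides$t_ic_end[i])
    if ("SN" %in% c(l1, l2)) "SN"
    else if ("CW" %in% c(l1, l2)) "CW"
    else "SW"
  }, character(1))
  strides$condition <- cond
  strides
}
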