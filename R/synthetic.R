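# Synthetic gait-trajectory simulator with exact ground-truth events.
#
# Foot model: during stance the markers are stationary (heel-then-toe rocker
# for rearfoot strikes, toe-first for forefoot); swings follow raised-cosine
# displacement profiles along the walking path with a two-hump vertical
# toe-clearance profile. The heel additionally performs a small
# "ankle-rocker" velocity bump peaking exactly at toe-off, giving the heel
# speed the local maximum that velocity-based final-contact refinement keys
# on. Ground truth (first/last stationary instants) is recorded analytically
# before noise or occlusion is applied.

#' Specification of a synthetic gait trial
#'
#' @param sampling_rate Hz (default 100).
#' @param n_strides strides per side.
#' @param stride_length meters.
#' @param stride_duration seconds.
#' @param stance_fraction fraction of the stride spent in stance, in
#'   (0.5, 0.8); default 0.62.
#' @param foot_strike `"rearfoot"`, `"forefoot"`, or `"mixed"`
#'   (alternating).
#' @param turn optional `list(angle, start, duration)`: smooth yaw rotation
#'   of `angle` degrees (raised-cosine yaw-rate profile) starting at
#'   `start` seconds.
#' @param step optional `list(height, position)`: smooth ground-height
#'   change of `height` meters centered `position` meters along the path.
#' @param noise_sd additive i.i.d. Gaussian marker noise per coordinate,
#'   meters (default 0).
#' @param occlusions list of `list(marker, start, duration)`; `marker` may
#'   be `"PELVIS"` for the whole cluster.
#' @param seed integer RNG seed for the noise.
#' @param yaw_sway_deg amplitude of the sinusoidal pelvis yaw sway at
#'   stride frequency, degrees (default 2).
#' @param first_ic time of the first right initial contact, seconds.
#' @param step_width lateral distance between the feet, meters.
#' @return list of class `synthetic_gait_spec`.
#' @export
synthetic_gait_spec <- function(sampling_rate = 100, n_strides = 10,
                                stride_length = 1.2, stride_duration = 1.1,
                                stance_fraction = 0.62,
                                foot_strike = c("rearfoot", "forefoot",
                                                "mixed"),
                                turn = NULL, step = NULL, noise_sd = 0,
                                occlusions = list(), seed = 1L,
                                yaw_sway_deg = 2, first_ic = 0.5,
                                step_width = 0.12) {
  foot_strike <- match.arg(foot_strike)
  stopifnot(sampling_rate > 0, n_strides >= 1, stride_length > 0,
            stride_duration > 0,
            stance_fraction > 0.5, stance_fraction < 0.8, noise_sd >= 0,
            first_ic > 0.3)
  structure(list(sampling_rate = sampling_rate, n_strides = n_strides,
                 stride_length = stride_length,
                 stride_duration = stride_duration,
                 stance_fraction = stance_fraction,
                 foot_strike = foot_strike, turn = turn, step = step,
                 noise_sd = noise_sd, occlusions = occlusions,
                 seed = as.integer(seed), yaw_sway_deg = yaw_sway_deg,
                 first_ic = first_ic, step_width = step_width),
            class = "synthetic_gait_spec")
}

# turn yaw profile in radians as a function of time
.turn_yaw_fun <- function(turn) {
  if (is.null(turn)) return(function(t) rep(0, length(t)))
  a <- turn$angle * pi / 180
  function(t) {
    u <- pmin(pmax((t - turn$start) / turn$duration, 0), 1)
    a * (u - sin(2 * pi * u) / (2 * pi))
  }
}

.smoothstep <- function(w) {
  w <- pmin(pmax(w, 0), 1)
  w * w * (3 - 2 * w)
}

#' Simulate a gait trial with known ground truth
#'
#' @param spec a [synthetic_gait_spec()].
#' @return list of class `synthetic_trial` with elements `trial` (a
#'   [marker_trial()]), and `truth` (class `gait_truth`: exact `events`,
#'   `cw_segments`, `sn_segments`, analytic `strides`, and the nominal
#'   `walking_speed`).
#' @export
simulate_trial <- function(spec) {
  fs <- spec$sampling_rate
  dt <- 1 / fs
  T <- spec$stride_duration
  L <- spec$stride_length
  f <- spec$stance_fraction
  n <- spec$n_strides
  v <- L / T
  d1 <- 0.09      # rocker half-width (s)
  pk <- 0.00      # rocker peak delay after toe-off (s)
  pause <- 0.02   # settle time between rocker and main swing (s)
  d2 <- 0.08      # landing delay of the trailing marker (s)
  v1 <- 0.35      # rocker peak heel speed (m/s), below the IC thresholds
  ddec <- 0.10    # fly-in deceleration time (s)
  vc <- 4.0       # fly-in cruise speed (m/s), above the FC thresholds
  c_heel <- 0.04  # heel swing clearance (m)
  c_toe <- 0.06   # toe swing clearance (m)
  z_heel0 <- 0.05 # heel marker height above ground in stance (m)
  z_toe0 <- 0.03  # toe marker height above ground in stance (m)
  foot_len <- 0.15
  pelvis_h <- 1.0

  t0 <- list(R = spec$first_ic, L = spec$first_ic + T / 2)
  ic <- lapply(t0, function(a) a + (0:n) * T)
  fc <- lapply(t0, function(a) a + (0:(n - 1)) * T + f * T)
  D <- max(ic$L[n + 1], ic$R[n + 1]) + 0.4 * T
  time <- seq(0, D, by = dt)
  N <- length(time)

  if (!is.null(spec$turn)) {
    if (spec$turn$start < 0 || spec$turn$start + spec$turn$duration > D) {
      stop("turn placed outside the walk duration")
    }
  }
  total_path <- v * D + f * T * v / 2 + foot_len + 1
  if (!is.null(spec$step)) {
    if (spec$step$position <= 0 || spec$step$position >= total_path) {
      stop("step placed outside the walk path")
    }
  }

  strikes <- lapply(c(R = "R", L = "L"), function(s) {
    switch(spec$foot_strike,
           rearfoot = rep("rearfoot", n + 1),
           forefoot = rep("forefoot", n + 1),
           mixed = rep(c("rearfoot", "forefoot"), length.out = n + 1))
  })

  # ground height along the path
  gfun <- if (is.null(spec$step)) {
    function(s) rep(0, length(s))
  } else {
    function(s) spec$step$height *
      .smoothstep((s - spec$step$position + 0.15) / 0.3)
  }

  # path geometry: integrate the turn heading over arc length
  yaw_turn <- .turn_yaw_fun(spec$turn)
  c_f <- v * f * T / 2
  s_lo <- -vc * max(t0$L, t0$R) - 2    # feet fly in from behind
  s_hi <- v * D + c_f + foot_len + 2
  ss <- seq(s_lo, s_hi, by = max(v * dt, 1e-3))
  psi <- yaw_turn(pmin(pmax(ss / v, 0), D))
  dss <- diff(ss)
  cx <- cumsum(c(0, dss * (cos(psi[-1]) + cos(psi[-length(psi)])) / 2))
  cy <- cumsum(c(0, dss * (sin(psi[-1]) + sin(psi[-length(psi)])) / 2))
  path_xy <- function(s) {
    cbind(stats::approx(ss, cx, s, rule = 2)$y,
          stats::approx(ss, cy, s, rule = 2)$y)
  }
  path_psi <- function(s) stats::approx(ss, psi, s, rule = 2)$y

  # piecewise progression of one marker along the path
  prog <- function(land, lift, anchors) {
    s <- rep(anchors[length(anchors)], N)
    swing_u <- rep(NA_real_, N)       # phase within the main swing
    # fly-in
    cr_end <- land[1] - ddec
    m <- time < cr_end
    s[m] <- anchors[1] - vc * ddec / 2 - vc * (cr_end - time[m])
    m <- time >= cr_end & time < land[1]
    tp <- time[m] - cr_end
    s[m] <- anchors[1] - vc * ddec / 2 +
      vc / 2 * (tp + (ddec / pi) * sin(pi * tp / ddec))
    for (k in seq_along(lift)) {
      a <- anchors[k]; b <- anchors[k + 1]
      m <- time >= land[k] & time < lift[k]
      s[m] <- a
      dur <- land[k + 1] - lift[k]
      m <- time >= lift[k] & time < land[k + 1]
      u <- (time[m] - lift[k]) / dur
      s[m] <- a + (b - a) * (1 - cos(pi * u)) / 2
      swing_u[m] <- u
    }
    list(s = s, swing_u = swing_u)
  }

  # heel progression with the rocker bump before each main swing
  prog_heel <- function(land, ho, anchors) {
    s <- rep(anchors[length(anchors)], N)
    swing_u <- rep(NA_real_, N)
    cr_end <- land[1] - ddec
    m <- time < cr_end
    s[m] <- anchors[1] - vc * ddec / 2 - vc * (cr_end - time[m])
    m <- time >= cr_end & time < land[1]
    tp <- time[m] - cr_end
    s[m] <- anchors[1] - vc * ddec / 2 +
      vc / 2 * (tp + (ddec / pi) * sin(pi * tp / ddec))
    delta <- v1 * d1
    for (k in seq_along(ho)) {
      a <- anchors[k]; b <- anchors[k + 1]
      m <- time >= land[k] & time < ho[k]
      s[m] <- a
      m <- time >= ho[k] & time < ho[k] + 2 * d1
      tp <- time[m] - ho[k]
      s[m] <- a + v1 / 2 * (tp - (d1 / pi) * sin(pi * tp / d1))
      m <- time >= ho[k] + 2 * d1 & time < ho[k] + 2 * d1 + pause
      s[m] <- a + delta
      sw_a <- ho[k] + 2 * d1 + pause
      dur <- land[k + 1] - sw_a
      m <- time >= sw_a & time < land[k + 1]
      u <- (time[m] - sw_a) / dur
      s[m] <- a + delta + (b - a - delta) * (1 - cos(pi * u)) / 2
      swing_u[m] <- u
    }
    list(s = s, swing_u = swing_u)
  }

  up <- c(0, 0, 1)
  traj <- list()
  for (side in c("L", "R")) {
    lat_sign <- if (side == "R") 1 else -1
    stk <- strikes[[side]]
    ics <- ic[[side]]; fcs <- fc[[side]]
    S_anchor <- v * ics + c_f
    heel_land <- ics + d2 * (stk == "forefoot")
    toe_land <- ics + d2 * (stk == "rearfoot")
    ho <- fcs + pk - d1

    ph <- prog_heel(heel_land, ho, S_anchor)
    pt <- prog(toe_land, fcs, S_anchor + foot_len)

    mk <- function(p, clearance, z0, two_hump, land1, fly_h) {
      xy <- path_xy(p$s)
      psi_s <- path_psi(p$s)
      right <- cbind(sin(psi_s), -cos(psi_s))
      xy <- xy + lat_sign * (spec$step_width / 2) * right
      cl <- rep(0, N)
      u <- p$swing_u
      m <- !is.na(u)
      cl[m] <- if (two_hump) {
        clearance * (0.6 * (1 - cos(2 * pi * u[m])) / 2 +
                     0.4 * (1 - cos(4 * pi * u[m])) / 2)
      } else {
        clearance * (1 - cos(2 * pi * u[m])) / 2
      }
      cl <- cl + fly_h * .smoothstep((land1 - time) / 0.3) *
        as.numeric(time < land1)
      z <- z0 + gfun(p$s) + cl
      cbind(xy, z)
    }
    traj[[paste0(side, "HEEL")]] <-
      mk(ph, c_heel, z_heel0, FALSE, heel_land[1], c_heel)
    traj[[paste0(side, "TOE")]] <-
      mk(pt, c_toe, z_toe0, TRUE, toe_land[1], c_toe)
  }

  # pelvis cluster: rigid, following the path with small oscillations
  s_p <- v * time   # pelvis passes over the stance foot at mid-stance
  O_xy <- path_xy(s_p)
  psi_p <- yaw_turn(time) +
    (spec$yaw_sway_deg * pi / 180) * sin(2 * pi * time / T)
  right_p <- cbind(sin(psi_p), -cos(psi_p))
  fwd_p <- cbind(cos(psi_p), sin(psi_p))
  O_xy <- O_xy + 0.02 * sin(2 * pi * time / T) * right_p
  O_z <- pelvis_h + gfun(s_p) + 0.015 * sin(4 * pi * time / T)
  O <- cbind(O_xy, O_z)
  zero <- rep(0, N)
  traj$P0 <- O - 0.12 * cbind(right_p, zero)
  traj$P1 <- O + 0.12 * cbind(right_p, zero)
  traj$P2 <- O + 0.05 * cbind(fwd_p, zero) + matrix(c(0, 0, 0.02), N, 3,
                                                    byrow = TRUE)
  traj$P3 <- O - matrix(c(0, 0, 0.10), N, 3, byrow = TRUE)

  # ---- ground truth (before noise/occlusion) -------------------------
  ev <- list()
  for (side in c("L", "R")) {
    ev[[paste0(side, "IC")]] <-
      gait_events(time = ic[[side]], side = side, type = "IC",
                  sampling_rate = fs, foot_strike = strikes[[side]],
                  method = "truth")
    ev[[paste0(side, "FC")]] <-
      gait_events(time = fc[[side]], side = side, type = "FC",
                  sampling_rate = fs, method = "truth")
  }
  truth_events <- do.call(.bind_events, ev)

  cw <- curvilinear_segments_from_yaw(psi_p * 180 / pi, time, fs)
  attr(cw, "rejected") <- NULL

  sn <- list()
  for (side in c("L", "R")) {
    S_anchor <- v * ic[[side]] + c_f
    z_ic <- z_heel0 + gfun(S_anchor)
    for (k in seq_len(n)) {
      dz <- z_ic[k + 1] - z_ic[k]
      if (abs(dz) - 0.15 > 1e-9) {
        sn[[length(sn) + 1L]] <- data.frame(label = "SN",
                                            start = ic[[side]][k],
                                            end = ic[[side]][k + 1],
                                            height_change = dz,
                                            side = side)
      }
    }
  }
  sn <- if (length(sn)) do.call(rbind, sn) else
    data.frame(label = character(0), start = numeric(0), end = numeric(0),
               height_change = numeric(0), side = character(0))

  truth_events <- label_events(truth_events, cw, sn)

  strides <- list()
  for (side in c("L", "R")) {
    S_anchor <- v * ic[[side]] + c_f
    xy_anchor <- path_xy(S_anchor)
    psi_anchor <- path_psi(S_anchor)
    lat_sign <- if (side == "R") 1 else -1
    xy_anchor <- xy_anchor + lat_sign * (spec$step_width / 2) *
      cbind(sin(psi_anchor), -cos(psi_anchor))
    for (k in seq_len(n)) {
      len <- sqrt(sum((xy_anchor[k + 1, ] - xy_anchor[k, ])^2))
      strides[[length(strides) + 1L]] <- data.frame(
        side = side, t_ic_start = ic[[side]][k],
        t_fc = fc[[side]][k], t_ic_end = ic[[side]][k + 1],
        duration = T, stance = f * T, swing = (1 - f) * T,
        fc_flag = "ok", length = len, speed = len / T)
    }
  }
  strides <- do.call(rbind, strides)
  strides <- strides[order(strides$t_ic_start), , drop = FALSE]
  rownames(strides) <- NULL
  strides <- label_strides(strides, truth_events)

  # ---- assemble the trial, then add noise and occlusions -------------
  valid <- lapply(traj, function(m) rep(TRUE, N))
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(spec$seed)
    for (m in names(traj)) {
      traj[[m]] <- traj[[m]] + matrix(stats::rnorm(3 * N, 0, spec$noise_sd),
                                      N, 3)
    }
  }
  for (oc in spec$occlusions) {
    mks <- if (identical(oc$marker, "PELVIS")) c("P0", "P1", "P2", "P3")
           else oc$marker
    idx <- which(time >= oc$start & time < oc$start + oc$duration)
    for (m in intersect(mks, names(traj))) {
      traj[[m]][idx, ] <- NA_real_
      valid[[m]][idx] <- FALSE
    }
  }

  trial <- marker_trial(trial_id = sprintf("synthetic_%s_seed%d",
                                           spec$foot_strike, spec$seed),
                        sampling_rate = fs, time = time,
                        trajectories = traj, valid = valid, vertical = up)
  truth <- structure(list(events = truth_events, cw_segments = cw,
                          sn_segments = sn, strides = strides,
                          walking_speed = v, spec = spec),
                     class = "gait_truth")
  structure(list(trial = trial, truth = truth), class = "synthetic_trial")
}

#' Deterministic corpus of validation trial archetypes
#'
#' Straight walks at three speeds (0.8, 1.2, 1.6 m/s), a forefoot-pattern
#' walk, a 180-degree U-turn, a 0.20 m step negotiation, a noisy straight
#' walk and a pelvis-occluded walk -- each with exact ground truth.
#'
#' @param seed integer; offsets the per-trial noise seeds.
#' @param n_strides strides per side for every archetype.
#' @param noise_sd noise level of the noisy archetype, meters.
#' @return named list of `synthetic_trial` objects.
#' @export
make_validation_corpus <- function(seed = 1L, n_strides = 10,
                                   noise_sd = 0.001) {
  seed <- as.integer(seed)
  base <- function(..., seed_offset = 0L) {
    synthetic_gait_spec(n_strides = n_strides, seed = seed + seed_offset,
                        ...)
  }
  # place the maneuvers mid-walk whatever the trial length
  mid_t <- 0.5 + n_strides * 1.0 / 2
  turn_dur <- min(2.5, n_strides * 0.3)
  specs <- list(
    sw_slow = base(stride_length = 1.0, stride_duration = 1.25),
    sw_comfortable = base(stride_length = 1.2, stride_duration = 1.0),
    sw_fast = base(stride_length = 1.6, stride_duration = 1.0),
    forefoot = base(stride_length = 1.2, stride_duration = 1.0,
                    foot_strike = "forefoot"),
    uturn = base(stride_length = 1.2, stride_duration = 1.0,
                 turn = list(angle = 180, start = mid_t - turn_dur / 2,
                             duration = turn_dur)),
    step = base(stride_length = 1.2, stride_duration = 1.0,
                step = list(height = 0.20, position = 1.2 * mid_t)),
    noisy_sw = base(stride_length = 1.2, stride_duration = 1.0,
                    noise_sd = noise_sd, seed_offset = 1000L),
    pelvis_occluded = base(stride_length = 1.2, stride_duration = 1.0,
                           occlusions = list(list(marker = "PELVIS",
                                                  start = 0,
                                                  duration = Inf))))
  lapply(specs, simulate_trial)
}
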