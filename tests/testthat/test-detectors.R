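# Construct a single-sided trial whose right-foot markers follow prescribed
# speed profiles (trapezoid-integrated so central differences recover them).
speed_profile_trial <- function(v_heel, v_toe, fs = 100) {
  n <- length(v_heel)
  t <- (seq_len(n) - 1) / fs
  trap <- function(v) cumsum(c(0, (v[-1] + v[-length(v)]) / 2)) / fs
  mk <- function(x, z = 0.05) cbind(x, 0, z)
  marker_trial("profile", fs, t, list(
    RHEEL = mk(trap(v_heel)), RTOE = mk(trap(v_toe), 0.03),
    LHEEL = mk(rep(0, n)), LTOE = mk(rep(0, n), 0.03)))
}

test_that("threshold crossings fire at the first satisfying sample, debounced", {
  fs <- 100
  x <- c(rep(1, 50), seq(1, 0, length.out = 21), rep(0, 30),
         rep(1, 10), rep(0, 10),   # brief re-arm: too short to debounce
         rep(1, 30), rep(0, 20))
  idx <- gaitevents:::.threshold_crossings(x, fs, 0.5, "below", 0.2)
  # first crossing: the ramp passes below 0.5 (value 0.45 at its 12th
  # sample) after 0.5 s of arming
  expect_equal(idx[1], 50 + 12)
  # the dip after only 10 above-threshold samples is rejected; the final
  # crossing (30 above-threshold samples = 0.3 s) is kept
  expect_equal(length(idx), 2L)
  # never-crossing signal yields nothing
  expect_length(gaitevents:::.threshold_crossings(rep(1, 100), fs, 0.5,
                                                  "below", 0.2), 0L)
})

test_that("sagittal-velocity IC fires where heel speed drops below threshold", {
  # heel sagittal speed ramps below 0.5 m/s at t = 1.00 s
  fs <- 100
  n <- 301
  t <- (seq_len(n) - 1) / fs
  # speed ramps through the 0.5 m/s threshold at t = 1.00 s (the velocity
  # continues through zero so the filtered speed has no corner there)
  v <- ifelse(t < 0.5, 2, 2 - 3 * (t - 0.5))
  tr <- speed_profile_trial(v, rep(0, n))
  # attach an axis-aligned pelvis so the sagittal plane is defined
  y <- tr$trajectories$RHEEL[, 1]
  tr$trajectories$P0 <- cbind(y, -0.1, 1)
  tr$trajectories$P1 <- cbind(y, 0.1, 1)
  tr$trajectories$P3 <- cbind(y, 0, 0.9)
  tr$valid$P0 <- tr$valid$P1 <- tr$valid$P3 <- rep(TRUE, n)
  ev <- detect_sagittal_velocity(tr, detector_params("M4"))
  ic <- ev[ev$type == "IC" & ev$side == "R", ]
  expect_equal(nrow(ic), 1L)
  expect_equal(ic$time, 1.0, tolerance = 0.021)
})

test_that("3D-velocity IC applies the rearfoot/forefoot decision rule", {
  st <- sim_comfortable()
  ic <- detect_ic_velocity3d(st$trial, detector_params("M5"),
                             prep = prep_comfortable())
  expect_true(all(ic$foot_strike == "rearfoot"))
  truth_ic <- st$truth$events[st$truth$events$type == "IC", ]
  expect_equal(nrow(ic), nrow(truth_ic))
  ff <- sim_forefoot()
  ic2 <- detect_ic_velocity3d(ff$trial, detector_params("M5"),
                              prep = prep_forefoot())
  expect_true(mean(ic2$foot_strike == "forefoot") >= 0.9)
  # stationary markers produce no contacts
  n <- 300
  quiet <- speed_profile_trial(rep(0, n), rep(0, n))
  expect_equal(nrow(detect_ic_velocity3d(quiet, detector_params("M5"))), 0L)
})

test_that("3D-velocity FC refines to the sample after the heel-speed peak", {
  fs <- 100
  t <- seq(0, 4, 1 / fs)
  # toe speed crosses 1 m/s upward at 2.00 s; heel-speed peak at 1.98 s
  v_heel <- 0.1 + 1.4 * ifelse(abs(t - 1.98) <= 0.10,
                               (1 + cos(pi * (t - 1.98) / 0.10)) / 2, 0)
  v_toe <- pmax(0, 10 * (t - 1.899))
  tr <- speed_profile_trial(v_heel, v_toe)
  fc <- detect_fc_velocity3d(tr, detector_params("M5"))
  expect_equal(fc$time[fc$side == "R"], 1.99)
  # without a heel peak in the window, the toe crossing itself is the event
  tr2 <- speed_profile_trial(rep(0.1, length(t)), v_toe)
  fc2 <- detect_fc_velocity3d(tr2, detector_params("M5"))
  expect_equal(fc2$time[fc2$side == "R"], 2.00)
  # stationary trial: no final contacts
  quiet <- speed_profile_trial(rep(0, 300), rep(0, 300))
  expect_equal(nrow(detect_fc_velocity3d(quiet, detector_params("M5"))), 0L)
})

test_that("walking speed estimate matches the simulated progression speed", {
  st <- sim_comfortable()
  ws <- estimate_walking_speed(st$trial, prep = prep_comfortable())
  expect_equal(ws, 1.2, tolerance = 0.05)
  # a single IC per side cannot define a stride speed
  one_ic <- gait_events(time = c(1, 1.5), side = c("L", "R"),
                        type = "IC", sampling_rate = 100)
  expect_error(estimate_walking_speed(st$trial, ic_events = one_ic,
                                      prep = prep_comfortable()),
               "walking speed")
})

test_that("doubling the playback speed doubles the walking-speed estimate", {
  st <- sim_comfortable()
  tr2 <- st$trial
  tr2$time <- tr2$time / 2
  tr2$sampling_rate <- tr2$sampling_rate * 2
  # the debounce window is a physical time, so it is rescaled along with
  # the playback to keep the detector's event set identical
  ic2 <- detect_ic_velocity3d(tr2, detector_params(
    "M5", min_event_separation = 0.1))
  ws2 <- estimate_walking_speed(tr2, ic_events = ic2)
  ws1 <- estimate_walking_speed(st$trial, prep = prep_comfortable())
  expect_equal(ws2 / ws1, 2, tolerance = 0.1)
})

test_that("M1 recovers one IC and FC per cycle and is translation invariant", {
  st <- sim_comfortable()
  ev <- detect_m1(st$trial, prep = prep_comfortable())
  truth <- st$truth$events
  for (ty in c("IC", "FC")) {
    expect_equal(sum(ev$type == ty), sum(truth$type == ty))
  }
  tr2 <- st$trial
  for (m in names(tr2$trajectories)) {
    tr2$trajectories[[m]] <- tr2$trajectories[[m]] +
      matrix(c(10, -20, 5), nrow(tr2$trajectories[[m]]), 3, byrow = TRUE)
  }
  ev2 <- detect_m1(tr2)
  expect_equal(ev2$time, ev$time)
  # no pelvis -> warning and empty set
  tr3 <- st$trial
  tr3$trajectories <- tr3$trajectories[c("LHEEL", "RHEEL", "LTOE", "RTOE")]
  tr3$valid <- tr3$valid[names(tr3$trajectories)]
  expect_warning(ev3 <- detect_m1(tr3), "pelvis")
  expect_equal(nrow(ev3), 0L)
})

test_that("adaptive thresholds reproduce fixed ones when forced", {
  st <- sim_comfortable()
  tr <- st$trial
  prep <- prep_comfortable()
  # IC: 0.5 x ws = 0.5 m/s at ws = 1
  icM5 <- detect_ic_velocity3d(tr, detector_params("M5"), prep = prep)
  icM7 <- detect_ic_velocity3d(tr, detector_params("M7", walking_speed = 1),
                               prep = prep)
  expect_equal(icM7$time, icM5$time)
  expect_identical(icM7$foot_strike, icM5$foot_strike)
  # FC: 0.8 x ws = 1.0 m/s at ws = 1.25
  fcM5 <- detect_fc_velocity3d(tr, detector_params("M5"), prep = prep)
  fcM7 <- detect_fc_velocity3d(tr, detector_params("M7",
                                                   walking_speed = 1.25),
                               prep = prep)
  expect_equal(fcM7$time, fcM5$time)
  # M6 IC with 0.78 x ws = 0.5
  m4 <- detect_sagittal_velocity(tr, detector_params("M4"), prep = prep)
  m6 <- detect_sagittal_velocity(tr, detector_params("M6",
                                 walking_speed = 0.5 / 0.78), prep = prep)
  expect_equal(m6$time[m6$type == "IC"], m4$time[m4$type == "IC"])
})

test_that("every detector emits ordered, debounced per-(side,type) events", {
  st <- sim_comfortable()
  prep <- prep_comfortable()
  for (method in paste0("M", 1:10)) {
    ev <- suppressWarnings(detect_events(st$trial, method, prep = prep))
    for (s in c("L", "R")) for (ty in c("IC", "FC")) {
      tt <- ev$time[ev$side == s & ev$type == ty]
      if (length(tt) > 1L) {
        expect_true(all(diff(tt) > 0), label = paste(method, s, ty))
        expect_true(all(diff(tt) >= 0.2 - 1e-9),
                    label = paste(method, s, ty, "separation"))
      }
    }
  }
})

test_that("time-shifting a trial shifts every event time exactly", {
  st <- sim_comfortable()
  ev <- detect_events(st$trial, "M5", prep = prep_comfortable())
  tr2 <- st$trial
  tr2$time <- tr2$time + 7
  ev2 <- detect_events(tr2, "M5")
  expect_equal(ev2$time, ev$time + 7, tolerance = 1e-9)
})

test_that("M10 fuses M1 anchors with M7 refinements", {
  st <- sim_comfortable()
  prep <- prep_comfortable()
  m10 <- detect_events(st$trial, "M10", prep = prep)
  ws <- estimate_walking_speed(st$trial, prep = prep)
  m7 <- detect_events(st$trial, "M7",
                      params = detector_params("M7", walking_speed = ws),
                      prep = prep)
  # on clean gait every M10 event is an M7 event (refinement took over)
  expect_true(all(m10$time %in% m7$time))
  expect_true(all(m10$method == "M10"))
  # IC strike labels inherited from the 3D-velocity rule
  expect_true(all(m10$foot_strike[m10$type == "IC"] == "rearfoot"))
})

test_that("M10 under full pelvis occlusion equals M7 exactly", {
  occl <- cached("occluded", simulate_trial(synthetic_gait_spec(
    n_strides = 6, stride_length = 1.2, stride_duration = 1.0,
    occlusions = list(list(marker = "PELVIS", start = 0, duration = Inf)))))
  prep <- prepare_trial(occl$trial)
  m10 <- suppressWarnings(detect_events(occl$trial, "M10", prep = prep))
  ws <- estimate_walking_speed(occl$trial, prep = prep)
  m7 <- detect_events(occl$trial, "M7",
                      params = detector_params("M7", walking_speed = ws),
                      prep = prep)
  expect_equal(m10$time, m7$time)
  expect_identical(m10$side, m7$side)
  expect_identical(m10$type, m7$type)
  expect_identical(m10$foot_strike, m7$foot_strike)
})

test_that("noiseless recovery: M5/M7/M10 find every event within 2 frames", {
  st <- sim_comfortable()
  prep <- prep_comfortable()
  truth <- st$truth$events
  for (method in c("M5", "M7", "M10")) {
    ev <- detect_events(st$trial, method, prep = prep)
    for (s in c("L", "R")) for (ty in c("IC", "FC")) {
      det <- ev$time[ev$side == s & ev$type == ty]
      ref <- truth$time[truth$side == s & truth$type == ty]
      expect_equal(length(det), length(ref),
                   label = paste(method, s, ty, "count"))
      expect_lt(max(abs(det - ref)), 2 / 100 + 1e-9)
    }
  }
})
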