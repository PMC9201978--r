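test_that("a 180-degree U-turn yields exactly one curvilinear segment", {
  st <- sim_uturn()
  prep <- cached("uturn_prep", prepare_trial(st$trial))
  cw <- detect_curvilinear(prep$frames)
  expect_equal(nrow(cw), 1L)
  expect_equal(abs(cw$total_yaw), 180, tolerance = 10)
  expect_gte(cw$peak_yaw_rate, 15)
  expect_gte(cw$end - cw$start, 0.5)
  expect_lte(cw$end - cw$start, 10)
  # ground truth agrees
  expect_equal(nrow(st$truth$cw_segments), 1L)
})

test_that("gait-like yaw sway produces no curvilinear segments", {
  fs <- 100
  t <- seq(0, 12, 1 / fs)
  yaw <- 10 * sin(2 * pi * 0.9 * t)          # +-10 degrees, below 45
  expect_equal(nrow(curvilinear_segments_from_yaw(yaw, t, fs)), 0L)
  # a whole simulated trial with exaggerated (+-15 deg) sway: still none
  sway <- cached("sway", simulate_trial(synthetic_gait_spec(
    n_strides = 8, stride_length = 1.2, stride_duration = 1.0,
    yaw_sway_deg = 15)))
  prep <- prepare_trial(sway$trial)
  expect_equal(nrow(detect_curvilinear(prep$frames)), 0L)
})

test_that("a slow wide rotation is rejected on segment duration", {
  fs <- 100
  t <- seq(0, 13, 1 / fs)
  u <- pmin(pmax((t - 1) / 11, 0), 1)
  rate <- 1.5 + 15.5 * sin(pi * u)^16        # 50 deg over 11 s, peak ~17
  rate[u <= 0 | u >= 1] <- 0
  yaw <- cumsum(rate) / fs
  segs <- curvilinear_segments_from_yaw(yaw, t, fs)
  expect_equal(nrow(segs), 0L)
  rej <- attr(segs, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$reason, "duration")
  expect_gte(abs(rej$total_yaw), 45)
  expect_gt(rej$duration, 10)
})

test_that("step negotiation uses the strict 0.15 m inequality", {
  fs <- 100
  n <- 600
  t <- (seq_len(n) - 1) / fs
  mkz <- function(z) cbind(t, 0, z)
  heel_z <- rep(0.05, n)
  heel_z[t >= 2] <- 0.05 + 0.20                # 0.20 m step before 3rd IC
  tr <- marker_trial("steps", fs, t, list(
    RHEEL = mkz(heel_z), RTOE = mkz(heel_z - 0.02),
    LHEEL = mkz(rep(0.05, n)), LTOE = mkz(rep(0.03, n))))
  ics <- gait_events(time = c(1, 2.5, 4), side = "R", type = "IC",
                     sampling_rate = fs)
  sn <- detect_step_negotiation(tr, ics)
  expect_equal(nrow(sn), 1L)
  expect_equal(sn$height_change, 0.20, tolerance = 1e-9)
  expect_equal(c(sn$start, sn$end), c(1, 2.5))
  # exactly 0.15 m: not step negotiation
  tr2 <- tr
  tr2$trajectories$RHEEL[, 3] <- ifelse(t >= 2, 0.05 + 0.15, 0.05)
  expect_equal(nrow(detect_step_negotiation(tr2, ics)), 0L)
  # level walking
  tr3 <- tr
  tr3$trajectories$RHEEL[, 3] <- 0.05
  expect_equal(nrow(detect_step_negotiation(tr3, ics)), 0L)
})

test_that("simulated 0.20 m step produces SN ground truth and detection", {
  st <- sim_step(0.20)
  ev <- detect_events(st$trial, "M10",
                      prep = cached("step_prep", prepare_trial(st$trial)))
  sn <- detect_step_negotiation(st$trial, ev)
  expect_gte(nrow(sn), 1L)
  expect_true(all(abs(sn$height_change) > 0.15))
  expect_gte(nrow(st$truth$sn_segments), 1L)
  # a 0.15 m-exact simulated step yields no SN segments (strict inequality)
  st2 <- sim_step(0.15)
  ev2 <- detect_events(st2$trial, "M10")
  expect_equal(nrow(detect_step_negotiation(st2$trial, ev2)), 0L)
  expect_equal(nrow(st2$truth$sn_segments), 0L)
})

test_that("event labeling partitions into SW/CW/SN with SN precedence", {
  ev <- gait_events(time = c(1, 3, 5, 7), side = "R", type = "IC",
                    sampling_rate = 100)
  cw <- data.frame(label = "CW", start = 2.5, end = 5.5)
  sn <- data.frame(label = "SN", start = 4.5, end = 6)
  out <- label_events(ev, cw, sn)
  expect_equal(out$condition, c("SW", "CW", "SN", "SW"))
  # no segments: everything SW
  out2 <- label_events(ev, NULL, NULL)
  expect_true(all(out2$condition == "SW"))
  expect_true(all(out$condition %in% c("SW", "CW", "SN")))
})

test_that("condition labels survive a horizontal rotation of the scene", {
  st <- sim_uturn()
  tr2 <- st$trial
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  for (m in names(tr2$trajectories)) {
    tr2$trajectories[[m]] <- tr2$trajectories[[m]] %*% t(R)
  }
  cw1 <- detect_curvilinear(cached("uturn_prep",
                                   prepare_trial(st$trial))$frames)
  cw2 <- detect_curvilinear(prepare_trial(tr2)$frames)
  expect_equal(nrow(cw2), nrow(cw1))
  expect_equal(cw2$start, cw1$start, tolerance = 0.02)
  expect_equal(abs(cw2$total_yaw), abs(cw1$total_yaw), tolerance = 1)
})

test_that("simulator labels and pipeline labels agree on mixed trials", {
  for (st in list(sim_uturn(), sim_step(0.20))) {
    prep <- prepare_trial(st$trial)
    ev <- detect_events(st$trial, "M10", prep = prep)
    cw <- detect_curvilinear(prep$frames)
    sn <- detect_step_negotiation(st$trial, ev)
    lab <- label_events(ev, cw, sn)
    truth <- st$truth$events
    agree <- 0L; total <- 0L
    for (i in seq_len(nrow(truth))) {
      j <- which(lab$side == truth$side[i] & lab$type == truth$type[i] &
                 abs(lab$time - truth$time[i]) <= 0.25)
      if (length(j)) {
        total <- total + 1L
        if (lab$condition[j[1]] == truth$condition[i]) agree <- agree + 1L
      }
    }
    expect_gte(agree / total, 0.95)
  }
})
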