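test_that("fill_gaps interpolates short interior gaps only", {
  fs <- 100
  t <- (0:399) / fs
  pos <- cbind(sin(2 * pi * 0.8 * t), cos(2 * pi * 0.8 * t), t)
  base <- list(LHEEL = pos, RHEEL = pos + 1, LTOE = pos + 2, RTOE = pos + 3)

  gap <- function(tr, marker, idx) {
    tr$trajectories[[marker]][idx, ] <- NA_real_
    tr$valid[[marker]][idx] <- FALSE
    tr
  }
  tr <- marker_trial("gaps", fs, t, base)
  tr <- gap(tr, "LHEEL", 101:130)   # 0.3 s interior
  tr <- gap(tr, "RHEEL", 151:210)   # 0.6 s interior
  tr <- gap(tr, "LTOE", 1:20)       # leading

  out <- fill_gaps(tr, max_gap = 0.5)
  expect_true(all(out$valid$LHEEL[101:130]))
  # cubic accuracy across a 0.3 s hole in a 0.8 Hz signal:
  # |f''''| h^4 / 384 ~ 0.014
  expect_lt(max(abs(out$trajectories$LHEEL[101:130, ] - pos[101:130, ])),
            0.02)
  # and agrees with an independently computed natural spline
  oracle <- stats::spline(x = t[tr$valid$LHEEL],
                          y = pos[tr$valid$LHEEL, 1],
                          xout = t[101:130], method = "natural")$y
  expect_lt(max(abs(out$trajectories$LHEEL[101:130, 1] - oracle)), 1e-9)
  expect_false(any(out$valid$RHEEL[151:210]))
  expect_false(any(out$valid$LTOE[1:20]))
  # gap-free trial is returned unchanged
  tr2 <- marker_trial("nogap", fs, t, base)
  out2 <- fill_gaps(tr2)
  expect_identical(out2$trajectories, tr2$trajectories)
})

test_that("zero-phase Butterworth: DC gain, cutoff gain, reversal symmetry", {
  fs <- 100
  expect_lt(max(abs(lowpass_filter(rep(3.3, 200), fs, 7) - 3.3)), 1e-9)
  t <- seq(0, 10, 1 / fs)
  y <- lowpass_filter(sin(2 * pi * 7 * t), fs, cutoff = 7)
  # two squared passes at the cutoff: |H|^2 = 1/2
  expect_equal(max(abs(y[300:700])), 0.5, tolerance = 0.05)
  set.seed(3)
  x <- rnorm(500)
  expect_lt(max(abs(rev(lowpass_filter(rev(x), fs, 7)) -
                    lowpass_filter(x, fs, 7))), 1e-6)
})

test_that("segments too short to pad are left unfiltered with a warning", {
  x <- c(rep(NA_real_, 5), rnorm(12), rep(NA_real_, 5))
  expect_warning(out <- lowpass_filter(x, 100, 7), "too short")
  expect_identical(out[6:17], x[6:17])
})

test_that("differentiation is exact for low-degree polynomials", {
  fs <- 100
  t <- (0:99) / fs
  ramp <- 1.2 * t
  v <- differentiate(ramp, fs)
  expect_lt(max(abs(v[2:99] - 1.2)), 1e-9)
  expect_lt(max(abs(differentiate(rep(5, 100), fs))), 1e-12)
  # quadratic: central differences exact in the interior
  q <- 3 * t^2
  a <- differentiate(q, fs)
  expect_lt(max(abs(a[2:99] - 6 * t[2:99])), 1e-9)
  # sinusoid obeys the Taylor truncation bound in the interior
  f <- 2
  s <- sin(2 * pi * f * t)
  ds <- differentiate(s, fs)
  bound <- (2 * pi * f)^3 / (6 * fs^2)
  expect_lt(max(abs(ds[2:99] - 2 * pi * f * cos(2 * pi * f * t[2:99]))),
            bound * 1.01)
  expect_true(all(is.na(differentiate(c(NA, 1, 2, NA), fs))))
})

test_that("pelvis frames: axis-aligned configuration and orthonormality", {
  tr <- axis_aligned_trial()
  fr <- build_pelvis_frames(tr)
  mid <- 100
  expect_equal(fr$ml[mid, ], c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$ap[mid, ], c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr$v[mid, ], c(0, 0, 1), tolerance = 1e-9)
  # orthonormal wherever valid, on a realistic simulated trial too
  pr <- prep_comfortable()
  fr2 <- pr$frames
  ok <- which(fr2$valid)
  for (ax in list(fr2$ml, fr2$ap, fr2$v)) {
    expect_lt(max(abs(sqrt(rowSums(ax[ok, ]^2)) - 1)), 1e-9)
  }
  expect_lt(max(abs(rowSums(fr2$ml[ok, ] * fr2$ap[ok, ]))), 1e-9)
  expect_lt(max(abs(rowSums(fr2$ml[ok, ] * fr2$v[ok, ]))), 1e-9)
  expect_lt(max(abs(rowSums(fr2$ap[ok, ] * fr2$v[ok, ]))), 1e-9)
})

test_that("pelvis frames: occlusion and collinearity invalidate frames", {
  tr <- axis_aligned_trial()
  tr$valid$P0[] <- FALSE
  fr <- build_pelvis_frames(tr)
  expect_false(any(fr$valid))
  tr2 <- axis_aligned_trial()
  tr2$trajectories$P3 <- (tr2$trajectories$P0 + tr2$trajectories$P1) / 2
  fr2 <- build_pelvis_frames(tr2)
  expect_false(any(fr2$valid))
})

test_that("pelvis frames rotate with a rigid rotation of the scene", {
  tr <- axis_aligned_trial()
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr2 <- tr
  for (m in names(tr2$trajectories)) {
    tr2$trajectories[[m]] <- tr2$trajectories[[m]] %*% t(R)
  }
  fr <- build_pelvis_frames(tr)
  fr2 <- build_pelvis_frames(tr2)
  expect_lt(max(abs(fr2$ml - fr$ml %*% t(R))), 1e-9)
  expect_lt(max(abs(fr2$ap - fr$ap %*% t(R))), 1e-9)
  expect_lt(max(abs(fr2$v - fr$v %*% t(R))), 1e-9)
})

test_that("decomposition is relative and translation invariant", {
  tr <- axis_aligned_trial()
  fr <- build_pelvis_frames(tr)
  # a marker 0.3 m ahead of the origin along AP
  probe <- fr$origin + matrix(c(0, 0.3, 0), nrow(fr$origin), 3, byrow = TRUE)
  d <- decompose(probe, fr)
  expect_equal(unname(unlist(d[50, ])), c(0.3, 0, 0), tolerance = 1e-9)
  # rigid translation of the whole scene leaves relative components alone
  tr2 <- tr
  for (m in names(tr2$trajectories)) {
    tr2$trajectories[[m]] <- tr2$trajectories[[m]] +
      matrix(c(5, -3, 2), nrow(tr2$trajectories[[m]]), 3, byrow = TRUE)
  }
  fr2 <- build_pelvis_frames(tr2)
  d1 <- decompose(tr$trajectories$LHEEL, fr)
  d2 <- decompose(tr2$trajectories$LHEEL, fr2)
  expect_lt(max(abs(as.matrix(d1) - as.matrix(d2))), 1e-9)
})
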