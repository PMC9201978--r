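test_that("tolerance-window matching classifies TP/FN/FP correctly", {
  m <- match_events(c(1.1, 2.3), c(1.0, 2.0), tw = 0.5)
  expect_equal(m$tp, 1L)
  expect_equal(m$pairs$dt, 0.1)
  expect_equal(m$fn_times, 2.0)
  expect_equal(m$fp_times, 2.3)
  # identical sets: all TP with zero error
  m2 <- match_events(1:5, 1:5, 0.5)
  expect_equal(m2$tp, 5L)
  expect_true(all(m2$pairs$dt == 0))
  # empty detected: all FN
  m3 <- match_events(numeric(0), 1:4, 0.5)
  expect_equal(m3$fn, 4L)
  expect_equal(m3$tp, 0L)
})

test_that("matching count identities hold on random event sets", {
  set.seed(101)
  for (i in 1:50) {
    ref <- sort(runif(sample(0:8, 1), 0, 10))
    det <- sort(runif(sample(0:8, 1), 0, 10))
    m <- match_events(det, ref, 0.5)
    expect_equal(m$tp + m$fn, length(ref))
    expect_equal(m$tp + m$fp, length(det))
    if (m$tp) expect_true(all(abs(m$pairs$dt) <= 0.25))
  }
})

test_that("greedy matching tracks the exhaustive optimum", {
  set.seed(202)
  diverged <- 0L
  for (i in 1:100) {
    ref <- sort(runif(sample(2:6, 1), 0, 5))
    det <- sort(runif(sample(2:6, 1), 0, 5))
    g <- match_events(det, ref, 0.5)$tp
    e <- exhaustive_tp(det, ref, 0.5)
    expect_lte(g, e)          # greedy can never beat the optimum
    if (g != e) diverged <- diverged + 1L
  }
  # time-ordered nearest-neighbour matching occasionally drops one pair
  # relative to the exhaustive optimum; the divergence is rare
  expect_lte(diverged, 5L)
})

test_that("classification scores match the defining formulas", {
  sc <- classification_scores(9, fn = 1, fp = 0)
  expect_equal(unname(sc), c(0.9, 1, 2 * 0.9 / 1.9), tolerance = 1e-9)
  expect_equal(unname(classification_scores(7, fn = 0, fp = 0)),
               c(1, 1, 1))
  set.seed(9)
  for (i in 1:1000) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1); fp <- sample(0:20, 1)
    sc <- classification_scores(tp, fn = fn, fp = fp)
    S <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    P <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    F1 <- if (is.na(S) || is.na(P)) NA_real_
          else if (S + P == 0) 0 else 2 * P * S / (P + S)
    expect_identical(is.na(sc), is.na(c(S = S, PPV = P, F1 = F1)))
    if (!anyNA(sc)) {
      expect_equal(unname(sc), c(S, P, F1), tolerance = 1e-12)
      # harmonic mean lies between its arguments
      expect_gte(sc["F1"] + 1e-12, min(S, P))
      expect_lte(sc["F1"] - 1e-12, max(S, P))
    }
  }
})

test_that("timing-error statistics use the declared quantile convention", {
  e <- c(-0.020, -0.010, 0, 0.010, 0.020)
  st <- timing_error_stats(e)
  expect_equal(unname(st), c(0, 0.020, 0.010))
  expect_equal(unname(timing_error_stats(rep(0, 5))), c(0, 0, 0))
  # sign flip negates the bias, preserves precision and accuracy
  st2 <- timing_error_stats(-e)
  expect_equal(st2[["ME"]], -st[["ME"]])
  expect_equal(st2[["IQRE"]], st[["IQRE"]])
  expect_equal(st2[["MAE"]], st[["MAE"]])
  expect_true(all(is.na(timing_error_stats(numeric(0)))))
})

test_that("false-negative imputation switches at the 5% missing fraction", {
  pool <- c(-0.04, 0.01, 0.02, 0.03, 0.01, 0.02, 0.00, 0.01, 0.02)
  # 1 FN among 10 expected: 10% > 5% -> worst (max-magnitude, signed)
  out <- impute_fn_errors(pool, 1)
  expect_equal(out[length(out)], -0.04)
  # 2 FN among 100 expected: 2% <= 5% -> mean
  pool2 <- rep(0.01, 98)
  out2 <- impute_fn_errors(pool2, 2)
  expect_equal(out2[99:100], rep(mean(pool2), 2))
  expect_identical(impute_fn_errors(pool, 0), pool)
  expect_error(impute_fn_errors(numeric(0), 3), "empty pool")
})

test_that("stride errors pair through TP initial contacts", {
  st <- sim_comfortable()
  ref <- compute_stride_params(assemble_strides(st$truth$events), st$trial)
  # identical tables: zero errors, nothing missing
  err <- stride_param_errors(ref, ref)
  expect_equal(err$n_missing, 0L)
  expect_true(all(abs(err$pairs$duration_err) < 1e-12))
  expect_true(all(abs(err$pairs$speed_rel) < 1e-9))
  # one-frame shift of every detected IC: durations unchanged, the
  # stance/swing split moves by one frame
  ev2 <- st$truth$events
  ev2$time[ev2$type == "IC"] <- ev2$time[ev2$type == "IC"] + 0.01
  det <- compute_stride_params(assemble_strides(ev2), st$trial)
  err2 <- stride_param_errors(det, ref)
  expect_true(all(abs(err2$pairs$duration_err) < 1e-9))
  expect_true(all(abs(err2$pairs$stance_err + 0.01) < 1e-9))
  expect_true(all(abs(err2$pairs$swing_err - 0.01) < 1e-9))
  # an absolute example: +10 ms on 1.10 s is +0.909%
  expect_equal(100 * 0.01 / 1.10, 0.909, tolerance = 1e-3)
})

test_that("agreement statistics: exact cases", {
  x <- c(1.1, 1.2, 1.3, 1.4, 1.5)
  ag <- agreement_stats(x, x)
  expect_equal(ag$icc, 1)
  expect_equal(ag$spearman, 1)
  expect_equal(ag$bias, 0)
  expect_equal(ag$rmse, 0)
  expect_equal(unname(ag$loa), c(0, 0))
  # constant offset: bias = d, zero spread
  ag2 <- agreement_stats(x + 0.2, x)
  expect_equal(ag2$bias, 0.2)
  expect_equal(ag2$rmse, 0.2)
  expect_equal(ag2$sd_diff, 0)
  expect_error(agreement_stats(1:2, 1:2), "at least 3")
})

test_that("ICC(2,1) matches an aov-based mean-squares oracle to 1e-10", {
  set.seed(77)
  for (i in 1:50) {
    x <- rnorm(30)
    y <- x + rnorm(30, 0.1, 0.4)
    ag <- agreement_stats(x, y)
    df <- data.frame(v = c(x, y), subj = factor(rep(1:30, 2)),
                     rater = factor(rep(1:2, each = 30)))
    av <- summary(stats::aov(v ~ rater + Error(subj), data = df))
    msr <- av[[1]][[1]]["Residuals", "Mean Sq"]
    msc <- av[[2]][[1]]["rater", "Mean Sq"]
    mse <- av[[2]][[1]]["Residuals", "Mean Sq"]
    icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 30)
    expect_lt(abs(ag$icc - icc_oracle), 1e-10)
    # the confidence interval brackets the estimate
    expect_lte(ag$icc_ci[1], ag$icc + 1e-12)
    expect_gte(ag$icc_ci[2], ag$icc - 1e-12)
  }
})

test_that("RMSE decomposes into bias and spread on every paired table", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    ag <- agreement_stats(x, y)
    expect_equal(ag$rmse^2,
                 ag$bias^2 + ag$sd_diff^2 * (n - 1) / n,
                 tolerance = 1e-12)
    # limits of agreement bracket the bias
    expect_lte(ag$loa[["lower"]], ag$bias)
    expect_gte(ag$loa[["upper"]], ag$bias)
    expect_gte(ag$rmse, abs(ag$bias) - 1e-12)
  }
})

test_that("per-stratum evaluation excludes occlusion-impossible references", {
  st <- sim_comfortable()
  tr <- st$trial
  truth <- st$truth$events
  # occlude the right foot around one reference IC
  t_occl <- truth$time[truth$side == "R" & truth$type == "IC"][3]
  idx <- which(abs(tr$time - t_occl) <= 0.05)
  tr$valid$RHEEL[idx] <- FALSE
  tr$trajectories$RHEEL[idx, ] <- NA_real_
  det <- truth  # perfect detector
  p_full <- evaluate_performance(det, truth, trial = st$trial)
  p_occl <- evaluate_performance(det, truth, trial = tr)
  ic_full <- p_full[p_full$type == "IC" & p_full$condition == "all", ]
  ic_occl <- p_occl[p_occl$type == "IC" & p_occl$condition == "all", ]
  expect_equal(ic_occl$tp + 1L, ic_full$tp)
})
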