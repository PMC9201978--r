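# Shared fixtures: small simulated trials, cached (with their prepared
# kinematics) so the suite does not re-filter the same trial repeatedly.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

sim_comfortable <- function() {
  cached("comfortable", simulate_trial(synthetic_gait_spec(
    n_strides = 6, stride_length = 1.2, stride_duration = 1.0)))
}

prep_comfortable <- function() {
  cached("comfortable_prep", prepare_trial(sim_comfortable()$trial))
}

sim_forefoot <- function() {
  cached("forefoot", simulate_trial(synthetic_gait_spec(
    n_strides = 6, stride_length = 1.2, stride_duration = 1.0,
    foot_strike = "forefoot")))
}

prep_forefoot <- function() {
  cached("forefoot_prep", prepare_trial(sim_forefoot()$trial))
}

sim_uturn <- function() {
  cached("uturn", simulate_trial(synthetic_gait_spec(
    n_strides = 10, stride_length = 1.2, stride_duration = 1.0,
    turn = list(angle = 180, start = 4, duration = 2.5))))
}

sim_step <- function(height = 0.20) {
  cached(paste0("step", height), simulate_trial(synthetic_gait_spec(
    n_strides = 8, stride_length = 1.2, stride_duration = 1.0,
    step = list(height = height, position = 5))))
}

# minimal straight-walk trial built by hand (no simulator) for frame tests:
# pelvis advancing along +y, axis-aligned cluster
axis_aligned_trial <- function(n = 200, fs = 100) {
  t <- (seq_len(n) - 1) / fs
  y <- 1.2 * t
  marker_trial("axis_aligned", fs, t, list(
    LHEEL = cbind(0.05, y - 0.3, 0.05), RHEEL = cbind(0.25, y - 0.3, 0.05),
    LTOE = cbind(0.05, y - 0.1, 0.03), RTOE = cbind(0.25, y - 0.1, 0.03),
    P0 = cbind(0, y, 1), P1 = cbind(0.2, y, 1), P3 = cbind(0.1, y, 0.8)))
}

# exhaustive optimal one-to-one matching (branch and bound), the
# independent oracle for the greedy matcher
exhaustive_tp <- function(det, ref, tw) {
  if (!length(ref) || !length(det)) return(0L)
  best <- 0L
  rec <- function(ri, used, count) {
    if (count + (length(ref) - ri + 1L) <= best) return(invisible())
    if (ri > length(ref)) { best <<- max(best, count); return(invisible()) }
    rec(ri + 1L, used, count)
    for (j in seq_along(det)) {
      if (!used[j] && abs(det[j] - ref[ri]) <= tw / 2) {
        u <- used; u[j] <- TRUE
        rec(ri + 1L, u, count + 1L)
      }
    }
  }
  rec(1L, rep(FALSE, length(det)), 0L)
  best
}

# per-stratum row helper
perf_row <- function(perf, ty, cond = "all") {
  perf[perf$type == ty & perf$condition == cond, , drop = FALSE]
}
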