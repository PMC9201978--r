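# Event-level validation (tolerance-window matching, classification scores,
# timing-error statistics) and stride-level agreement statistics.

#' Match detected to reference events within a tolerance window
#'
#' One-to-one, time-ordered greedy matching: reference events are processed
#' in time order and each is paired with the nearest unmatched detected
#' event within half the tolerance window. Unmatched reference events are
#' false negatives, unmatched detected events false positives.
#'
#' @param detected,reference numeric vectors of event times (one side and
#'   type at a time) or [gait_events()] tables (then matched per side/type
#'   jointly only if both are single-stratum).
#' @param tw full tolerance-window width, seconds (default 0.5; a detection
#'   within +-tw/2 of a reference event can match it).
#' @return list of class `match_result`: `pairs` (data.frame `ref`, `det`,
#'   `dt = det - ref`), `fn_times`, `fp_times`, counts `tp`, `fn`, `fp`,
#'   and `tw`.
#' @export
match_events <- function(detected, reference, tw = 0.5) {
  if (is.data.frame(detected)) detected <- detected$time
  if (is.data.frame(reference)) reference <- reference$time
  detected <- sort(detected); reference <- sort(reference)
  used <- rep(FALSE, length(detected))
  ref_m <- det_m <- numeric(0)
  for (r in reference) {
    if (!length(detected)) break
    d <- abs(detected - r)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tw / 2) {
      used[j] <- TRUE
      ref_m <- c(ref_m, r); det_m <- c(det_m, detected[j])
    }
  }
  pairs <- data.frame(ref = ref_m, det = det_m, dt = det_m - ref_m)
  structure(list(pairs = pairs,
                 fn_times = setdiff(reference, ref_m),
                 fp_times = detected[!used],
                 tp = nrow(pairs),
                 fn = length(reference) - nrow(pairs),
                 fp = sum(!used),
                 tw = tw),
            class = "match_result")
}

#' Sensitivity, positive predictive value and F1
#'
#' S = TP/(TP+FN), PPV = TP/(TP+FP), F1 = 2 PPV S / (PPV + S). Undefined
#' ratios (zero denominators) are returned as NA; F1 is 0 when S and PPV
#' are both 0 and NA when either is undefined.
#'
#' @param match a [match_events()] result, or TP count.
#' @param fn,fp counts when `match` is a TP count.
#' @return named numeric vector `c(S, PPV, F1)` (fractions).
#' @export
classification_scores <- function(match, fn = NULL, fp = NULL) {
  if (inherits(match, "match_result")) {
    tp <- match$tp; fn <- match$fn; fp <- match$fp
  } else {
    tp <- match
  }
  S <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  PPV <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  F1 <- if (is.na(S) || is.na(PPV)) NA_real_
        else if (S + PPV == 0) 0
        else 2 * PPV * S / (PPV + S)
  c(S = S, PPV = PPV, F1 = F1)
}

#' Timing-error statistics: bias, precision, accuracy
#'
#' ME (median error, bias), IQRE (inter-quartile-range error, precision)
#' and MAE (median absolute error, accuracy) of the timing errors
#' `dt = detected - reference` (negative = anticipation). Quantiles use
#' linear interpolation between order statistics (R type 7).
#'
#' @param errors numeric vector of timing errors (seconds).
#' @return named numeric vector `c(ME, IQRE, MAE)`; all NA when empty.
#' @export
timing_error_stats <- function(errors) {
  errors <- errors[is.finite(errors)]
  if (!length(errors)) {
    return(c(ME = NA_real_, IQRE = NA_real_, MAE = NA_real_))
  }
  q <- stats::quantile(errors, c(0.25, 0.75), names = FALSE, type = 7)
  c(ME = stats::median(errors), IQRE = q[2] - q[1],
    MAE = stats::median(abs(errors)))
}

#' Impute timing errors for false negatives
#'
#' When more than 5% of the expected events are missing, each false
#' negative is assigned the highest observed error of the method (the
#' maximum-magnitude error, keeping its sign); otherwise the mean observed
#' error. False positives never enter the error pool.
#'
#' @param errors observed timing errors (the TP pool for the method).
#' @param n_fn number of false negatives to impute.
#' @param missing_threshold fraction above which the worst-case value is
#'   used (default 0.05).
#' @return `errors` with `n_fn` imputed values appended.
#' @export
impute_fn_errors <- function(errors, n_fn, missing_threshold = 0.05) {
  if (n_fn == 0) return(errors)
  pool <- errors[is.finite(errors)]
  if (!length(pool)) stop("cannot impute false-negative errors: empty pool")
  frac_missing <- n_fn / (n_fn + length(pool))
  fill <- if (frac_missing > missing_threshold) {
    pool[which.max(abs(pool))]
  } else {
    mean(pool)
  }
  c(errors, rep(fill, n_fn))
}

#' Pair detected and reference strides and compute parameter errors
#'
#' Strides are paired through true-positive initial contacts: both bounding
#' reference ICs must match the corresponding detected stride's bounding
#' ICs inside the tolerance window. Remaining strides are counted missing.
#' For each parameter (duration, stance, swing, length, speed) the absolute
#' error `detected - reference` and the relative error (percent of the
#' reference) are returned, with ME/IQRE/MAE summaries and the fraction of
#' absolute errors within the resolution (`1/sampling_rate` for temporal
#' parameters, `spatial_resolution` for length, 0.01 m/s for speed).
#'
#' @param detected,reference stride tables (see [compute_stride_params()]).
#' @param tw tolerance window for IC matching, seconds.
#' @param sampling_rate Hz, for the temporal resolution.
#' @param spatial_resolution meters (default 0.001).
#' @return list of class `stride_error_table`: `pairs` (per-stride errors),
#'   `summary` (per-parameter ME/IQRE/MAE, absolute and relative),
#'   `n_missing`.
#' @export
stride_param_errors <- function(detected, reference, tw = 0.5,
                                sampling_rate = 100,
                                spatial_resolution = 0.001) {
  params <- c("duration", "stance", "swing", "length", "speed")
  res_of <- c(duration = 1 / sampling_rate, stance = 1 / sampling_rate,
              swing = 1 / sampling_rate, length = spatial_resolution,
              speed = 0.01)
  rows <- list()
  n_missing <- 0L
  for (side in c("L", "R")) {
    det <- detected[detected$side == side, , drop = FALSE]
    ref <- reference[reference$side == side, , drop = FALSE]
    if (!nrow(ref)) next
    ics_det <- sort(unique(c(det$t_ic_start, det$t_ic_end)))
    m <- match_events(ics_det, sort(unique(c(ref$t_ic_start,
                                             ref$t_ic_end))), tw)
    map <- stats::setNames(m$pairs$det, sprintf("%.9f", m$pairs$ref))
    for (i in seq_len(nrow(ref))) {
      k1 <- sprintf("%.9f", ref$t_ic_start[i])
      k2 <- sprintf("%.9f", ref$t_ic_end[i])
      if (!(k1 %in% names(map) && k2 %in% names(map))) {
        n_missing <- n_missing + 1L; next
      }
      j <- which(abs(det$t_ic_start - map[[k1]]) < 1e-9 &
                 abs(det$t_ic_end - map[[k2]]) < 1e-9)
      if (length(j) != 1L) { n_missing <- n_missing + 1L; next }
      row <- data.frame(side = side, t_ref = ref$t_ic_start[i],
                        condition = if ("condition" %in% names(ref))
                          ref$condition[i] else "SW")
      for (p in params) {
        dv <- if (p %in% names(det)) det[[p]][j] else NA_real_
        rv <- if (p %in% names(ref)) ref[[p]][i] else NA_real_
        row[[paste0(p, "_err")]] <- dv - rv
        row[[paste0(p, "_rel")]] <- 100 * (dv - rv) / rv
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else NULL
  summ <- list()
  for (p in params) {
    e <- if (!is.null(pairs)) pairs[[paste0(p, "_err")]] else numeric(0)
    r <- if (!is.null(pairs)) pairs[[paste0(p, "_rel")]] else numeric(0)
    st <- timing_error_stats(e)
    str <- timing_error_stats(r)
    summ[[p]] <- data.frame(parameter = p,
                            ME = st["ME"], IQRE = st["IQRE"], MAE = st["MAE"],
                            ME_rel = str["ME"], IQRE_rel = str["IQRE"],
                            MAE_rel = str["MAE"],
                            frac_within_resolution =
                              if (length(e[is.finite(e)]))
                                mean(abs(e[is.finite(e)]) <= res_of[[p]])
                              else NA_real_,
                            n = sum(is.finite(e)))
  }
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  structure(list(pairs = pairs, summary = summ, n_missing = n_missing),
            class = "stride_error_table")
}

#' Paired-parameter agreement statistics
#'
#' Absolute agreement via the single-measure two-way intraclass correlation
#' ICC(2,1) computed from the ANOVA mean squares, with the standard F-based
#' 95% confidence interval; relative agreement via Spearman's rho; plus the
#' Bland-Altman quantities: bias (mean difference), limits of agreement
#' (bias +- 1.96 SD) and RMSE. Differences are `detected - reference`.
#'
#' @param detected,reference paired numeric vectors (>= 3 pairs).
#' @param conf_level confidence level for the ICC interval.
#' @return list of class `agreement_report` with `icc`, `icc_ci`,
#'   `spearman`, `bias`, `loa` (lower, upper), `sd_diff`, `rmse`, `n`, and
#'   `ba` (data.frame of Bland-Altman plot coordinates `mean`, `diff`).
#' @export
agreement_stats <- function(detected, reference, conf_level = 0.95) {
  ok <- is.finite(detected) & is.finite(reference)
  x <- detected[ok]; y <- reference[ok]
  n <- length(x)
  if (n < 3L) stop("agreement statistics need at least 3 pairs")
  k <- 2
  grand <- mean(c(x, y))
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  SSR <- k * sum((row_means - grand)^2)
  SSC <- n * sum((col_means - grand)^2)
  SST <- sum((c(x, y) - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  icc <- if (abs(denom) < .Machine$double.eps) NA_real_
         else (MSR - MSE) / denom
  # F-based confidence interval (single-measure, absolute agreement)
  ci <- c(NA_real_, NA_real_)
  if (is.finite(icc) && MSE > 0) {
    alpha <- 1 - conf_level
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    F1 <- stats::qf(1 - alpha / 2, n - 1, v)
    F2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - F1 * MSE) /
      (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (F2 * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
    ci <- c(lower, upper)
  }
  d <- x - y
  bias <- mean(d)
  sd_d <- stats::sd(d)
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
         else stats::cor(x, y, method = "spearman")
  structure(list(icc = icc, icc_ci = ci, spearman = rho, bias = bias,
                 loa = c(lower = bias - 1.96 * sd_d,
                         upper = bias + 1.96 * sd_d),
                 sd_diff = sd_d,
                 rmse = sqrt(mean(d^2)), n = n,
                 ba = data.frame(mean = (x + y) / 2, diff = d)),
            class = "agreement_report")
}

#' Per-stratum event-detection performance
#'
#' Matches detected against reference events separately per side and event
#' type, pools sides, and reports classification scores and timing-error
#' statistics per (event type x condition) stratum plus an overall `all`
#' condition. Reference events are labeled with conditions beforehand (see
#' [label_events()]); reference events at which the relevant foot markers
#' are occluded can be excluded by passing the trial.
#'
#' @param detected,reference [gait_events()] tables.
#' @param tw tolerance window, seconds.
#' @param trial optional [marker_trial()]; when given, reference events
#'   whose side's heel or toe marker is invalid at the event frame are
#'   excluded before matching.
#' @param method label for the report.
#' @return data.frame with one row per stratum: counts, S/PPV/F1, ME, IQRE,
#'   MAE and the fraction of |errors| within one sampling period.
#' @export
evaluate_performance <- function(detected, reference, tw = 0.5,
                                 trial = NULL, method = NA_character_) {
  if (!is.null(trial)) {
    n <- length(trial$time)
    keep <- vapply(seq_len(nrow(reference)), function(i) {
      side <- reference$side[i]
      idx <- pmin(pmax(round(reference$time[i] * trial$sampling_rate) + 1L,
                       1L), n)
      trial$valid[[paste0(side, "HEEL")]][idx] &&
        trial$valid[[paste0(side, "TOE")]][idx]
    }, logical(1))
    reference <- reference[keep, , drop = FALSE]
  }
  conds <- unique(c("all", reference$condition))
  dt_min <- NULL
  rows <- list()
  for (ty in c("IC", "FC")) for (w in conds) {
    tp <- fn <- fp <- 0L
    errs <- numeric(0)
    for (side in c("L", "R")) {
      ref <- reference[reference$side == side & reference$type == ty &
                       (w == "all" | reference$condition == w), ,
                       drop = FALSE]
      det <- detected[detected$side == side & detected$type == ty &
                      (w == "all" | detected$condition == w), ,
                      drop = FALSE]
      m <- match_events(det$time, ref$time, tw)
      tp <- tp + m$tp; fn <- fn + m$fn; fp <- fp + m$fp
      errs <- c(errs, m$pairs$dt)
    }
    sc <- classification_scores(tp, fn, fp)
    st <- timing_error_stats(errs)
    frac <- NA_real_
    if (!is.null(trial)) dt_min <- 1 / trial$sampling_rate
    if (!is.null(dt_min) && length(errs)) {
      frac <- mean(abs(errs) <= dt_min + 1e-12)
    }
    rows[[paste(ty, w)]] <- data.frame(method = method, type = ty,
                                       condition = w, tp = tp, fn = fn,
                                       fp = fp, S = sc["S"],
                                       PPV = sc["PPV"], F1 = sc["F1"],
                                       ME = st["ME"], IQRE = st["IQRE"],
                                       MAE = st["MAE"],
                                       frac_within_dtmin = frac)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
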