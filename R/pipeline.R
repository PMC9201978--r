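# End-to-end validation runner: detect -> classify -> strides -> evaluate,
# over a collection of trials with reference events.

#' Run the full validation pipeline
#'
#' For every trial, runs the requested detectors, segments walking
#' conditions (curvilinear from the pelvis yaw, step negotiation from the
#' detected initial contacts), labels events and strides, and scores the
#' detections against the reference events: per-stratum classification and
#' timing statistics, stride-parameter error propagation, and pooled
#' paired-parameter agreement statistics.
#'
#' @param trials a list as produced by [make_validation_corpus()]: each
#'   element has `$trial` (a [marker_trial()]) and `$truth` with `$events`
#'   (condition-labeled reference events) and optionally `$strides`
#'   (reference stride parameters).
#' @param methods character vector of detector names (`"M1"`..`"M10"`).
#' @param tw tolerance window, seconds.
#' @param out_dir optional directory; when given, writes
#'   `performance.csv`, `stride_errors.csv`, `agreement.csv` and a combined
#'   `report.json`.
#' @return list with `performance`, `stride_summary`, `agreement`
#'   data.frames (and invisibly writes files when `out_dir` is set).
#' @export
run_validation <- function(trials, methods = paste0("M", 1:10), tw = 0.5,
                           out_dir = NULL) {
  perf <- list()
  stride_rows <- list()
  agree_pairs <- list()  # per parameter: accumulated (det, ref) pairs
  for (tn in names(trials)) {
    item <- trials[[tn]]
    trial <- item$trial
    ref_events <- item$truth$events
    ref_strides <- item$truth$strides
    prep <- prepare_trial(trial)
    cw <- if (!is.null(prep$frames)) detect_curvilinear(prep$frames)
          else NULL
    for (method in methods) {
      events <- tryCatch(detect_events(trial, method, prep = prep),
                         error = function(e) {
                           warning(tn, "/", method, ": ",
                                   conditionMessage(e))
                           gait_events()
                         })
      sn <- if (nrow(events)) detect_step_negotiation(trial, events)
            else NULL
      labeled <- label_events(events, cw, sn)
      p <- evaluate_performance(labeled, ref_events, tw = tw,
                                trial = trial, method = method)
      p$trial <- tn
      perf[[paste(tn, method)]] <- p
      if (!is.null(ref_strides) && nrow(labeled)) {
        det_str <- assemble_strides(labeled)
        if (nrow(det_str)) {
          det_str <- compute_stride_params(det_str, trial, method = method)
          bouts <- identify_bouts(det_str)
          det_str <- strides_in_bouts(det_str, bouts)
          det_str <- label_strides(det_str, labeled)
          err <- stride_param_errors(det_str, ref_strides, tw = tw,
                                     sampling_rate = trial$sampling_rate)
          s <- err$summary
          s$method <- method; s$trial <- tn
          s$n_missing <- err$n_missing
          stride_rows[[paste(tn, method)]] <- s
          if (!is.null(err$pairs)) {
            for (pname in c("duration", "length", "speed")) {
              ecol <- err$pairs[[paste0(pname, "_err")]]
              rv <- .ref_values_for_pairs(err$pairs, ref_strides, pname)
              ok <- is.finite(ecol) & is.finite(rv)
              key <- paste(method, pname)
              agree_pairs[[key]] <- rbind(agree_pairs[[key]],
                                          data.frame(det = rv[ok] + ecol[ok],
                                                     ref = rv[ok]))
            }
          }
        }
      }
    }
  }
  performance <- do.call(rbind, perf)
  rownames(performance) <- NULL
  stride_summary <- if (length(stride_rows)) {
    out <- do.call(rbind, stride_rows); rownames(out) <- NULL; out
  } else NULL
  agreement <- NULL
  if (length(agree_pairs)) {
    rows <- list()
    for (key in sort(names(agree_pairs))) {
      pp <- agree_pairs[[key]]
      if (nrow(pp) < 3L) next
      ag <- agreement_stats(pp$det, pp$ref)
      parts <- strsplit(key, " ")[[1]]
      rows[[key]] <- data.frame(method = parts[1], parameter = parts[2],
                                n = ag$n, icc = ag$icc,
                                icc_lo = ag$icc_ci[1],
                                icc_hi = ag$icc_ci[2],
                                spearman = ag$spearman, bias = ag$bias,
                                loa_lower = ag$loa["lower"],
                                loa_upper = ag$loa["upper"],
                                rmse = ag$rmse)
    }
    if (length(rows)) {
      agreement <- do.call(rbind, rows)
      rownames(agreement) <- NULL
    }
  }
  result <- list(performance = performance, stride_summary = stride_summary,
                 agreement = agreement)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(performance, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    if (!is.null(stride_summary)) {
      utils::write.csv(stride_summary,
                       file.path(out_dir, "stride_errors.csv"),
                       row.names = FALSE)
    }
    if (!is.null(agreement)) {
      utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(result, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  result
}

# reference values for the strides that produced the paired errors
.ref_values_for_pairs <- function(pairs, ref_strides, pname) {
  vapply(seq_len(nrow(pairs)), function(i) {
    j <- which(ref_strides$side == pairs$side[i] &
               abs(ref_strides$t_ic_start - pairs$t_ref[i]) < 1e-9)
    if (length(j) == 1L && pname %in% names(ref_strides)) {
      ref_strides[[pname]][j]
    } else NA_real_
  }, numeric(1))
}
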