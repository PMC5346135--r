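#' Segment a recording into overlapping epochs
#'
#' Fixed 60 s epochs overlapping by 15 s (stride 45 s), starting at 0;
#' a trailing window shorter than 60 s is dropped. The alternative
#' reading of the overlap (stride 15 s) is available via `stride_s`.
#'
#' @param duration_s Recording duration in seconds (`>= 60` for a
#'   non-empty result).
#' @param epoch_s Epoch length, seconds.
#' @param stride_s Start-to-start stride, seconds (default
#'   `epoch_s - 15`).
#' @return Data frame of half-open epochs: `start_s`, `end_s`.
#' @examples
#' segment_epochs(150)  # starts 0, 45, 90
#' @export
segment_epochs <- function(duration_s, epoch_s = 60, stride_s = epoch_s - 15) {
  stopifnot(is.numeric(duration_s), length(duration_s) == 1,
            epoch_s > 0, stride_s > 0)
  if (duration_s < epoch_s) {
    warning(sprintf("duration %g s is shorter than one %g s epoch; no epochs",
                    duration_s, epoch_s))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  starts <- seq(0, duration_s - epoch_s, by = stride_s)
  data.frame(start_s = starts, end_s = starts + epoch_s)
}

# Does any interval in `events` overlap the half-open epoch [s, e)?
overlaps_any <- function(start_s, end_s, ev_start, ev_end) {
  if (length(ev_start) == 0) return(rep(FALSE, length(start_s)))
  vapply(seq_along(start_s), function(i) {
    any(ev_start < end_s[i] & ev_end > start_s[i])
  }, logical(1))
}

#' Label epochs against clinical and IPI events
#'
#' An epoch is clinically positive iff it has non-empty time overlap with
#' any clinical event of the chosen class, and IPI-positive iff it
#' overlaps any IPI event. Epochs overlapping seconds with invalid data
#' can be excluded via `invalid_intervals`.
#'
#' @param epochs From [segment_epochs()].
#' @param clinical_events Data frame with `kind`, `start_s`, `end_s`
#'   (from [detect_events()] or ground truth).
#' @param ipi_events Data frame with `start_s`, `end_s` (from
#'   [detect_ipi_events()]).
#' @param event_class `"severe"` or `"clinically_significant"`.
#' @param invalid_intervals Optional data frame of `start_s`, `end_s`
#'   intervals of invalid data; overlapping epochs are marked excluded.
#' @return Data frame: `start_s`, `end_s`, `clinical_pos`, `ipi_pos`,
#'   `excluded`.
#' @export
label_epochs <- function(epochs, clinical_events, ipi_events,
                         event_class = c("severe", "clinically_significant"),
                         invalid_intervals = NULL) {
  event_class <- match.arg(event_class)
  kinds <- event_class_kinds(event_class)
  ce <- clinical_events[clinical_events$kind %in% kinds, , drop = FALSE]
  out <- epochs
  out$clinical_pos <- overlaps_any(epochs$start_s, epochs$end_s,
                                   ce$start_s, ce$end_s)
  out$ipi_pos <- overlaps_any(epochs$start_s, epochs$end_s,
                              ipi_events$start_s, ipi_events$end_s)
  out$excluded <- if (is.null(invalid_intervals)) {
    rep(FALSE, nrow(epochs))
  } else {
    overlaps_any(epochs$start_s, epochs$end_s,
                 invalid_intervals$start_s, invalid_intervals$end_s)
  }
  out
}

#' Tally a confusion matrix over labeled epochs
#'
#' @param labels From [label_epochs()]; excluded epochs are dropped.
#' @return Named integer vector `tp`, `fp`, `fn`, `tn` summing to the
#'   number of analyzed epochs.
#' @export
confusion_counts <- function(labels) {
  l <- labels[!labels$excluded, , drop = FALSE]
  c(tp = sum(l$ipi_pos & l$clinical_pos),
    fp = sum(l$ipi_pos & !l$clinical_pos),
    fn = sum(!l$ipi_pos & l$clinical_pos),
    tn = sum(!l$ipi_pos & !l$clinical_pos))
}

stop_undefined_metric <- function(msg) {
  stop(structure(class = c("ipindex_undefined_metric", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP). A zero
#' denominator raises a classed error (`ipindex_undefined_metric`)
#' rather than silently returning 0.
#'
#' @param counts Named vector with `tp`, `fp`, `fn`, `tn`.
#' @return Named numeric vector `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)),
            all(counts >= 0))
  if (counts[["tp"]] + counts[["fn"]] == 0) {
    stop_undefined_metric("sensitivity undefined: no clinically positive epochs")
  }
  if (counts[["tn"]] + counts[["fp"]] == 0) {
    stop_undefined_metric("specificity undefined: no clinically negative epochs")
  }
  c(sensitivity = counts[["tp"]] / (counts[["tp"]] + counts[["fn"]]),
    specificity = counts[["tn"]] / (counts[["tn"]] + counts[["fp"]]))
}

# Trapezoidal AUC over (1 - specificity, sensitivity) points with the
# (0,0) and (1,1) anchors.
auc_from_points <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord], 1)
  y <- c(0, tpr[ord], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Pool per-epoch labels for one or more streams: compute traces, detect
# clinical and IPI events, segment and label. Returns one data frame of
# epochs with clinical_pos and ipi_pos_1..ipi_pos_9 columns.
pool_epoch_labels <- function(streams,
                              event_class = c("severe", "clinically_significant"),
                              thresholds = 1:9,
                              calibration = NULL, stride_s = 45) {
  event_class <- match.arg(event_class)
  if (inherits(streams, "vital_stream")) streams <- list(streams)
  pooled <- lapply(streams, function(st) {
    cal <- if (is.null(calibration)) {
      read_calibration(mode = attr(st, "mode"))
    } else calibration
    trace <- compute_ipi_stream(st, calibration = cal)
    clin <- detect_events(st)
    epochs <- segment_epochs(nrow(st), stride_s = stride_s)
    if (nrow(epochs) == 0) return(NULL)
    inv <- invalid_intervals(trace)
    lab <- label_epochs(epochs, clin, empty_events()[0, c("start_s", "end_s")],
                        event_class, invalid_intervals = inv)
    for (k in thresholds) {
      ev <- detect_ipi_events(trace, k)
      lab[[paste0("ipi_pos_", k)]] <-
        overlaps_any(epochs$start_s, epochs$end_s, ev$start_s, ev$end_s)
    }
    lab$ipi_pos <- NULL
    lab
  })
  do.call(rbind, pooled)
}

# Maximal runs of invalid seconds in a trace, as half-open intervals.
invalid_intervals <- function(trace) {
  runs <- maximal_runs(!trace$valid, 1L)
  if (nrow(runs) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  data.frame(start_s = trace$t[runs$start], end_s = trace$t[runs$end] + 1)
}

#' Epoch-based ROC analysis of the IPI against clinical events
#'
#' For every IPI threshold 1-9: detect IPI events (IPI at or below the
#' threshold for at least 15 s), label 60 s epochs (overlap 15 s, pooled
#' across streams) as positive/negative against the chosen clinical event
#' class, tally the confusion matrix and compute sensitivity and
#' specificity; then the trapezoidal AUC over the resulting ROC points
#' anchored at (0,0) and (1,1).
#'
#' @param streams A `vital_stream` or list of them.
#' @param event_class `"severe"` or `"clinically_significant"`.
#' @param thresholds IPI thresholds to evaluate (subset of 1..9).
#' @param calibration Optional shared calibration (default: shipped
#'   calibration for each stream's mode).
#' @param stride_s Epoch stride (45 s = overlap 15 s).
#' @return List with `points` (data frame: `threshold`, `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity`), `auc`, and `n_epochs`.
#' @export
roc_analysis <- function(streams,
                         event_class = c("severe", "clinically_significant"),
                         thresholds = 1:9, calibration = NULL,
                         stride_s = 45) {
  event_class <- match.arg(event_class)
  stopifnot(all(thresholds %in% 1:9))
  lab <- pool_epoch_labels(streams, event_class, thresholds, calibration,
                           stride_s)
  if (is.null(lab) || nrow(lab) == 0) {
    stop("no epochs to analyze (streams shorter than one epoch?)",
         call. = FALSE)
  }
  lab <- lab[!lab$excluded, , drop = FALSE]
  if (all(lab$clinical_pos) || !any(lab$clinical_pos)) {
    stop_undefined_metric(
      "ROC undefined: pooled epochs contain a single clinical class")
  }
  pts <- do.call(rbind, lapply(thresholds, function(k) {
    l <- lab
    l$ipi_pos <- lab[[paste0("ipi_pos_", k)]]
    cc <- confusion_counts(l)
    ss <- sensitivity_specificity(cc)
    data.frame(threshold = k, t(cc), sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]])
  }))
  list(points = pts,
       auc = auc_from_points(1 - pts$specificity, pts$sensitivity),
       n_epochs = nrow(lab))
}

#' Permutation-null AUC
#'
#' Shuffles the pooled epochs' clinical labels relative to their IPI
#' labels and recomputes the AUC; under the null of no association the
#' mean AUC is 0.5. Used as the negative control of the reliability
#' analysis.
#'
#' @param streams A `vital_stream` or list of them.
#' @param event_class `"severe"` or `"clinically_significant"`.
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutations.
#' @param calibration Optional shared calibration.
#' @return List with `auc` (vector of permuted AUCs) and `mean_auc`.
#' @export
permutation_null_auc <- function(streams,
                                 event_class = c("severe", "clinically_significant"),
                                 n_perm = 100, seed = 1, calibration = NULL) {
  event_class <- match.arg(event_class)
  lab <- pool_epoch_labels(streams, event_class, 1:9, calibration)
  lab <- lab[!lab$excluded, , drop = FALSE]
  if (all(lab$clinical_pos) || !any(lab$clinical_pos)) {
    stop_undefined_metric(
      "permutation null undefined: single clinical class in pooled epochs")
  }
  ipi_cols <- paste0("ipi_pos_", 1:9)
  aucs <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cp <- sample(lab$clinical_pos)
      sens <- spec <- numeric(9)
      for (k in 1:9) {
        ip <- lab[[ipi_cols[k]]]
        sens[k] <- sum(ip & cp) / sum(cp)
        spec[k] <- sum(!ip & !cp) / sum(!cp)
      }
      auc_from_points(1 - spec, sens)
    }, numeric(1))
  })
  list(auc = aucs, mean_auc = mean(aucs))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
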