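#' @name vitals_csv
#' @title Vitals CSV dialect
#' @description
#' Plain CSV with header `time_s, etco2_mmhg, rr_bpm, spo2_pct, pr_bpm`.
#' On read, rows are validated (non-numeric cells become invalid
#' samples), out-of-range values are clamped to the physical range and
#' flagged, and the recording is resampled to a uniform 1 Hz grid by
#' nearest neighbour with a 1 s tolerance; grid seconds with no sample
#' within tolerance become invalid samples (gaps).
NULL

vitals_csv_columns <- function() {
  c(time_s = "t", etco2_mmhg = "etco2", rr_bpm = "rr",
    spo2_pct = "spo2", pr_bpm = "pr")
}

#' Resample irregular samples onto the 1 Hz grid
#'
#' Nearest-neighbour assignment: grid second `g` takes the sample whose
#' time is closest to `g`, if within `tol_s`; otherwise the second is a
#' gap (all channels `NA`).
#'
#' @param t Sample times, seconds (sorted, finite).
#' @param values Data frame of channel columns aligned with `t`.
#' @param tol_s Matching tolerance, seconds.
#' @return Data frame with grid `t` (0..floor(max t)) and channels,
#'   `NA` where no sample matched.
#' @export
resample_1hz <- function(t, values, tol_s = 1) {
  stopifnot(is.numeric(t), nrow(values) == length(t))
  keep <- is.finite(t)
  t <- t[keep]; values <- values[keep, , drop = FALSE]
  if (length(t) == 0) return(cbind(data.frame(t = numeric(0)), values[0, ]))
  ord <- order(t)
  t <- t[ord]; values <- values[ord, , drop = FALSE]
  grid <- 0:floor(max(t))
  # nearest sample per grid point
  pos <- findInterval(grid, t)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(t))
  d_lo <- abs(grid - t[lo])
  d_hi <- abs(grid - t[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  nearest[pos == 0 & d_hi > d_lo] <- 1L  # before first sample
  out <- values[nearest, , drop = FALSE]
  out[dist > tol_s, ] <- NA
  rownames(out) <- NULL
  cbind(data.frame(t = grid), out)
}

#' Read a vitals CSV into a 1 Hz stream
#'
#' @param path CSV file with the columns of [vitals_csv].
#' @param mode Age mode of the recording.
#' @param tol_s Resampling tolerance, seconds.
#' @return A [vital_stream()].
#' @export
read_vitals_csv <- function(path, mode = "adult", tol_s = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  cols <- vitals_csv_columns()
  missing <- setdiff(names(cols), names(raw))
  if (length(missing)) {
    stop(sprintf("vitals CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num <- lapply(raw[names(cols)], function(x) suppressWarnings(as.numeric(x)))
  bad <- !is.finite(num$time_s)
  if (any(bad)) {
    message(sprintf("read_vitals_csv: %d row(s) with unparseable time marked invalid",
                    sum(bad)))
  }
  values <- data.frame(etco2 = num$etco2_mmhg, rr = num$rr_bpm,
                       spo2 = num$spo2_pct, pr = num$pr_bpm)
  g <- resample_1hz(num$time_s, values, tol_s = tol_s)
  vital_stream(g$t, g$etco2, g$rr, g$spo2, g$pr, mode = mode)
}

#' Write a stream to the vitals CSV dialect
#'
#' @param stream A [vital_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vitals_csv <- function(stream, path) {
  stopifnot(inherits(stream, "vital_stream"))
  out <- data.frame(time_s = stream$t, etco2_mmhg = stream$etco2,
                    rr_bpm = stream$rr, spo2_pct = stream$spo2,
                    pr_bpm = stream$pr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an IPI trace to CSV
#'
#' Columns: `time_s`, `ipi`, `ipi_raw`, `flags` (`"ok"`, `"gap"`, or
#' `"pr_adj"`).
#'
#' @param trace An `ipi_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  flags <- ifelse(!trace$valid, "gap",
                  ifelse(!is.na(trace$pr_adjustment_applied) &
                           trace$pr_adjustment_applied, "pr_adj", "ok"))
  out <- data.frame(time_s = trace$t, ipi = trace$ipi,
                    ipi_raw = round(trace$ipi_raw, 6), flags = flags)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write events to CSV
#'
#' @param events Data frame from [detect_events()] or ground truth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- events
  if (!"duration_s" %in% names(out)) {
    out$duration_s <- out$end_s - out$start_s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
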