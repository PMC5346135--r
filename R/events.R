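#' @name events
#' @title Respiratory event definitions
#'
#' @description
#' Events are maximal runs of grid seconds satisfying a channel condition
#' for at least a minimum duration, reported as half-open intervals
#' `[start_s, end_s)` in seconds. Two severity classes are defined.
#'
#' Severe events:
#' * `severe_apnea` — PetCO2 = 0 mmHg and RR = 0 bpm for at least 30 s;
#' * `severe_hypoxia` — SpO2 <= 85 % for at least 15 s.
#'
#' Clinically significant events (at least 15 s each):
#' * `cs_apnea` — PetCO2 = 0 mmHg and RR = 0 bpm;
#' * `cs_bradypneic_hypovent_hypoxia` — PetCO2 > 50, RR < 8, SpO2 < 90 %;
#' * `cs_nonbradypneic_hypovent_hypoxia` — PetCO2 < 30, RR 8-12, SpO2 < 90 %;
#' * `cs_hypoxia` — SpO2 < 90 %, any PetCO2 and RR.
#'
#' Zero-flow readings are tested as `< 1` (mmHg, bpm) to guard against
#' sensor quantization and CSV float round-trip; all other comparisons
#' are exactly as stated above. Runs are maximal with no gap bridging: a
#' single interrupted or invalid second splits an event. One episode can
#' legitimately yield events of several kinds (a 40 s apnea is both
#' `severe_apnea` and `cs_apnea`).
NULL

event_kinds <- function() {
  c("severe_apnea", "severe_hypoxia", "cs_apnea",
    "cs_bradypneic_hypovent_hypoxia", "cs_nonbradypneic_hypovent_hypoxia",
    "cs_hypoxia")
}

#' Event kinds per severity class
#'
#' @param event_class `"severe"` or `"clinically_significant"`.
#' @return Character vector of event kinds in the class.
#' @export
event_class_kinds <- function(event_class = c("severe", "clinically_significant")) {
  event_class <- match.arg(event_class)
  if (event_class == "severe") {
    c("severe_apnea", "severe_hypoxia")
  } else {
    c("cs_apnea", "cs_bradypneic_hypovent_hypoxia",
      "cs_nonbradypneic_hypovent_hypoxia", "cs_hypoxia")
  }
}

# Per-second condition vector for one kind; invalid channels make the
# condition FALSE, which breaks runs.
event_condition <- function(stream, kind) {
  e <- stream$etco2; r <- stream$rr; s <- stream$spo2
  ve <- stream$valid_etco2; vr <- stream$valid_rr; vs <- stream$valid_spo2
  safe <- function(x) !is.na(x) & x
  switch(kind,
    severe_apnea = ,
    cs_apnea = safe(ve & vr & e < 1 & r < 1),
    severe_hypoxia = safe(vs & s <= 85),
    cs_bradypneic_hypovent_hypoxia =
      safe(ve & vr & vs & e > 50 & r < 8 & s < 90),
    cs_nonbradypneic_hypovent_hypoxia =
      safe(ve & vr & vs & e < 30 & r >= 8 & r <= 12 & s < 90),
    cs_hypoxia = safe(vs & s < 90),
    stop(sprintf("unknown event kind '%s'", kind), call. = FALSE))
}

min_duration <- function(kind) if (kind == "severe_apnea") 30L else 15L

# Maximal TRUE runs of length >= min_len; returns start/end indices.
maximal_runs <- function(cond, min_len) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

empty_events <- function() {
  data.frame(kind = character(0), start_s = numeric(0), end_s = numeric(0),
             duration_s = numeric(0))
}

#' Detect severe and clinically significant respiratory events
#'
#' Scans a 1 Hz stream for maximal runs of each event condition meeting
#' its minimum duration (see [events]).
#'
#' @param stream A [vital_stream()].
#' @param kinds Event kinds to scan for (default: all six).
#' @return Data frame of events: `kind`, `start_s`, `end_s` (half-open,
#'   seconds), `duration_s`; ordered by kind then start.
#' @export
detect_events <- function(stream, kinds = event_kinds()) {
  stopifnot(inherits(stream, "vital_stream"), all(kinds %in% event_kinds()))
  if (nrow(stream) == 0) return(empty_events())
  out <- lapply(kinds, function(k) {
    runs <- maximal_runs(event_condition(stream, k), min_duration(k))
    if (nrow(runs) == 0) return(empty_events())
    data.frame(kind = k, start_s = stream$t[runs$start],
               end_s = stream$t[runs$end] + 1,
               duration_s = runs$end - runs$start + 1)
  })
  do.call(rbind, out)
}

#' Detect IPI-threshold events
#'
#' An IPI event at threshold `k` is a maximal run of at least 15 s during
#' which the reported integer IPI is `<= k`. Gaps (invalid seconds) break
#' runs.
#'
#' @param trace An `ipi_trace` from [compute_ipi_stream()].
#' @param threshold Integer IPI threshold in 1..9.
#' @param min_duration_s Minimum run length, seconds (default 15).
#' @return Data frame: `threshold`, `start_s`, `end_s`, `duration_s`.
#' @export
detect_ipi_events <- function(trace, threshold, min_duration_s = 15) {
  stopifnot(is.data.frame(trace), all(c("t", "ipi") %in% names(trace)))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold != round(threshold) || threshold < 1 || threshold > 9) {
    stop("threshold must be a single integer in 1..9", call. = FALSE)
  }
  cond <- !is.na(trace$ipi) & trace$ipi <= threshold
  runs <- maximal_runs(cond, as.integer(min_duration_s))
  if (nrow(runs) == 0) {
    return(data.frame(threshold = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0)))
  }
  data.frame(threshold = as.integer(threshold),
             start_s = trace$t[runs$start], end_s = trace$t[runs$end] + 1,
             duration_s = runs$end - runs$start + 1)
}
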