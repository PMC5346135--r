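#' Construct a vital-sign stream
#'
#' A `vital_stream` is a data frame on a uniform 1 Hz grid with columns
#' `t` (seconds from stream start), the four channels `etco2` (mmHg),
#' `rr` (breaths/min), `spo2` (%), `pr` (beats/min), and per-channel
#' validity flags `valid_etco2`, `valid_rr`, `valid_spo2`, `valid_pr`.
#' Channel values are clamped to their physical ranges; samples that
#' needed clamping or were non-finite are flagged invalid-free or
#' invalid respectively.
#'
#' @param t Integer-valued seconds, strictly increasing, spacing 1 s.
#' @param etco2,rr,spo2,pr Numeric channel vectors, same length as `t`.
#' @param mode Age mode, one of [age_modes()].
#' @param clamp Clamp out-of-range values to the physical range (and keep
#'   them valid, flagging `clamped`)? If `FALSE` they are marked invalid.
#' @return A `vital_stream` data frame with attribute `mode`.
#' @export
vital_stream <- function(t, etco2, rr, spo2, pr, mode = "adult", clamp = TRUE) {
  mode <- match.arg(mode, age_modes())
  n <- length(t)
  stopifnot(length(etco2) == n, length(rr) == n, length(spo2) == n,
            length(pr) == n)
  if (n > 1 && any(diff(t) != 1)) {
    stop("vital_stream requires a uniform 1 Hz grid (use resample_1hz())",
         call. = FALSE)
  }
  rg <- channel_ranges()
  df <- data.frame(t = as.numeric(t), etco2 = as.numeric(etco2),
                   rr = as.numeric(rr), spo2 = as.numeric(spo2),
                   pr = as.numeric(pr))
  df$clamped <- logical(n)
  for (ch in c("etco2", "rr", "spo2", "pr")) {
    x <- df[[ch]]
    ok <- is.finite(x)
    out <- ok & (x < rg[[ch]][1] | x > rg[[ch]][2])
    if (clamp) {
      df[[ch]] <- pmin(pmax(x, rg[[ch]][1]), rg[[ch]][2])
      df$clamped <- df$clamped | out
      df[[paste0("valid_", ch)]] <- ok
    } else {
      df[[paste0("valid_", ch)]] <- ok & !out
    }
    df[[ch]][!ok] <- NA_real_
  }
  structure(df, mode = mode, class = c("vital_stream", "data.frame"))
}

#' @export
print.vital_stream <- function(x, ...) {
  cat(sprintf("<vital_stream mode='%s', %d s at 1 Hz, %d invalid sample(s)>\n",
              attr(x, "mode"), nrow(x),
              sum(!(x$valid_etco2 & x$valid_rr & x$valid_spo2 & x$valid_pr))))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5))
  invisible(x)
}

#' Graded secondary pulse-rate adjustment
#'
#' Two secondary rules subtract one point from the defuzzified score when
#' the pulse contradicts the ventilatory picture: low PR with high/very
#' high PetCO2 and RR, or high PR with low/very low PetCO2 and RR. The
#' subtraction is graded: each condition's degree is the minimum over its
#' three clauses, each clause being the maximum grade over its admissible
#' labels; the rules combine with `max`. At fully crisp grades this
#' reduces exactly to "subtract one". The result is floored at 1.
#'
#' @param ipi_raw Defuzzified centroid value(s) in `[1, 10]`.
#' @param grades Named list with elements `pr`, `etco2`, `rr`, each a
#'   named grade vector (single sample) or grade matrix (one row per
#'   sample).
#' @param pr_rules Secondary rules, as in [default_rulebase()].
#' @return List with `value` (adjusted score, floored at 1) and
#'   `subtraction` (the graded amount subtracted).
#' @export
apply_pr_adjustment <- function(ipi_raw, grades,
                                pr_rules = default_pr_rules()) {
  as_mat <- function(g) if (is.matrix(g)) g else matrix(g, nrow = 1,
                                                        dimnames = list(NULL, names(g)))
  gpr <- as_mat(grades$pr); gco2 <- as_mat(grades$etco2); grr <- as_mat(grades$rr)
  n <- nrow(gpr)
  sub <- numeric(n)
  row_max <- function(m, labs) {
    if (length(labs) == 1L) m[, labs] else do.call(pmax, as.data.frame(m[, labs, drop = FALSE]))
  }
  for (rule in pr_rules) {
    deg <- pmin(gpr[, rule$pr],
                row_max(gco2, rule$etco2),
                row_max(grr, rule$rr)) * rule$subtract
    sub <- pmax(sub, deg)
  }
  list(value = pmax(ipi_raw - sub, 1), subtraction = sub)
}

# Vectorised fuzzification + rule evaluation + centroid over aligned
# channel vectors; the single shared path behind compute_ipi() and
# compute_ipi_stream(). Returns raw centroid, subtraction and grades.
ipi_pipeline <- function(etco2, rr, spo2, pr, calibration) {
  p <- calibration$partitions
  g <- list(etco2 = grade_matrix(etco2, p$etco2),
            rr = grade_matrix(rr, p$rr),
            spo2 = grade_matrix(spo2, p$spo2),
            pr = grade_matrix(pr, p$pr))
  rules <- calibration$rulebase$rules
  n <- length(etco2)
  act <- matrix(0, n, 10)
  for (i in seq_len(nrow(rules))) {
    a <- pmin(g$rr[, rules$rr[i]], g$etco2[, rules$etco2[i]])
    if (!is.na(rules$spo2[i])) a <- pmin(a, g$spo2[, rules$spo2[i]])
    k <- rules$consequent[i]
    act[, k] <- pmax(act[, k], a)
  }
  raw <- defuzzify_centroid_matrix(act)
  adj <- apply_pr_adjustment(raw, g, calibration$rulebase$pr_rules)
  list(raw = raw, adjusted = adj$value, subtraction = adj$subtraction,
       grades = g)
}

#' Compute the IPI for vital-sign samples
#'
#' Runs the full pipeline — fuzzification, Mamdani rule evaluation,
#' centroid defuzzification, graded pulse-rate adjustment, and
#' round-half-up to the reported integer — on one or more synchronized
#' four-channel observations. Vectorised over samples; deterministic.
#'
#' @param etco2 End-tidal CO2, mmHg.
#' @param rr Respiration rate, breaths/min.
#' @param spo2 Oxygen saturation, percent.
#' @param pr Pulse rate, beats/min.
#' @param mode Age mode, one of [age_modes()].
#' @param calibration An `ipi_calibration`; defaults to the shipped
#'   calibration for `mode`.
#' @return Data frame with columns `ipi` (reported integer, 1..10),
#'   `ipi_raw` (defuzzified centroid before the PR adjustment),
#'   `pr_subtraction`, `pr_adjustment_applied` and `valid`. Samples with
#'   any non-finite channel get `NA` scores and `valid = FALSE` rather
#'   than an error, so streaming computation survives sensor dropouts.
#' @examples
#' cal <- read_calibration(mode = "adult")
#' compute_ipi(etco2 = 26, rr = 12, spo2 = 98, pr = 70, calibration = cal)$ipi  # 8
#' compute_ipi(etco2 = 26, rr = 12, spo2 = 90, pr = 70, calibration = cal)$ipi  # 5
#' @export
compute_ipi <- function(etco2, rr, spo2, pr, mode = "adult",
                        calibration = read_calibration(mode = mode)) {
  n <- length(etco2)
  stopifnot(length(rr) == n, length(spo2) == n, length(pr) == n,
            inherits(calibration, "ipi_calibration"))
  valid <- is.finite(etco2) & is.finite(rr) & is.finite(spo2) & is.finite(pr)
  out <- data.frame(ipi = NA_integer_, ipi_raw = NA_real_,
                    pr_subtraction = NA_real_,
                    pr_adjustment_applied = NA, valid = valid)[rep(1, max(n, 1)), ]
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out$valid <- valid
  if (any(valid)) {
    res <- ipi_pipeline(etco2[valid], rr[valid], spo2[valid], pr[valid],
                        calibration)
    out$ipi_raw[valid] <- res$raw
    out$pr_subtraction[valid] <- res$subtraction
    out$pr_adjustment_applied[valid] <- res$subtraction > 0
    out$ipi[valid] <- as.integer(pmin(pmax(round_half_up(res$adjusted), 1), 10))
  }
  out
}

#' Compute the IPI trace of a stream
#'
#' One result per 1 Hz grid second. Seconds with any invalid channel
#' yield gaps (`NA` scores), not errors; no smoothing or state is carried
#' across time, so the trace equals an independent per-sample computation.
#'
#' @param stream A [vital_stream()].
#' @param calibration Calibration; defaults to the shipped calibration
#'   for the stream's mode.
#' @return An `ipi_trace`: data frame with `t`, `ipi`, `ipi_raw`,
#'   `pr_subtraction`, `pr_adjustment_applied`, `valid`.
#' @export
compute_ipi_stream <- function(stream,
                               calibration = read_calibration(mode = attr(stream, "mode"))) {
  stopifnot(inherits(stream, "vital_stream"))
  n <- nrow(stream)
  if (n == 0) {
    out <- data.frame(t = numeric(0), ipi = integer(0), ipi_raw = numeric(0),
                      pr_subtraction = numeric(0),
                      pr_adjustment_applied = logical(0), valid = logical(0))
    return(structure(out, class = c("ipi_trace", "data.frame")))
  }
  ch_ok <- stream$valid_etco2 & stream$valid_rr & stream$valid_spo2 &
    stream$valid_pr
  e <- ifelse(ch_ok, stream$etco2, NA_real_)
  out <- compute_ipi(e, stream$rr, stream$spo2, stream$pr,
                     calibration = calibration)
  out <- cbind(t = stream$t, out)
  out$valid <- out$valid & ch_ok
  out$ipi[!ch_ok] <- NA_integer_
  structure(out, class = c("ipi_trace", "data.frame"))
}

#' @export
print.ipi_trace <- function(x, ...) {
  cat(sprintf("<ipi_trace %d s, %d gap(s)>\n", nrow(x), sum(!x$valid)))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5))
  invisible(x)
}
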