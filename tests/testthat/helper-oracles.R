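# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: the centroid oracle integrates numerically
# on a dense grid, and the event oracle tests every (start, duration)
# window via cumulative sums.

# Membership of the output universe's unit-base triangle at level k,
# written directly from the geometric definition.
oracle_triangle <- function(x, k) pmax(0, 1 - 2 * abs(x - k))

# Dense trapezoidal integration of the Mamdani aggregate (pointwise max
# of activation-clipped triangles) over the output axis [0.5, 10.5].
oracle_centroid <- function(activations, step = 2e-5) {
  x <- seq(0.5, 10.5, by = step)
  f <- rep(0, length(x))
  lv <- as.integer(names(activations))
  for (i in seq_along(activations)) {
    f <- pmax(f, pmin(oracle_triangle(x, lv[i]), activations[[i]]))
  }
  trap <- function(y) sum((utils::head(y, -1) + utils::tail(y, -1)) / 2) * step
  trap(x * f) / trap(f)
}

# Hand trapezoid formula, independent of membership_grade().
oracle_trap <- function(x, a, b, c, d) {
  if (x <= a || x >= d) return(if (x >= b && x <= c) 1 else 0)
  if (x < b) return((x - a) / (b - a))
  if (x <= c) return(1)
  (d - x) / (d - c)
}

# Brute-force event scanner: enumerates every window [s, s+len) with
# len >= min_len, accepts windows where the condition holds at every
# second, and keeps those not extendable in either direction.
oracle_scan_events <- function(cond, min_len) {
  n <- length(cond)
  cs <- c(0, cumsum(cond))
  pad <- c(cond, FALSE)
  out <- list()
  for (s in seq_len(n)) {
    if (s + min_len - 1 > n) break
    e <- (s + min_len - 1):n
    sat <- (cs[e + 1] - cs[s]) == (e - s + 1)   # condition at every second
    left_ext <- s > 1 && cond[s - 1]
    keep <- sat & !left_ext & !pad[e + 1]       # not extendable either way
    for (ee in e[keep]) {
      out[[length(out) + 1]] <- c(start = s, end = ee)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- unique(as.data.frame(do.call(rbind, out)))
  df[order(df$start), , drop = FALSE]
}

# Recode the six event conditions independently of the package (same
# printed thresholds, zero-flow guard < 1).
oracle_condition <- function(stream, kind) {
  e <- stream$etco2; r <- stream$rr; s <- stream$spo2
  ve <- stream$valid_etco2; vr <- stream$valid_rr; vs <- stream$valid_spo2
  res <- switch(kind,
    severe_apnea = ve & vr & e < 1 & r < 1,
    cs_apnea = ve & vr & e < 1 & r < 1,
    severe_hypoxia = vs & s <= 85,
    cs_bradypneic_hypovent_hypoxia =
      ve & vr & vs & e > 50 & r < 8 & s < 90,
    cs_nonbradypneic_hypovent_hypoxia =
      ve & vr & vs & e < 30 & r >= 8 & r <= 12 & s < 90,
    cs_hypoxia = vs & s < 90)
  !is.na(res) & res
}

oracle_min_len <- function(kind) if (kind == "severe_apnea") 30L else 15L

# Random scripted scenario for detector stress tests: a few episodes of
# random kind/duration (some below the duration thresholds).
random_scenario <- function(seed, duration_s = 600) {
  kinds <- c("apnea", "severe_hypoxia", "bradypneic_hypovent_hypoxia",
             "nonbradypneic_hypovent_hypoxia", "hypoxia")
  ep <- withr::with_seed(seed, {
    n_ep <- sample(0:3, 1)
    if (n_ep == 0) NULL else {
      slots <- seq(60, max(70, duration_s - 120), by = 10)
      onsets <- sort(sample(slots, min(n_ep, length(slots))))
      n_ep <- length(onsets)
      data.frame(kind = sample(kinds, n_ep, replace = TRUE),
                 onset_s = onsets,
                 duration_s = sample(c(10, 14, 16, 20, 25, 31, 40, 50), n_ep,
                                     replace = TRUE),
                 ramp_s = sample(0:5, n_ep, replace = TRUE))
    }
  })
  # enforce stream bounds and non-overlap including ramps; drop offenders
  if (!is.null(ep)) {
    keep <- rep(TRUE, nrow(ep))
    last_end <- -Inf
    for (i in seq_len(nrow(ep))) {
      lo <- ep$onset_s[i] - ep$ramp_s[i]
      hi <- ep$onset_s[i] + ep$duration_s[i] + ep$ramp_s[i]
      if (lo <= last_end || lo < 0 || hi > duration_s) {
        keep[i] <- FALSE
      } else {
        last_end <- hi
      }
    }
    ep <- ep[keep, , drop = FALSE]
    if (nrow(ep) == 0) ep <- NULL
  }
  scenario_spec(duration_s, episodes = ep, seed = seed)
}

adult_cal <- function() read_calibration(mode = "adult")
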