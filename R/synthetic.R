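#' @name synthetic
#' @title Synthetic vital-sign streams
#'
#' @description
#' Seeded generator of 1 Hz four-channel streams: Gaussian noise around
#' per-channel baselines, with scripted respiratory-compromise episodes
#' that override channels to satisfy their event condition with margin.
#' Linear ramps flank each episode but interpolate only between the
#' baseline and a condition-safe boundary value, then jump into the
#' episode band at onset — so each episode's ground-truth interval is
#' exactly the maximal run the detectors should report. Ramp seconds are
#' excluded from ground truth.
NULL

episode_kinds <- function() {
  c("apnea", "severe_hypoxia", "bradypneic_hypovent_hypoxia",
    "nonbradypneic_hypovent_hypoxia", "hypoxia")
}

# Channel targets per episode kind: `band` = [lo, hi] the channel is
# confined to during the episode (condition satisfied with margin);
# `safe` = the ramp endpoint just outside the condition.
episode_targets <- function(kind) {
  switch(kind,
    apnea = list(
      etco2 = list(band = c(0, 0), safe = 8),
      rr = list(band = c(0, 0), safe = 3)),
    severe_hypoxia = list(
      spo2 = list(band = c(80.5, 84.5), safe = 91)),
    bradypneic_hypovent_hypoxia = list(
      etco2 = list(band = c(53, 58), safe = 48),
      rr = list(band = c(4, 6), safe = 9),
      spo2 = list(band = c(86.5, 88.5), safe = 91)),
    nonbradypneic_hypovent_hypoxia = list(
      etco2 = list(band = c(21, 28), safe = 32),
      rr = list(band = c(9, 11), safe = 13),
      spo2 = list(band = c(86.5, 88.5), safe = 91)),
    hypoxia = list(
      spo2 = list(band = c(86.5, 88.5), safe = 91)),
    stop(sprintf("unknown episode kind '%s'", kind), call. = FALSE))
}

# Ground-truth event kinds implied by an episode of a given duration.
episode_truth_kinds <- function(kind, duration_s) {
  switch(kind,
    apnea = c(if (duration_s >= 30) "severe_apnea",
              if (duration_s >= 15) "cs_apnea"),
    severe_hypoxia = c(if (duration_s >= 15) c("severe_hypoxia", "cs_hypoxia")),
    bradypneic_hypovent_hypoxia =
      c(if (duration_s >= 15) c("cs_bradypneic_hypovent_hypoxia", "cs_hypoxia")),
    nonbradypneic_hypovent_hypoxia =
      c(if (duration_s >= 15) c("cs_nonbradypneic_hypovent_hypoxia", "cs_hypoxia")),
    hypoxia = c(if (duration_s >= 15) "cs_hypoxia"))
}

#' Default channel baselines for an age mode
#'
#' Means sit inside the Normal plateau of the mode's partitions; the
#' noise SDs (etco2 1.5 mmHg, rr 0.8 /min, spo2 0.6 %, pr 2 /min) are
#' small enough that baseline seconds never cross an event threshold.
#'
#' @param mode One of [age_modes()].
#' @return List with `mean` and `sd`, each a named numeric vector.
#' @export
default_baselines <- function(mode = "adult") {
  mode <- match.arg(mode, age_modes())
  mean <- switch(mode,
    adult    = c(etco2 = 38, rr = 14, spo2 = 97.5, pr = 72),
    ped_1_3  = c(etco2 = 38, rr = 24, spo2 = 97.5, pr = 110),
    ped_3_6  = c(etco2 = 38, rr = 21, spo2 = 97.5, pr = 100),
    ped_6_12 = c(etco2 = 38, rr = 18, spo2 = 97.5, pr = 90))
  list(mean = mean, sd = c(etco2 = 1.5, rr = 0.8, spo2 = 0.6, pr = 2.0))
}

#' Specify a synthetic scenario
#'
#' @param duration_s Stream duration, seconds.
#' @param mode Age mode.
#' @param episodes Data frame with columns `kind` (see
#'   `c("apnea", "severe_hypoxia", "bradypneic_hypovent_hypoxia",
#'   "nonbradypneic_hypovent_hypoxia", "hypoxia")`), `onset_s`,
#'   `duration_s`, `ramp_s`; or `NULL` for an event-free stream.
#' @param baselines As [default_baselines()].
#' @param seed Integer seed; identical seeds give bit-identical streams.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(duration_s, mode = "adult", episodes = NULL,
                          baselines = default_baselines(mode), seed = 1) {
  mode <- match.arg(mode, age_modes())
  if (is.null(episodes)) {
    episodes <- data.frame(kind = character(0), onset_s = numeric(0),
                           duration_s = numeric(0), ramp_s = numeric(0))
  }
  stopifnot(all(c("kind", "onset_s", "duration_s", "ramp_s") %in%
                  names(episodes)),
            all(episodes$kind %in% episode_kinds()),
            all(episodes$onset_s >= 0), all(episodes$duration_s > 0))
  if (nrow(episodes) > 0) {
    ep <- episodes[order(episodes$onset_s), , drop = FALSE]
    lo <- ep$onset_s - ep$ramp_s
    hi <- ep$onset_s + ep$duration_s + ep$ramp_s
    if (any(lo < 0) || any(hi > duration_s)) {
      stop("episodes (including ramps) must lie within the stream",
           call. = FALSE)
    }
    if (nrow(ep) > 1 && any(lo[-1] < hi[-nrow(ep)])) {
      stop("episodes overlap after ramps", call. = FALSE)
    }
    episodes <- ep
  }
  bm <- baselines$mean
  parts <- default_partitions(mode)
  for (ch in names(bm)) {
    g <- fuzzify(bm[[ch]], parts[[ch]])
    if (g[["N"]] < 1) {
      stop(sprintf("baseline for '%s' (%g) is not inside the N plateau of mode '%s'",
                   ch, bm[[ch]], mode), call. = FALSE)
    }
  }
  structure(list(duration_s = duration_s, mode = mode, episodes = episodes,
                 baselines = baselines, seed = as.integer(seed)),
            class = "scenario_spec")
}

# One RNG substream per channel, derived from the shared seed, so adding
# a channel elsewhere never perturbs the others.
channel_noise <- function(seed, channel, n, sd) {
  idx <- match(channel, c("etco2", "rr", "spo2", "pr"))
  withr_seed((abs(seed) %% 100000L) * 16L + idx, stats::rnorm(n, 0, sd))
}

#' Generate a synthetic vital-sign stream with ground truth
#'
#' @param spec A [scenario_spec()].
#' @return List with `stream` (a [vital_stream()]) and `truth` (data
#'   frame `kind`, `start_s`, `end_s` of intervals where each event
#'   condition provably holds).
#' @examples
#' sp <- scenario_spec(300, episodes = data.frame(
#'   kind = "apnea", onset_s = 100, duration_s = 40, ramp_s = 5), seed = 42)
#' g <- generate_vitals(sp)
#' detect_events(g$stream)
#' @export
generate_vitals <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- as.integer(spec$duration_s)
  t <- seq_len(n) - 1
  rg <- channel_ranges()
  ch_names <- c("etco2", "rr", "spo2", "pr")
  vals <- list()
  for (ch in ch_names) {
    x <- spec$baselines$mean[[ch]] +
      channel_noise(spec$seed, ch, n, spec$baselines$sd[[ch]])
    vals[[ch]] <- pmin(pmax(x, rg[[ch]][1]), rg[[ch]][2])
  }
  truth <- list()
  for (i in seq_len(nrow(spec$episodes))) {
    ep <- spec$episodes[i, ]
    tg <- episode_targets(ep$kind)
    on <- ep$onset_s
    off <- ep$onset_s + ep$duration_s
    idx_ep <- which(t >= on & t < off)
    for (ch in names(tg)) {
      band <- tg[[ch]]$band
      if (band[1] == band[2]) {
        vals[[ch]][idx_ep] <- band[1]
      } else {
        mid <- mean(band)
        noisy <- mid + channel_noise(spec$seed + i, ch, length(idx_ep),
                                     spec$baselines$sd[[ch]] / 2)
        vals[[ch]][idx_ep] <- pmin(pmax(noisy, band[1]), band[2])
      }
      # linear ramps: baseline -> safe boundary before onset, and back after
      if (ep$ramp_s > 0) {
        base <- spec$baselines$mean[[ch]]
        safe <- tg[[ch]]$safe
        kk <- seq_len(ep$ramp_s)
        idx_in <- which(t >= on - ep$ramp_s & t < on)
        vals[[ch]][idx_in] <- base + (safe - base) * kk / ep$ramp_s
        idx_out <- which(t >= off & t < off + ep$ramp_s)
        vals[[ch]][idx_out] <- safe + (base - safe) * kk / ep$ramp_s
      }
    }
    for (k in episode_truth_kinds(ep$kind, ep$duration_s)) {
      truth[[length(truth) + 1]] <-
        data.frame(kind = k, start_s = on, end_s = off)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(0), start_s = numeric(0), end_s = numeric(0))
  truth <- truth[order(truth$kind, truth$start_s), , drop = FALSE]
  rownames(truth) <- NULL
  stream <- vital_stream(t, vals$etco2, vals$rr, vals$spo2, vals$pr,
                         mode = spec$mode)
  list(stream = stream, truth = truth)
}

#' The standard synthetic benchmark
#'
#' Twenty 30-minute streams (36,000 s in total) with a fixed episode
#' census: four event-free controls, then sixteen streams carrying three
#' scripted episodes each, cycling through all five episode kinds with
#' 5 s ramps. Apnea durations alternate 40 s (severe + clinically
#' significant) and 20 s (clinically significant only); other episodes
#' last 30-40 s.
#'
#' @param seed Integer seed driving all noise.
#' @param n_streams,stream_duration_s Census size (defaults 20 x 1800 s).
#' @return List with `streams` (list of `(stream, truth)` pairs as from
#'   [generate_vitals()]) and `manifest` (data frame of all scripted
#'   episodes: `stream`, `kind`, `onset_s`, `duration_s`, `ramp_s`).
#' @export
standard_benchmark <- function(seed = 20, n_streams = 20,
                               stream_duration_s = 1800) {
  kinds <- episode_kinds()
  manifest <- list()
  specs <- list()
  n_controls <- max(1L, round(n_streams / 5))
  for (i in seq_len(n_streams)) {
    if (i <= n_controls) {
      ep <- NULL
    } else {
      j <- i - n_controls
      kk <- kinds[(j + 0:2 - 1) %% length(kinds) + 1]
      dur <- vapply(kk, function(k) {
        if (k == "apnea") { if (j %% 2 == 1) 40 else 20 }
        else if (k == "severe_hypoxia") 30 else 40
      }, numeric(1))
      ep <- data.frame(kind = kk, onset_s = c(300, 900, 1400),
                       duration_s = dur, ramp_s = 5)
      manifest[[length(manifest) + 1]] <- cbind(stream = i, ep)
    }
    specs[[i]] <- scenario_spec(stream_duration_s, mode = "adult",
                                episodes = ep, seed = seed + i)
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stream = integer(0), kind = character(0), onset_s = numeric(0),
               duration_s = numeric(0), ramp_s = numeric(0))
  rownames(manifest) <- NULL
  list(streams = lapply(specs, generate_vitals), manifest = manifest)
}
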