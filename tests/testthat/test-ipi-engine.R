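cal <- read_calibration(mode = "adult")

test_that("reference samples score as calibrated", {
  # hypoventilation step: low PetCO2 with normal RR under normal SpO2/PR
  expect_equal(compute_ipi(etco2 = 26, rr = 12, spo2 = 98, pr = 70,
                           calibration = cal)$ipi, 8L)
  # the same sample desaturated to SpO2 90 drops from 8 to 5
  expect_equal(compute_ipi(etco2 = 26, rr = 12, spo2 = 90, pr = 70,
                           calibration = cal)$ipi, 5L)
  # all-normal vitals: top of the scale, no PR adjustment
  top <- compute_ipi(etco2 = 38, rr = 14, spo2 = 98, pr = 72,
                     calibration = cal)
  expect_equal(top$ipi, 10L)
  expect_equal(top$ipi_raw, 10.0)
  expect_false(top$pr_adjustment_applied)
  # apneic, hypoxic, tachycardic extreme: bottom of the scale
  expect_equal(compute_ipi(etco2 = 0, rr = 0, spo2 = 70, pr = 130,
                           calibration = cal)$ipi, 1L)
})

test_that("the graded pulse-rate adjustment subtracts up to one point and floors at 1", {
  parts <- default_partitions("adult")
  crisp <- function(etco2, rr, pr) {
    list(etco2 = fuzzify(etco2, parts$etco2), rr = fuzzify(rr, parts$rr),
         pr = fuzzify(pr, parts$pr))
  }
  # PR fully L with PetCO2 fully H and RR fully VH: subtract exactly one
  g <- crisp(etco2 = 50, rr = 40, pr = 30)
  adj <- apply_pr_adjustment(4.0, g)
  expect_equal(adj$value, 3.0)
  expect_equal(adj$subtraction, 1.0)
  # floor at the scale bottom
  expect_equal(apply_pr_adjustment(1.2, g)$value, 1.0)
  # PR fully N: no change
  gn <- crisp(etco2 = 50, rr = 40, pr = 70)
  expect_equal(apply_pr_adjustment(4.0, gn)$subtraction, 0.0)
  # partial condition: subtraction equals the weakest clause grade
  gp <- crisp(etco2 = 46, rr = 40, pr = 30)  # PetCO2 N/H transition 43..48
  expect_equal(apply_pr_adjustment(4.0, gp)$subtraction, 3 / 5)
  # high PR with low PetCO2 and RR triggers the second rule
  g2 <- crisp(etco2 = 20, rr = 3, pr = 130)
  expect_equal(apply_pr_adjustment(6.0, g2)$subtraction, 1.0)
})

test_that("scores stay within the 1-10 scale over random valid inputs in all modes", {
  set.seed(101)
  for (mode in age_modes()) {
    n <- 25000
    res <- compute_ipi(runif(n, 0, 100), runif(n, 0, 60),
                       runif(n, 0, 100), runif(n, 0, 250),
                       mode = mode,
                       calibration = read_calibration(mode = mode))
    expect_true(all(res$ipi >= 1L & res$ipi <= 10L))
    expect_true(all(res$ipi_raw >= 1 & res$ipi_raw <= 10))
    expect_false(any(is.na(res$ipi)))
  }
})

test_that("the score never rises as oxygen saturation falls", {
  set.seed(7)
  s <- seq(100, 70, by = -0.5)
  for (i in 1:60) {
    e <- runif(1, 0, 100); r <- runif(1, 0, 60); p <- runif(1, 30, 180)
    raw <- compute_ipi(rep(e, length(s)), rep(r, length(s)), s,
                       rep(p, length(s)), calibration = cal)$ipi_raw
    expect_true(all(diff(raw) <= 1e-9))
  }
})

test_that("single-parameter departures from normal never raise the score", {
  norm <- c(etco2 = 38, rr = 14, spo2 = 98, pr = 72)
  lims <- list(etco2 = c(0, 100), rr = c(0, 60), spo2 = c(70, 100),
               pr = c(30, 180))
  for (ch in names(norm)) {
    for (stop_at in lims[[ch]]) {
      path <- seq(norm[[ch]], stop_at, by = if (stop_at > norm[[ch]]) 0.25 else -0.25)
      args <- lapply(names(norm), function(nm) {
        if (nm == ch) path else rep(norm[[nm]], length(path))
      })
      names(args) <- names(norm)
      raw <- do.call(compute_ipi, c(args, list(calibration = cal)))$ipi_raw
      expect_true(all(diff(raw) <= 1e-9))
    }
  }
})

test_that("invalid channels yield score gaps, not errors", {
  res <- compute_ipi(c(38, NA, 38), c(14, 14, NaN), c(98, 98, 98),
                     c(72, 72, 72), calibration = cal)
  expect_equal(res$valid, c(TRUE, FALSE, FALSE))
  expect_equal(res$ipi, c(10L, NA_integer_, NA_integer_))
})

test_that("stream scoring equals independent per-sample scoring and is stateless", {
  g <- generate_vitals(random_scenario(42))
  trace <- compute_ipi_stream(g$stream, calibration = cal)
  expect_equal(nrow(trace), nrow(g$stream))
  # per-sample recomputation, one sample at a time
  idx <- seq(1, nrow(g$stream), by = 7)
  for (i in idx) {
    one <- compute_ipi(g$stream$etco2[i], g$stream$rr[i], g$stream$spo2[i],
                       g$stream$pr[i], calibration = cal)
    expect_equal(trace$ipi[i], one$ipi)
    expect_equal(trace$ipi_raw[i], one$ipi_raw)
  }
  # splitting the stream and concatenating traces changes nothing
  cut <- 211
  top <- g$stream[1:cut, ]; bot <- g$stream[(cut + 1):nrow(g$stream), ]
  s1 <- vital_stream(top$t, top$etco2, top$rr, top$spo2, top$pr)
  s2 <- vital_stream(bot$t, bot$etco2, bot$rr, bot$spo2, bot$pr)
  both <- rbind(compute_ipi_stream(s1, calibration = cal),
                compute_ipi_stream(s2, calibration = cal))
  expect_equal(both$ipi, trace$ipi)
  expect_equal(both$ipi_raw, trace$ipi_raw)
  # empty stream -> empty trace
  e <- vital_stream(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(compute_ipi_stream(e, calibration = cal)), 0L)
})

test_that("reported IPI equals round-half-up of the adjusted raw score", {
  set.seed(5)
  n <- 4000
  res <- compute_ipi(runif(n, 0, 100), runif(n, 0, 60), runif(n, 0, 100),
                     runif(n, 0, 250), calibration = cal)
  recomputed <- pmin(pmax(floor(res$ipi_raw - res$pr_subtraction + 0.5), 1), 10)
  expect_equal(res$ipi, as.integer(pmax(recomputed, 1)))
})
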