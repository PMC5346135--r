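test_that("epoch segmentation follows the 60 s / stride-45 convention", {
  e60 <- segment_epochs(60)
  expect_equal(e60$start_s, 0)
  expect_equal(e60$end_s, 60)
  e120 <- segment_epochs(120)
  expect_equal(e120$start_s, c(0, 45))  # start 90 would end at 150 > 120
  e150 <- segment_epochs(150)
  expect_equal(e150$start_s, c(0, 45, 90))
  expect_equal(e150$end_s - e150$start_s, rep(60, 3))
  # consecutive epochs overlap by exactly 15 s
  expect_equal(e150$end_s[-3] - e150$start_s[-1], rep(15, 2))
  expect_warning(none <- segment_epochs(59), "shorter")
  expect_equal(nrow(none), 0L)
  # the alternative overlap reading is available as a stride option
  expect_equal(segment_epochs(120, stride_s = 15)$start_s, seq(0, 60, 15))
})

test_that("epochs are labeled by any-overlap against events", {
  epochs <- segment_epochs(150)
  clin <- data.frame(kind = "severe_apnea", start_s = 50, end_s = 70)
  ipi <- data.frame(start_s = numeric(0), end_s = numeric(0))
  lab <- label_epochs(epochs, clin, ipi, "severe")
  expect_equal(lab$clinical_pos, c(TRUE, TRUE, FALSE))
  expect_false(any(lab$ipi_pos))
  # events of the other class are ignored
  lab2 <- label_epochs(epochs, clin, ipi, "clinically_significant")
  expect_false(any(lab2$clinical_pos))
  # an event touching only the epoch edge second still counts ([59,61) vs [0,60))
  clin3 <- data.frame(kind = "severe_hypoxia", start_s = 59, end_s = 61)
  expect_true(label_epochs(epochs, clin3, ipi, "severe")$clinical_pos[1])
  # zero-length overlap does not ([60, 70) vs [0, 60))
  clin4 <- data.frame(kind = "severe_hypoxia", start_s = 60, end_s = 70)
  expect_false(label_epochs(epochs, clin4, ipi, "severe")$clinical_pos[1])
})

test_that("generated ground truth reproduces the constructed epoch labels", {
  sp <- scenario_spec(300, episodes = data.frame(
    kind = c("apnea", "hypoxia"), onset_s = c(60, 200),
    duration_s = c(40, 30), ramp_s = 5), seed = 99)
  g <- generate_vitals(sp)
  epochs <- segment_epochs(nrow(g$stream))
  lab <- label_epochs(epochs, g$truth,
                      data.frame(start_s = numeric(0), end_s = numeric(0)),
                      "severe")
  # apnea occupies [60, 100): overlapping epochs are those starting 0..90
  expect_equal(lab$clinical_pos, epochs$start_s < 100 & epochs$end_s > 60)
})

test_that("sensitivity and specificity are the exact confusion ratios", {
  expect_equal(sensitivity_specificity(c(tp = 5, fn = 0, tn = 10, fp = 0)),
               c(sensitivity = 1.0, specificity = 1.0))
  expect_equal(sensitivity_specificity(c(tp = 83, fn = 17, tn = 96, fp = 4)),
               c(sensitivity = 0.83, specificity = 0.96))
  expect_error(sensitivity_specificity(c(tp = 0, fn = 0, tn = 5, fp = 5)),
               class = "ipindex_undefined_metric")
  expect_error(sensitivity_specificity(c(tp = 3, fn = 2, tn = 0, fp = 0)),
               class = "ipindex_undefined_metric")
})

test_that("confusion counts conserve the number of analyzed epochs", {
  lab <- data.frame(clinical_pos = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                    ipi_pos = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  cc <- confusion_counts(lab)
  expect_equal(sum(cc), 4L)
  expect_equal(cc[["tp"]], 1L)
  expect_equal(cc[["fn"]], 1L)
  expect_equal(cc[["fp"]], 1L)
  expect_equal(cc[["tn"]], 1L)
})

test_that("an oracle detector yields a perfect ROC and permuted labels a null AUC", {
  # oracle: ipi events exactly at the clinical events
  epochs <- segment_epochs(3600)
  set.seed(33)
  ev_start <- sort(sample(seq(0, 3500, by = 100), 12))
  clin <- data.frame(kind = "severe_hypoxia", start_s = ev_start,
                     end_s = ev_start + 20)
  lab <- label_epochs(epochs, clin, clin[, c("start_s", "end_s")], "severe")
  cc <- confusion_counts(lab)
  ss <- sensitivity_specificity(cc)
  expect_equal(ss[["sensitivity"]], 1.0)
  expect_equal(ss[["specificity"]], 1.0)
})

test_that("ROC analysis is deterministic, monotone in threshold, and counts conserve", {
  bench <- lapply(c(401, 402, 403, 404), function(s) {
    generate_vitals(random_scenario(s, duration_s = 900))$stream
  })
  roc <- roc_analysis(bench, "clinically_significant", calibration = adult_cal())
  expect_equal(roc$points$threshold, 1:9)
  expect_true(all(diff(roc$points$sensitivity) >= 0))
  expect_true(all(diff(roc$points$specificity) <= 0))
  expect_true(all(rowSums(roc$points[, c("tp", "fp", "fn", "tn")]) ==
                    roc$n_epochs))
  expect_gte(roc$auc, 0)
  expect_lte(roc$auc, 1)
  # identical rerun
  roc2 <- roc_analysis(bench, "clinically_significant", calibration = adult_cal())
  expect_identical(roc, roc2)
  # streams with no events at all give a single-class error
  quiet <- list(generate_vitals(scenario_spec(300, seed = 1))$stream)
  expect_error(roc_analysis(quiet, "severe"), class = "ipindex_undefined_metric")
})
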