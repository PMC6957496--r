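fs <- 500

test_that("the adaptive threshold is the scaled mean of the history", {
  cfg <- detector_config()
  expect_equal(adaptive_threshold(rep(1, 200), cfg), 1.25)
  expect_equal(adaptive_threshold(rep(0, 200), cfg), 0)
  expect_error(adaptive_threshold(numeric(0), cfg), "empty")
  # brute-force summation oracle on random histories
  set.seed(31)
  for (i in 1:50) {
    h <- runif(200, 0, 10)
    oracle <- 0
    for (v in h) oracle <- oracle + v
    expect_equal(adaptive_threshold(h, cfg), 1.25 / 200 * oracle,
                 tolerance = 1e-12)
    k <- sample(1:199, 1)
    expect_equal(adaptive_threshold(h[1:k], cfg), 1.25 * mean(h[1:k]),
                 tolerance = 1e-12)
  }
  # histories longer than the window use only the most recent values
  h <- c(rep(100, 50), rep(1, 200))
  expect_equal(adaptive_threshold(h, cfg), 1.25)
})

test_that("SWT detail coefficients are aligned and length-preserving", {
  cfg <- detector_config()
  expect_equal(swt_detail(numeric(4000), cfg), numeric(4000))
  x <- s_dip_signal(10000, at = 5000)
  cd2 <- swt_detail(x, cfg)
  expect_length(cd2, length(x))
  expect_lt(abs(which.max(cd2) - 5000) / fs, 0.040)
  expect_error(swt_detail(numeric(50), cfg), "too short")
})

test_that("detection scales with the signal and respects amplitude ratios", {
  x <- filtered_equine_lead()
  cfg <- detector_config(polarity = "min")
  d1 <- detect_speaks(x, fs, cfg)
  d2 <- detect_speaks(3.7 * x, fs, cfg)
  expect_identical(d1$peak_indices, d2$peak_indices)
  expect_equal(d2$threshold_trace$value, 3.7^2 * d1$threshold_trace$value,
               tolerance = 1e-9)
})

test_that("the larger of two close suprathreshold maxima is selected", {
  # two S deflections 150 ms apart: within one refractory span, so only
  # the larger should be reported
  x <- s_dip_signal(8000, at = 4000, amp = -1.5)
  x <- x + s_dip_signal(8000, at = 4075, amp = -1.0)
  # regular smaller beats elsewhere keep the rolling threshold sensible
  for (p in seq(500, 3500, by = 500)) {
    x <- x + s_dip_signal(8000, at = p, amp = -1.2)
  }
  d <- detect_speaks(x, fs, detector_config(polarity = "min"))
  near <- d$peak_indices[abs(d$peak_indices - 4000) < 150]
  expect_length(near, 1L)
  expect_lt(abs(near - 4000), 0.040 * fs)
  expect_length(d$peak_indices[abs(d$peak_indices - 4075) < 20], 0L)
})

test_that("a flat signal yields no detections from either detector", {
  expect_length(detect_speaks(numeric(5000), fs,
                              detector_config())$peak_indices, 0L)
  expect_length(pan_tompkins(numeric(5000), fs)$peak_indices, 0L)
})

test_that("a clean synthetic record is detected perfectly", {
  rec <- clean_equine_record()
  x <- filtered_equine_lead()
  d <- detect_speaks(x, fs, detector_config(polarity = "min"))
  sc <- score_detections(d$peak_indices, ideal_annotations(rec)$sample,
                         fs, 0.050)
  expect_equal(sc$recall, 100)
  expect_equal(sc$ppv, 100)
})

test_that("Pan-Tompkins finds every beat of a clean human record", {
  rec <- generate_record(beat_template("human"),
                         rhythm_spec(60, 60, seed = 2),
                         noise_preset("clean"))
  x <- record_lead(filter_record(rec), "II")
  d <- pan_tompkins(x, fs)
  sc <- score_detections(d$peak_indices, ideal_annotations(rec)$sample,
                         fs, 0.050)
  expect_equal(sc$recall, 100)
})

test_that("detections always respect the refractory period", {
  cfg <- detector_config(polarity = "min")
  refr <- round(cfg$refractory * fs)
  for (seed in c(5, 17)) {
    rec <- generate_record(
      beat_template("equine"),
      rhythm_spec(180, 20, apc_rate = 6, vpc_rate = 6, artefact_rate = 4,
                  seed = seed),
      noise_preset("exercise"))
    d <- detect_speaks(record_lead(filter_record(rec), "II"), fs, cfg)
    if (length(d$peak_indices) > 1L) {
      expect_gt(min(diff(d$peak_indices)), refr)
    }
  }
})

test_that("detection scoring implements the PPV/recall identities", {
  ref <- seq(500, 10000, by = 500)
  sc <- score_detections(ref, ref, fs, 0.05)
  expect_equal(sc$false_positive, 0L)
  expect_equal(sc$false_negative, 0L)
  expect_equal(sc$ppv, 100)
  expect_equal(sc$recall, 100)
  sc2 <- score_detections(c(ref, 10250L), ref, fs, 0.05)
  expect_equal(sc2$false_positive, 1L)
  expect_equal(sc2$true_positive, length(ref))
  expect_error(score_detections(ref, ref, fs, -1), "tolerance")

  # a large benchmark-sized scenario: 10356 reference beats, 204 missed,
  # 94 spurious detections
  ref_big <- seq(300, by = 400, length.out = 10356)
  missed <- seq(7, by = 50, length.out = 204)
  spurious <- ref_big[seq(10, by = 100, length.out = 94)] + 200L
  det <- sort(c(ref_big[-missed], spurious))
  sc3 <- score_detections(det, ref_big, fs, 0.05)
  expect_equal(sc3$false_negative, 204L)
  expect_equal(round(sc3$recall, 1), 98.0)
  expect_equal(round(sc3$ppv, 1), 99.1)
})
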