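make_record <- function(peaks, n = 30000L) {
  sig <- matrix(0, n, 2)
  for (p in peaks) {
    lo <- max(1L, p - 5L)
    hi <- min(n, p + 5L)
    sig[lo:hi, 1] <- 0.5
    sig[lo:hi, 2] <- 1.0
  }
  ecg_record(sig, fs = 500,
             annotations = data.frame(sample = sort(peaks),
                                      label = rep("N", length(peaks))))
}

test_that("a lone beat has a single centered timing mark", {
  rec <- make_record(15000L)
  ds <- extract_beats(rec, 15000L, "N")
  expect_equal(sum(ds$timing[1, ]), 1)
  expect_equal(ds$timing[1, 1001], 1L)  # center of the 2000-bin vector
  expect_equal(dim(ds$morphology), c(1L, 2L, 500L))
})

test_that("neighbours one second away land 100 bins from the center", {
  rec <- make_record(c(14500L, 15000L, 15500L))
  ds <- extract_beats(rec, c(14500L, 15000L, 15500L), rep("N", 3))
  expect_equal(which(ds$timing[2, ] == 1L), c(901L, 1001L, 1101L))
  expect_equal(sum(ds$timing[2, ]), 3)
})

test_that("windows crossing the record edge are zero-padded", {
  rec <- make_record(100L, n = 2000L)  # beat 0.2 s after record start
  ds <- extract_beats(rec, 100L, "N")
  expect_true(all(ds$morphology[1, , 1:150] == 0))
  expect_false(all(ds$morphology[1, , 151:500] == 0))
})

test_that("timing vectors count exactly the beats in the 20 s span", {
  rec <- generate_record(beat_template("equine"),
                         rhythm_spec(90, 60, apc_rate = 4, vpc_rate = 4,
                                     seed = 13))
  ann <- ideal_annotations(rec)
  ds <- extract_beats(rec, ann$sample, ann$label)
  span <- 1000L * 5L
  for (i in seq_len(n_beats(ds))) {
    p <- ann$sample[i]
    expected <- sum(ann$sample >= p - span & ann$sample < p + span)
    expect_equal(sum(ds$timing[i, ]), expected)
  }
  expect_equal(n_beats(ds), nrow(ann))
  expect_identical(as.character(ds$labels), ann$label)
})

test_that("input contracts of extract_beats are enforced", {
  rec <- make_record(15000L)
  one_lead <- ecg_record(rec$signal[, 1, drop = FALSE], fs = 500)
  expect_error(extract_beats(one_lead, 100L), "two-lead")
  wrong_rate <- ecg_record(rec$signal, fs = 360)
  expect_error(extract_beats(wrong_rate, 100L), "500 Hz")
})

test_that("splitting partitions the dataset at the requested fractions", {
  ds <- toy_beat_dataset(100, "separable", seed = 2)
  sp <- split_beats(ds, split_spec(c(0.6, 0.2, 0.2), seed = 9))
  expect_equal(n_beats(sp$train), 60L)
  expect_equal(n_beats(sp$validation), 20L)
  expect_equal(n_beats(sp$test), 20L)
  ids <- c(sp$train$beat_index, sp$validation$beat_index,
           sp$test$beat_index)
  expect_setequal(ids, ds$beat_index)
  expect_equal(anyDuplicated(ids), 0L)

  sp2 <- split_beats(ds, split_spec(c(0.6, 0.2, 0.2), seed = 9))
  expect_identical(sp$train$beat_index, sp2$train$beat_index)

  all_train <- split_beats(ds, split_spec(c(1, 0, 0), seed = 1))
  expect_equal(n_beats(all_train$train), 100L)
  expect_equal(n_beats(all_train$test), 0L)
})

test_that("the median target reproduces the published class balances", {
  expect_equal(median_target(c(186874, 11799, 37153, 1878)), 24476L)
  expect_equal(median_target(c(15991, 1087, 3699, 375)), 2393L)
})

test_that("median resampling balances every class at the median count", {
  ds <- toy_beat_dataset(140, "timing_only", seed = 5)  # unbalanced: N x2
  out <- median_resample(ds, seed = 3)
  counts <- table(out$labels)
  target <- median_target(table(ds$labels))
  expect_true(all(counts == target))
  expect_equal(n_beats(out), 4L * target)

  balanced <- toy_beat_dataset(40, "separable", seed = 6)
  re <- median_resample(balanced, seed = 1)
  expect_equal(sort(re$beat_index), sort(balanced$beat_index))
})

test_that("labels are matched to detections within the tolerance", {
  ann <- data.frame(sample = c(1000L, 2000L, 3000L),
                    label = c("N", "VPC", "N"))
  labs <- label_detections(c(1010L, 2990L, 5000L), ann, 500)
  expect_equal(labs, c("N", "N", NA))
})

test_that("datasets persist through the RDS + manifest container", {
  ds <- toy_beat_dataset(30, "separable", seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_beat_dataset(ds, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  back <- load_beat_dataset(path)
  expect_identical(back$morphology, ds$morphology)
  expect_identical(back$labels, ds$labels)
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(manifest$n, 30L)
})
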