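test_that("WFDB write/read round-trips signal and annotations", {
  rec <- generate_record(beat_template("equine"),
                         rhythm_spec(60, 20, vpc_rate = 3, apc_rate = 3,
                                     seed = 5))
  dir <- withr::local_tempdir()
  write_record_wfdb(rec, dir, "rt")
  back <- read_record(file.path(dir, "rt"))
  expect_equal(back$fs, rec$fs)
  expect_identical(back$leads, rec$leads)
  expect_identical(back$annotations, rec$annotations)
  # amplitudes agree to the quantization step (gain 1000 -> 0.001 mV)
  expect_lt(max(abs(back$signal - rec$signal)), 0.5e-3 + 1e-12)
  # a second pass through the quantized domain is bit-exact
  write_record_wfdb(back, dir, "rt2")
  again <- read_record(file.path(dir, "rt2"))
  expect_identical(again$signal, back$signal)
})

test_that("the CSV dialect round-trips records exactly", {
  rec <- generate_record(beat_template("human"),
                         rhythm_spec(75, 10, seed = 8),
                         noise_preset("clinic"))
  dir <- withr::local_tempdir()
  write_record_csv(rec, file.path(dir, "c"))
  back <- read_record_csv(file.path(dir, "c"))
  expect_equal(back$signal, rec$signal, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(back$annotations, rec$annotations)
  expect_equal(back$fs, 500)
})

test_that("MIT annotation bytes decode and map to the four classes", {
  # assemble an .atr stream by the format rules: 16-bit little-endian
  # words, code in the high 6 bits, interval in the low 10
  word <- function(code, interval) {
    as.raw(c(interval %% 256L, code * 4L + interval %/% 256L))
  }
  bytes <- c(word(1L, 100L),                      # N at 100
             word(5L, 300L),                      # V at 400
             word(60L, 3L),                       # NUM modifier (skipped)
             word(8L, 250L),                      # A at 650
             word(63L, 4L), charToRaw("note"),    # AUX with payload
             word(14L, 250L),                     # ~ at 900
             word(28L, 100L),                     # + rhythm change at 1000
             word(0L, 0L))
  dir <- withr::local_tempdir()
  writeLines(c("amap 1 360 2000", "amap.dat 16 200(0)/mV 16 0 0 0 0 II"),
             file.path(dir, "amap.hea"))
  writeBin(integer(2000), file.path(dir, "amap.dat"), size = 2L,
           endian = "little")
  writeBin(bytes, file.path(dir, "amap.atr"))
  rec <- read_record(file.path(dir, "amap"))
  # 0-based WFDB times become 1-based indices; '+' is ignored
  expect_equal(rec$annotations$sample, c(101L, 401L, 651L, 901L))
  expect_equal(rec$annotations$label, c("N", "VPC", "APC", "A"))
  expect_equal(rec$fs, 360)
})

test_that("unmapped symbols and missing annotation files are errors", {
  dir <- withr::local_tempdir()
  writeLines(c("bad 1 360 100", "bad.dat 16 200(0)/mV 16 0 0 0 0 II"),
             file.path(dir, "bad.hea"))
  writeBin(integer(100), file.path(dir, "bad.dat"), size = 2L,
           endian = "little")
  expect_error(read_record(file.path(dir, "bad")), "no annotation file")
  word <- function(code, interval) {
    as.raw(c(interval %% 256L, code * 4L + interval %/% 256L))
  }
  writeBin(c(word(1L, 10L), word(31L, 10L), word(0L, 0L)),
           file.path(dir, "bad.atr"))
  # '!' (ventricular flutter wave) is ignorable by default, but an
  # incomplete map must fail loudly, naming the symbol
  expect_error(read_record(file.path(dir, "bad"), class_map = c(N = "N")),
               "'!'")
})

test_that("format 212 packing decodes signed 12-bit sample pairs", {
  dir <- withr::local_tempdir()
  # samples: lead1 = 100, -100; lead2 = 2047, -2048 (12-bit extremes)
  pack212 <- function(s1, s2) {
    u1 <- ifelse(s1 < 0, s1 + 4096L, s1)
    u2 <- ifelse(s2 < 0, s2 + 4096L, s2)
    as.raw(c(u1 %% 256L, (u2 %/% 256L) * 16L + u1 %/% 256L, u2 %% 256L))
  }
  bytes <- c(pack212(100L, 2047L), pack212(-100L, -2048L))
  writeLines(c("p212 2 360 2",
               "p212.dat 212 200(0)/mV 12 0 100 0 0 MLII",
               "p212.dat 212 200(0)/mV 12 0 2047 0 0 V1"),
             file.path(dir, "p212.hea"))
  writeBin(bytes, file.path(dir, "p212.dat"))
  utils::write.csv(data.frame(sample = 1L, label = "N"),
                   file.path(dir, "p212_annotations.csv"),
                   row.names = FALSE)
  rec <- read_record(file.path(dir, "p212"))
  expect_equal(rec$signal[, 1], c(100, -100) / 200)
  expect_equal(rec$signal[, 2], c(2047, -2048) / 200)
  expect_equal(rec$leads, c("MLII", "V1"))
})

test_that("class map files round-trip and the default map is total over beats", {
  map <- default_class_map()
  expect_true(all(map %in% c("N", "APC", "VPC", "A", "ignore")))
  expect_equal(unname(map[c("V", "A", "N", "~")]),
               c("VPC", "APC", "N", "A"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "map.csv")
  write_class_map(map, p)
  expect_identical(read_class_map(p), map)
})

test_that("resampling scales length and preserves annotation times", {
  set.seed(6)
  rec <- ecg_record(matrix(rnorm(3600 * 2), ncol = 2), fs = 360,
                    annotations = data.frame(sample = c(361L, 1801L),
                                             label = c("N", "VPC")))
  up <- resample_record(rec, 500)
  expect_equal(nrow(up$signal), 5000L)      # 3600 * 500/360
  expect_equal(up$annotations$sample, c(501L, 2501L))
  expect_equal(up$fs, 500)
  expect_identical(resample_record(rec, 360), rec)
  expect_error(resample_record(rec, -5), "positive")

  # annotation times preserved to within one sample for arbitrary ratios
  for (target in c(250, 500, 720)) {
    r2 <- resample_record(rec, target)
    t_orig <- (rec$annotations$sample - 1) / rec$fs
    t_new <- (r2$annotations$sample - 1) / target
    expect_true(all(abs(t_new - t_orig) <= 1 / target + 1e-9))
  }
})

test_that("band-limited resampling reproduces an in-band tone", {
  t360 <- (0:3599) / 360
  rec <- ecg_record(matrix(sin(2 * pi * 5 * t360), ncol = 1), fs = 360)
  up <- resample_record(rec, 500)
  t500 <- (0:(nrow(up$signal) - 1)) / 500
  core <- 100:4900
  expect_lt(max(abs(up$signal[core, 1] - sin(2 * pi * 5 * t500[core]))),
            0.01)
})
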