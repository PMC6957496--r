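# Classifier dataset construction: two-lead morphology windows, binary
# beat-timing vectors, train/validation/test splitting and median class
# resampling.

#' Build classifier inputs from detected beats
#'
#' For every detection, extracts the two-lead morphology window of
#' `window` samples centered on the beat (0.5 s before to 0.5 s after at
#' 500 Hz for the default 500), and a binary timing vector of
#' `timing_length` bins at `timing_rate` Hz spanning 10 s before to 10 s
#' after the beat, with a 1 in every bin that contains a detected beat
#' (two beats in one 10 ms bin keep a single 1). Windows crossing the
#' record edges are zero-padded.
#'
#' @param record A two-lead [ecg_record()] at 500 Hz (resample first if
#'   needed), normally filtered.
#' @param detections Sorted integer vector of beat sample indices.
#' @param labels Character vector of per-beat classes (same length as
#'   `detections`), or `NULL` for inference-time datasets.
#' @param window Morphology window length in samples (default 500; 512
#'   gives the zero-padded variant).
#' @param timing_length Timing vector length in bins (default 2000 =
#'   20 s x 100 Hz; 2048 gives the zero-padded variant).
#' @param timing_rate Timing vector rate in Hz (default 100).
#' @return A `beat_dataset`: list with `morphology`
#'   (`n x 2 x window` array, mV), `timing` (`n x timing_length` 0/1
#'   matrix), `labels` (factor with levels N, APC, VPC, A, or `NA`),
#'   `beat_index`, `source_record`.
#' @export
extract_beats <- function(record, detections, labels = NULL,
                          window = 500L, timing_length = 2000L,
                          timing_rate = 100) {
  stopifnot(inherits(record, "ecg_record"))
  if (ncol(record$signal) != 2L) {
    stop("extract_beats needs a two-lead record")
  }
  if (record$fs != 500) {
    stop("record must be at 500 Hz; use resample_record() first")
  }
  detections <- as.integer(detections)
  n_beat <- length(detections)
  if (!is.null(labels) && length(labels) != n_beat) {
    stop("labels must match detections in length")
  }
  fs <- record$fs
  n <- nrow(record$signal)
  half_before <- window %/% 2L
  morph <- array(0, dim = c(n_beat, 2L, window))
  timing <- matrix(0L, n_beat, timing_length)
  dec <- as.integer(fs / timing_rate)          # 500 Hz -> 100 Hz: 5
  half_bins <- timing_length %/% 2L
  span <- half_bins * dec                      # +/- 10 s in samples
  center_bin <- half_bins + 1L                 # 1-based center position

  for (i in seq_len(n_beat)) {
    p <- detections[i]
    lo <- p - half_before
    hi <- lo + window - 1L
    src <- max(lo, 1L):min(hi, n)
    dst <- src - lo + 1L
    morph[i, 1L, dst] <- record$signal[src, 1L]
    morph[i, 2L, dst] <- record$signal[src, 2L]

    rel <- detections - p
    inside <- rel >= -span & rel < span
    bins <- rel[inside] %/% dec + center_bin
    bins <- bins[bins >= 1L & bins <= timing_length]
    timing[i, unique(bins)] <- 1L
  }

  labels <- if (is.null(labels)) {
    factor(rep(NA_character_, n_beat), levels = .beat_classes)
  } else {
    factor(as.character(labels), levels = .beat_classes)
  }
  structure(list(morphology = morph, timing = timing, labels = labels,
                 beat_index = detections,
                 source_record = rep("record", n_beat)),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats, morphology 2 x %d, timing %d\n",
              dim(x$morphology)[1L], dim(x$morphology)[3L],
              ncol(x$timing)))
  if (!all(is.na(x$labels))) print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

#' Number of beats in a dataset
#' @param dataset A `beat_dataset`.
#' @return Integer count.
#' @export
n_beats <- function(dataset) dim(dataset$morphology)[1L]

# subset a beat_dataset by row indices
.dataset_subset <- function(dataset, idx) {
  structure(list(morphology = dataset$morphology[idx, , , drop = FALSE],
                 timing = dataset$timing[idx, , drop = FALSE],
                 labels = dataset$labels[idx],
                 beat_index = dataset$beat_index[idx],
                 source_record = dataset$source_record[idx]),
            class = "beat_dataset")
}

# concatenate beat_datasets
.dataset_bind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, n_beats, 1L) > 0L]
  if (length(parts) == 1L) return(parts[[1L]])
  w <- dim(parts[[1L]]$morphology)[3L]
  morph <- do.call(abind_1, lapply(parts, `[[`, "morphology"))
  structure(list(
    morphology = morph,
    timing = do.call(rbind, lapply(parts, `[[`, "timing")),
    labels = factor(unlist(lapply(parts, function(p) as.character(p$labels))),
                    levels = .beat_classes),
    beat_index = unlist(lapply(parts, `[[`, "beat_index")),
    source_record = unlist(lapply(parts, `[[`, "source_record"))),
    class = "beat_dataset")
}

# bind 3-d arrays along the first dimension
abind_1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  total <- sum(vapply(arrs, function(a) dim(a)[1L], 1L))
  out <- array(0, dim = c(total, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k > 0L) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' Split specification
#'
#' @param fractions Train/validation/test fractions, summing to 1
#'   (default 0.6/0.2/0.2).
#' @param seed Integer seed for the random partition.
#' @param resample_training If `TRUE`, [split_beats()] median-resamples
#'   the training split.
#' @return A `split_spec` list.
#' @export
split_spec <- function(fractions = c(0.6, 0.2, 0.2), seed = 1L,
                       resample_training = FALSE) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three non-negative numbers summing to 1")
  }
  structure(list(fractions = fractions, seed = as.integer(seed),
                 resample_training = isTRUE(resample_training)),
            class = "split_spec")
}

#' Randomly partition a dataset into train/validation/test
#'
#' @param dataset A `beat_dataset`.
#' @param spec A [split_spec()].
#' @return Named list of three disjoint `beat_dataset`s (`train`,
#'   `validation`, `test`) whose union is the input; the training split is
#'   median-resampled when `spec$resample_training` is set.
#' @export
split_beats <- function(dataset, spec = split_spec()) {
  n <- n_beats(dataset)
  out <- .with_seed(spec$seed, {
    perm <- sample.int(n)
    n_train <- round(spec$fractions[1L] * n)
    n_val <- round(spec$fractions[2L] * n)
    n_val <- min(n_val, n - n_train)
    idx_train <- perm[seq_len(n_train)]
    idx_val <- perm[n_train + seq_len(n_val)]
    idx_test <- perm[setdiff(seq_len(n), seq_len(n_train + n_val))]
    list(train = .dataset_subset(dataset, sort(idx_train)),
         validation = .dataset_subset(dataset, sort(idx_val)),
         test = .dataset_subset(dataset, sort(idx_test)))
  })
  if (spec$resample_training) {
    out$train <- median_resample(out$train, seed = spec$seed + 1L)
  }
  out
}

#' Median-count target for class balancing
#'
#' The per-class target is the median of the class counts; with an even
#' number of classes this is the mean of the two middle counts, rounded to
#' the nearest integer.
#'
#' @param counts Integer vector of per-class sample counts.
#' @return Integer target count per class.
#' @export
median_target <- function(counts) {
  as.integer(round(stats::median(as.numeric(counts))))
}

#' Median resampling of a training dataset
#'
#' Each class present is randomly under-sampled (without replacement) or
#' over-sampled (with replacement) to the median class count, so all
#' classes end up equally represented.
#'
#' @param training A `beat_dataset` with labels.
#' @param seed Integer seed.
#' @return The resampled `beat_dataset` of size
#'   `median target x number of classes present`.
#' @export
median_resample <- function(training, seed = 1L) {
  labs <- as.character(training$labels)
  present <- .beat_classes[.beat_classes %in% labs]
  if (!length(present)) stop("median_resample needs at least one class")
  counts <- vapply(present, function(cl) sum(labs == cl), 1L)
  target <- median_target(counts)
  .with_seed(seed, {
    idx <- unlist(lapply(present, function(cl) {
      pool <- which(labs == cl)
      if (length(pool) >= target) {
        sample(pool, target)
      } else {
        c(pool, sample(pool, target - length(pool), replace = TRUE))
      }
    }))
    .dataset_subset(training, sample(idx))
  })
}

#' Match reference annotations to detections for training labels
#'
#' Greedy nearest matching within the tolerance; detections with no
#' matching reference beat get `NA` labels.
#'
#' @param detections Sorted integer detection indices.
#' @param annotations Data frame with `sample` and `label`.
#' @param rate Sample rate in Hz.
#' @param tolerance Matching tolerance in seconds (default 0.050).
#' @return Character vector of labels aligned with `detections` (`NA`
#'   where unmatched).
#' @export
label_detections <- function(detections, annotations, rate,
                             tolerance = 0.050) {
  tol <- tolerance * rate
  used <- rep(FALSE, nrow(annotations))
  out <- rep(NA_character_, length(detections))
  for (i in seq_along(detections)) {
    d <- detections[i]
    cand <- which(!used & abs(annotations$sample - d) <= tol)
    if (length(cand)) {
      j <- cand[which.min(abs(annotations$sample[cand] - d))]
      used[j] <- TRUE
      out[i] <- annotations$label[j]
    }
  }
  out
}

#' Persist / load a beat dataset
#'
#' The dataset is stored as an RDS container next to a JSON manifest
#' recording the class counts and dimensions.
#'
#' @param dataset A `beat_dataset` (or the named split list from
#'   [split_beats()]).
#' @param path Output `.rds` path; the manifest goes to
#'   `<path>.manifest.json`.
#' @return `save_beat_dataset`: `path`, invisibly; `load_beat_dataset`:
#'   the dataset object.
#' @export
save_beat_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  describe <- function(d) {
    list(n = n_beats(d),
         window = dim(d$morphology)[3L],
         timing_length = ncol(d$timing),
         class_counts = as.list(table(d$labels)))
  }
  manifest <- if (inherits(dataset, "beat_dataset")) {
    describe(dataset)
  } else {
    lapply(dataset, describe)
  }
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_beat_dataset
#' @export
load_beat_dataset <- function(path) readRDS(path)
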