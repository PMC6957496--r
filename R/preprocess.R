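# Baseline-wander removal and wavelet denoising.
#
# Baseline estimation follows the classical dual median filter: a 200 ms
# median removes P waves and QRS complexes, a subsequent 600 ms median
# removes T waves; what remains is the baseline, which is subtracted from
# the original signal. Residual high-frequency noise is then suppressed by
# multilevel DWT detail thresholding.

#' Filtering configuration
#'
#' @param median_width_1 Width (s) of the first median filter; 0.200 by
#'   default, wide enough to flatten P waves and QRS complexes.
#' @param median_width_2 Width (s) of the second median filter; 0.600 by
#'   default, wide enough to flatten T waves. Must exceed `median_width_1`.
#' @param denoise_wavelet `"db8"` (default) or `"coif2"`.
#' @param denoise_level DWT decomposition depth (default 4 at 500 Hz, which
#'   places the discarded detail scales above roughly 15 Hz).
#' @param threshold_rule `"universal_soft"` (default), `"universal_hard"`,
#'   or `"fixed"`. The universal threshold is sigma * sqrt(2 log n) with
#'   sigma estimated from the median absolute deviation of the finest
#'   detail scale.
#' @param fixed_threshold Threshold value used when `threshold_rule` is
#'   `"fixed"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(median_width_1 = 0.200, median_width_2 = 0.600,
                          denoise_wavelet = c("db8", "coif2"),
                          denoise_level = 4L,
                          threshold_rule = c("universal_soft",
                                             "universal_hard", "fixed"),
                          fixed_threshold = NULL) {
  denoise_wavelet <- match.arg(denoise_wavelet)
  threshold_rule <- match.arg(threshold_rule)
  if (median_width_1 <= 0 || median_width_2 <= median_width_1) {
    stop("median widths must satisfy 0 < median_width_1 < median_width_2")
  }
  if (denoise_level < 1L) stop("denoise_level must be >= 1")
  if (threshold_rule == "fixed" && is.null(fixed_threshold)) {
    stop("threshold_rule 'fixed' requires fixed_threshold")
  }
  structure(list(median_width_1 = median_width_1,
                 median_width_2 = median_width_2,
                 denoise_wavelet = denoise_wavelet,
                 denoise_level = as.integer(denoise_level),
                 threshold_rule = threshold_rule,
                 fixed_threshold = fixed_threshold),
            class = "filter_config")
}

# Running median with reflect padding; window = round(width * rate), forced
# odd so the filter is symmetric and output length equals input length.
.median_filter <- function(x, width, rate) {
  k <- round(width * rate)
  if (k %% 2 == 0) k <- k + 1L
  k <- max(k, 3L)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  y <- stats::runmed(xp, k, endrule = "keep")
  y[(half + 1L):(half + n)]
}

#' Remove baseline wander from one lead
#'
#' Estimates the baseline by cascading two median filters (widths
#' `median_width_1` then `median_width_2`) and subtracts it from the input.
#'
#' @param x Numeric vector, one lead's samples (mV).
#' @param rate Sample rate in Hz.
#' @param cfg A [filter_config()].
#' @return Numeric vector of the same length with the baseline removed.
#' @export
remove_baseline <- function(x, rate, cfg = filter_config()) {
  if (length(x) <= cfg$median_width_2 * rate) {
    stop("signal shorter than the second median window (",
         cfg$median_width_2, " s at ", rate, " Hz)")
  }
  baseline <- .median_filter(.median_filter(x, cfg$median_width_1, rate),
                             cfg$median_width_2, rate)
  x - baseline
}

#' Wavelet-threshold denoising of one lead
#'
#' Decomposes the signal with a multilevel DWT, sets detail coefficients
#' below the threshold to zero (soft or hard rule), and reconstructs.
#'
#' @inheritParams remove_baseline
#' @return Denoised numeric vector of the same length.
#' @export
denoise <- function(x, rate, cfg = filter_config()) {
  bank <- .wavelet_bank(cfg$denoise_wavelet)
  if (length(x) < bank$len) {
    stop("signal shorter than one wavelet filter length (", bank$len, ")")
  }
  dec <- .dwt(x, cfg$denoise_wavelet, cfg$denoise_level)
  thr <- switch(cfg$threshold_rule,
    fixed = cfg$fixed_threshold,
    {
      sigma <- stats::median(abs(dec$d[[1L]])) / 0.6745
      sigma * sqrt(2 * log(length(x)))
    })
  soft <- cfg$threshold_rule == "universal_soft"
  for (j in seq_along(dec$d)) {
    d <- dec$d[[j]]
    if (soft) {
      dec$d[[j]] <- sign(d) * pmax(abs(d) - thr, 0)
    } else {
      d[abs(d) < thr] <- 0
      dec$d[[j]] <- d
    }
  }
  .idwt(dec)
}

#' Filter a whole record
#'
#' Applies [remove_baseline()] and [denoise()] to every lead.
#'
#' @param record An [ecg_record()].
#' @param cfg A [filter_config()].
#' @return The filtered [ecg_record()] (annotations untouched).
#' @export
filter_record <- function(record, cfg = filter_config()) {
  stopifnot(inherits(record, "ecg_record"))
  sig <- record$signal
  for (j in seq_len(ncol(sig))) {
    sig[, j] <- denoise(remove_baseline(sig[, j], record$fs, cfg),
                        record$fs, cfg)
  }
  out <- record
  out$signal <- sig
  out
}
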