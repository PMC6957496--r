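# S-peak detection from stationary-wavelet detail coefficients.
#
# Detection statistic: squared Symlet-4 SWT detail coefficients at scale 4
# (cd4^2), whose passband at 500 Hz straddles the QRS energy while largely
# rejecting P/T waves. A relative maximum of cd4^2 is accepted as a beat
# when it exceeds an adaptive threshold equal to 1.25x the rolling mean of
# the last 200 relative maxima; among suprathreshold maxima within one
# 200 ms refractory span, the largest is kept. Accepted coefficient peaks
# are refined to the extremum of the filtered signal within +/- 40 ms.

#' S-peak detector configuration
#'
#' @param wavelet Wavelet for the stationary transform (default `"sym4"`,
#'   whose shape matches the equine QRS complex).
#' @param detail_scale SWT detail scale used for detection (default 4).
#' @param threshold_factor Multiplier on the rolling-mean of relative
#'   maxima (default 1.25).
#' @param maxima_window Number of relative maxima in the rolling mean
#'   (default 200).
#' @param refractory Minimum inter-beat interval in seconds (default
#'   0.200, the shortest equine ventricular effective refractory period).
#' @param detection_lead Lead label used for detection (default `"II"`).
#' @param polarity Refinement polarity: `"min"` (equine S), `"max"` (human
#'   R) or `"auto"` (largest absolute deflection).
#' @return A `detector_config` list.
#' @export
detector_config <- function(wavelet = "sym4", detail_scale = 4L,
                            threshold_factor = 1.25, maxima_window = 200L,
                            refractory = 0.200, detection_lead = "II",
                            polarity = c("auto", "min", "max")) {
  polarity <- match.arg(polarity)
  if (threshold_factor <= 0) stop("threshold_factor must be positive")
  if (maxima_window < 1L) stop("maxima_window must be >= 1")
  if (refractory <= 0) stop("refractory must be positive")
  structure(list(wavelet = wavelet, detail_scale = as.integer(detail_scale),
                 threshold_factor = threshold_factor,
                 maxima_window = as.integer(maxima_window),
                 refractory = refractory, detection_lead = detection_lead,
                 polarity = polarity),
            class = "detector_config")
}

#' Sample-aligned SWT detail coefficients
#'
#' Computes the squared stationary-wavelet detail coefficients (cd^2) at
#' `cfg$detail_scale`; the undecimated transform keeps the output aligned
#' with (and the same length as) the input.
#'
#' @param x Numeric vector, the filtered detection lead.
#' @param cfg A [detector_config()].
#' @return Numeric vector of squared detail coefficients, same length as
#'   `x`.
#' @export
swt_detail <- function(x, cfg = detector_config()) {
  .swt_detail(x, cfg$wavelet, cfg$detail_scale)^2
}

#' Adaptive detection threshold
#'
#' The threshold in effect at a relative maximum is
#' `threshold_factor` times the arithmetic mean of the available rolling
#' history of squared-coefficient maxima -- exactly
#' (1.25/200) * sum of the last 200 maxima once 200 have been seen.
#'
#' @param maxima_values Numeric vector: the rolling history (at most
#'   `cfg$maxima_window` values).
#' @param cfg A [detector_config()].
#' @return The threshold value.
#' @export
adaptive_threshold <- function(maxima_values, cfg = detector_config()) {
  if (!length(maxima_values)) {
    stop("empty maxima history: the threshold is undefined before the ",
         "first relative maximum has been observed")
  }
  if (length(maxima_values) > cfg$maxima_window) {
    maxima_values <- utils::tail(maxima_values, cfg$maxima_window)
  }
  cfg$threshold_factor * mean(maxima_values)
}

# Strict local maxima of `v` with a minimum separation (in samples);
# plateau duplicates within the separation keep the larger value.
.relative_maxima <- function(v, min_sep) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  core <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                  v[2:(n - 1L)] > v[3:n]) + 1L
  if (!length(core)) return(integer(0))
  kept <- integer(length(core))
  m <- 0L
  for (i in core) {
    if (m > 0L && i - kept[m] < min_sep) {
      if (v[i] > v[kept[m]]) kept[m] <- i
    } else {
      m <- m + 1L
      kept[m] <- i
    }
  }
  kept[seq_len(m)]
}

#' Detect S (or R) peaks with the adaptive-threshold SWT detector
#'
#' @param x Numeric vector: one filtered lead.
#' @param rate Sample rate in Hz.
#' @param cfg A [detector_config()].
#' @return A `detection_result` list with `peak_indices` (1-based,
#'   increasing, consecutive peaks separated by more than the refractory
#'   period) and `threshold_trace` (data frame: the relative-maximum index,
#'   its cd^2 value, and the threshold in effect there).
#' @export
detect_speaks <- function(x, rate, cfg = detector_config()) {
  cd2 <- swt_detail(x, cfg)
  min_sep <- max(1L, round(0.010 * rate))  # 10 ms plateau suppression
  mx <- .relative_maxima(cd2, min_sep)
  out <- list(peak_indices = integer(0),
              threshold_trace = data.frame(index = integer(0),
                                           value = numeric(0),
                                           threshold = numeric(0)))
  class(out) <- "detection_result"
  if (!length(mx)) return(out)

  vals <- cd2[mx]
  # Warm-up: the history is seeded with the global maximum of the first
  # second, so the first beats are not silently undetectable.
  seed_val <- max(cd2[seq_len(min(length(cd2), round(rate)))])
  w <- cfg$maxima_window
  # rolling mean over the last w maxima (seed value prepended), evaluated
  # just before each maximum
  hist_vals <- c(seed_val, vals)
  cs <- cumsum(hist_vals)
  nm <- length(mx)
  pos <- seq_len(nm)                    # history length before maximum i is pos[i]
  lo <- pmax(pos - w + 1L, 1L)
  means <- (cs[pos] - c(0, cs)[lo]) / (pos - lo + 1L)
  thresholds <- cfg$threshold_factor * means

  refr <- round(cfg$refractory * rate)
  supra <- which(vals > thresholds)
  peaks <- integer(0)
  peak_vals <- numeric(0)
  i <- 1L
  while (i <= length(supra)) {
    # group suprathreshold maxima within one refractory span; keep largest
    j <- i
    while (j + 1L <= length(supra) &&
           mx[supra[j + 1L]] - mx[supra[i]] <= refr) {
      j <- j + 1L
    }
    grp <- supra[i:j]
    best <- grp[which.max(vals[grp])]
    peaks <- c(peaks, mx[best])
    peak_vals <- c(peak_vals, vals[best])
    # skip maxima inside the refractory span after the accepted peak
    i <- j + 1L
    while (i <= length(supra) && mx[supra[i]] - mx[best] <= refr) {
      i <- i + 1L
    }
  }

  # refine each accepted coefficient peak to the extremum of the filtered
  # signal within +/- 40 ms
  half <- round(0.040 * rate)
  n <- length(x)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    seg <- x[lo:hi]
    k <- switch(cfg$polarity,
                min = which.min(seg),
                max = which.max(seg),
                auto = which.max(abs(seg)))
    as.integer(lo + k - 1L)
  }, integer(1))

  # refinement can shrink a gap below the refractory period; enforce it by
  # keeping the larger-coefficient peak of any violating pair
  if (length(refined) > 1L) {
    keep <- rep(TRUE, length(refined))
    last <- 1L
    for (k in 2L:length(refined)) {
      if (refined[k] - refined[last] <= refr) {
        if (peak_vals[k] > peak_vals[last]) {
          keep[last] <- FALSE
          last <- k
        } else {
          keep[k] <- FALSE
        }
      } else {
        last <- k
      }
    }
    refined <- refined[keep]
  }

  out$peak_indices <- as.integer(refined)
  out$threshold_trace <- data.frame(index = mx, value = vals,
                                    threshold = thresholds)
  out
}

#' Pan-Tompkins reference detector
#'
#' The classical pipeline: 5--15 Hz band-pass, five-point derivative,
#' squaring, 150 ms moving-window integration, then peak picking with the
#' adaptive signal/noise dual-threshold rule and a 200 ms refractory
#' period. Serves as the comparison baseline for the SWT detector; on
#' equine records with tall T waves its amplitude-based threshold mistakes
#' T waves for QRS complexes.
#'
#' @param x Numeric vector: one lead (raw or filtered).
#' @param rate Sample rate in Hz.
#' @return A `detection_result` (see [detect_speaks()]).
#' @export
pan_tompkins <- function(x, rate) {
  out <- list(peak_indices = integer(0),
              threshold_trace = data.frame(index = integer(0),
                                           value = numeric(0),
                                           threshold = numeric(0)))
  class(out) <- "detection_result"
  n <- length(x)
  if (n < rate) return(out)

  bp <- signal::butter(3, c(5, 15) / (rate / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  # five-point derivative
  dcoef <- c(1, 2, 0, -2, -1) * rate / 8
  dx <- stats::filter(xf, dcoef, sides = 2)
  dx[is.na(dx)] <- 0
  sq <- as.numeric(dx)^2
  nw <- max(1L, round(0.150 * rate))
  mwi <- stats::filter(sq, rep(1 / nw, nw), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refr <- round(0.200 * rate)
  cand <- .relative_maxima(mwi, refr)
  if (!length(cand)) return(out)

  spki <- max(mwi[seq_len(min(n, 2L * rate))]) / 3
  npki <- mean(mwi[seq_len(min(n, 2L * rate))]) / 2
  peaks <- integer(0)
  thr_trace <- numeric(length(cand))
  for (k in seq_along(cand)) {
    thr <- npki + 0.25 * (spki - npki)
    thr_trace[k] <- thr
    v <- mwi[cand[k]]
    if (v > thr) {
      spki <- 0.125 * v + 0.875 * spki
      peaks <- c(peaks, cand[k])
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
  }

  # refine: MWI peaks lag the QRS by roughly half the integration window;
  # snap to the largest absolute deflection of the band-passed signal
  half <- round(0.100 * rate)
  refined <- vapply(peaks, function(p) {
    ctr <- max(1L, p - nw %/% 2L)
    lo <- max(1L, ctr - half)
    hi <- min(n, ctr + half)
    as.integer(lo + which.max(abs(xf[lo:hi])) - 1L)
  }, integer(1))
  refined <- refined[c(TRUE, diff(refined) > refr)]

  out$peak_indices <- as.integer(refined)
  out$threshold_trace <- data.frame(index = cand, value = mwi[cand],
                                    threshold = thr_trace)
  out
}

#' Score detections against reference beat positions
#'
#' Greedy one-to-one matching in time order within the tolerance: each
#' detection is matched to the nearest unmatched reference beat; unmatched
#' detections count as false positives, unmatched references as false
#' negatives.
#'
#' @param detected Integer vector of detected peak indices (sorted).
#' @param reference Integer vector of reference annotation indices
#'   (sorted).
#' @param rate Sample rate in Hz.
#' @param tolerance Matching tolerance in seconds (default 0.050).
#' @return A `detection_score` list: `true_positive`, `false_positive`,
#'   `false_negative`, `ppv` (%), `recall` (%), `match_tolerance`.
#' @export
score_detections <- function(detected, reference, rate, tolerance = 0.050) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  tol <- tolerance * rate
  used <- rep(FALSE, length(reference))
  tp <- 0L
  for (d in detected) {
    cand <- which(!used & abs(reference - d) <= tol)
    if (length(cand)) {
      j <- cand[which.min(abs(reference[cand] - d))]
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(reference) - tp
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  structure(list(true_positive = tp, false_positive = fp,
                 false_negative = fn, ppv = ppv, recall = recall,
                 match_tolerance = tolerance),
            class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf("<detection_score> TP=%d FP=%d FN=%d  PPV=%.1f%%  recall=%.1f%% (tol %g s)\n",
              x$true_positive, x$false_positive, x$false_negative,
              x$ppv, x$recall, x$match_tolerance))
  invisible(x)
}
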