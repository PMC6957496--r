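# Small synthetic benchmark sets for the classifier.
#
# These are not ECG simulations: they are controlled 4-class toy problems
# used to verify that the network machinery learns at all ("separable":
# four well-separated morphology prototypes) and that the timing pathway
# carries class information the morphology cannot ("timing_only": N and
# APC share one morphology prototype and differ only in the premature
# beat pattern of the timing vector).

#' Build a toy beat dataset
#'
#' @param n Total number of samples. For `"separable"` classes are
#'   balanced; for `"timing_only"` the N class is twice as frequent as
#'   each other class (so a morphology-only classifier resolves the
#'   N/APC ambiguity in favour of N).
#' @param type `"separable"` or `"timing_only"`.
#' @param window Morphology window length (default 100).
#' @param timing_length Timing vector length (default 200).
#' @param noise_sd Morphology noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @return A `beat_dataset`.
#' @export
toy_beat_dataset <- function(n = 200L, type = c("separable", "timing_only"),
                             window = 100L, timing_length = 200L,
                             noise_sd = 0.05, seed = 1L) {
  type <- match.arg(type)
  .with_seed(seed, {
    if (type == "separable") {
      labels <- rep(.beat_classes, length.out = n)
    } else {
      weights <- c(N = 2, APC = 1, VPC = 1, A = 1)
      labels <- rep(rep(.beat_classes, times = weights),
                    length.out = n)
    }
    labels <- sample(labels)
    x <- seq_len(window)
    proto <- list(
      N = exp(-((x - 0.30 * window)^2) / (2 * (0.05 * window)^2)),
      APC = -exp(-((x - 0.70 * window)^2) / (2 * (0.05 * window)^2)),
      VPC = exp(-((x - 0.50 * window)^2) / (2 * (0.15 * window)^2)),
      A = 0.8 * sin(x * 1.3) * exp(-((x - 0.5 * window)^2) /
                                     (2 * (0.2 * window)^2)))
    if (type == "timing_only") proto$APC <- proto$N

    morph <- array(0, c(n, 2L, window))
    timing <- matrix(0L, n, timing_length)
    center <- timing_length %/% 2L + 1L
    comb_step <- 20L
    for (i in seq_len(n)) {
      base <- proto[[labels[i]]] + stats::rnorm(window, sd = noise_sd)
      morph[i, 1L, ] <- 0.8 * base
      morph[i, 2L, ] <- base
      if (type == "separable") {
        on <- stats::runif(timing_length) < 0.05
        timing[i, on] <- 1L
      } else {
        # regular comb of beats; for APC the beat preceding the center is
        # replaced by a premature one at half the normal interval
        pos <- center + seq(-4L, 4L) * comb_step
        if (labels[i] == "APC") {
          pos[4L] <- center - comb_step %/% 2L
        }
        pos <- pos[pos >= 1L & pos <= timing_length]
        timing[i, pos] <- 1L
      }
      timing[i, center] <- 1L
    }
    structure(list(morphology = morph, timing = timing,
                   labels = factor(labels, levels = .beat_classes),
                   beat_index = seq_len(n),
                   source_record = rep("toy", n)),
              class = "beat_dataset")
  })
}

#' Compact network configuration for the toy problems
#'
#' @param use_timing_path Include the timing branch.
#' @param window,timing_length Input sizes matching [toy_beat_dataset()].
#' @return A [network_config()].
#' @export
toy_network_config <- function(use_timing_path = TRUE, window = 100L,
                               timing_length = 200L) {
  network_config(
    morph_path1 = list(conv_block(4, 5, 8), conv_block(2, 5, 8)),
    morph_path2 = list(conv_block(2, 8, 4), conv_block(4, 4, 8)),
    timing_path = list(conv_block(8, 10, 8), conv_block(4, 5, 4)),
    dense_units = 32L, final_dense_units = 16L,
    dropout = 0.1, l2_lambda = 1e-4,
    use_timing_path = use_timing_path,
    morph_window = window, timing_length = timing_length)
}
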