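# Parametric two-lead ECG simulator.
#
# Beats are synthesized analytically as sums of Gaussian deflections
# (P, Q, R, S, T), which keeps the ground truth fully parametric: every
# generated record carries the exact sample index and class of every beat,
# so the detector and the classifier can be scored without any external
# recording. Equine-style templates have a dominant negative S deflection
# (and a prominent T wave, as recorded with the base-apex configuration);
# human-style templates have a dominant positive R.

.sim_fs <- 500

#' Beat morphology template
#'
#' Describes the shape of a single P-QRS-T complex as a sum of Gaussian
#' deflections, sampled at 500 Hz. The equine style has a deep negative S
#' wave as its dominant deflection and a large T wave; the human style has a
#' tall positive R.
#'
#' @param species_style `"equine"` or `"human"`.
#' @param qrs_width QRS duration in seconds (default 0.10 equine, 0.08
#'   human).
#' @param t_amplitude T-wave amplitude in mV; defaults to 0.50 (equine) or
#'   0.30 (human). Raising it produces the tall-T records on which
#'   amplitude-based detectors mistake T waves for QRS complexes.
#' @return A `beat_template` with the component table, the sampled
#'   `waveform` (mV at 500 Hz spanning the P-QRS-T complex), `dominant_peak`
#'   (`"S"` or `"R"`) and `qrs_width`.
#' @export
beat_template <- function(species_style = c("equine", "human"),
                          qrs_width = NULL, t_amplitude = NULL) {
  species_style <- match.arg(species_style)
  if (species_style == "equine") {
    if (is.null(qrs_width)) qrs_width <- 0.10
    if (is.null(t_amplitude)) t_amplitude <- 0.50
    comp <- data.frame(
      wave   = c("P", "R", "S", "T"),
      amp    = c(0.15, 0.25, -1.50, t_amplitude),
      center = c(-0.24, -0.030, 0.000, 0.30),
      sigma  = c(0.030, 0.009, 0.012, 0.035),
      qrs    = c(FALSE, TRUE, TRUE, FALSE))
    dominant <- "S"
  } else {
    if (is.null(qrs_width)) qrs_width <- 0.08
    if (is.null(t_amplitude)) t_amplitude <- 0.30
    comp <- data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      amp    = c(0.12, -0.10, 1.40, -0.25, t_amplitude),
      center = c(-0.16, -0.022, 0.000, 0.022, 0.22),
      sigma  = c(0.022, 0.006, 0.009, 0.007, 0.050),
      qrs    = c(FALSE, TRUE, TRUE, TRUE, FALSE))
    dominant <- "R"
  }
  # scale QRS component widths with the requested QRS duration
  ref <- if (species_style == "equine") 0.10 else 0.08
  comp$sigma[comp$qrs] <- comp$sigma[comp$qrs] * (qrs_width / ref)
  comp$center[comp$qrs] <- comp$center[comp$qrs] * (qrs_width / ref)
  tpl <- structure(list(species_style = species_style, components = comp,
                        qrs_width = qrs_width, dominant_peak = dominant,
                        fs = .sim_fs),
                   class = "beat_template")
  wf <- .render_beat(tpl, "N")
  tpl$waveform <- wf$y
  tpl
}

# Render one beat of class `cls` from a template. Returns amplitude samples
# `y` on the offset grid `offsets` (samples relative to the dominant peak).
# VPC beats have a widened (1.6x) QRS with inverted dominant deflection and
# no P wave; APC morphology is identical to N (the class is defined by its
# premature timing alone).
.render_beat <- function(template, cls) {
  comp <- template$components
  if (cls == "VPC") {
    comp <- comp[comp$wave != "P", ]
    widen <- comp$qrs
    comp$sigma[widen] <- comp$sigma[widen] * 1.6
    comp$center[widen] <- comp$center[widen] * 1.6
    dom <- comp$wave == template$dominant_peak
    comp$amp[dom] <- -comp$amp[dom]
    # ventricular repolarization is discordant: flip the T too
    comp$amp[comp$wave == "T"] <- -0.7 * comp$amp[comp$wave == "T"]
  }
  fs <- template$fs
  lo <- floor(min(comp$center - 4 * comp$sigma) * fs)
  hi <- ceiling(max(comp$center + 4 * comp$sigma) * fs)
  offsets <- lo:hi
  t <- offsets / fs
  y <- numeric(length(t))
  for (i in seq_len(nrow(comp))) {
    y <- y + comp$amp[i] * exp(-((t - comp$center[i])^2) /
                                 (2 * comp$sigma[i]^2))
  }
  list(y = y, offsets = offsets)
}

#' Rhythm specification for the simulator
#'
#' @param base_heart_rate Mean heart rate in bpm; must lie in \[20, 240\]
#'   (horses reach about 240 bpm at peak exercise).
#' @param duration Record duration in seconds.
#' @param rr_jitter Fractional beat-to-beat RR variation (uniform, +/- this
#'   fraction of the mean RR).
#' @param apc_rate,vpc_rate,artefact_rate Expected event counts per minute;
#'   realized counts are Poisson draws under the record seed.
#' @param apc_prematurity,vpc_prematurity Fraction of the mean RR by which a
#'   premature beat arrives early, in (0, 1).
#' @param seed Integer seed; identical specs with identical seeds produce
#'   bit-identical records.
#' @return A `rhythm_spec` list.
#' @export
rhythm_spec <- function(base_heart_rate, duration, rr_jitter = 0.03,
                        apc_rate = 0, vpc_rate = 0, artefact_rate = 0,
                        apc_prematurity = 0.25, vpc_prematurity = 0.30,
                        seed = 1L) {
  if (base_heart_rate < 20 || base_heart_rate > 240) {
    stop("base_heart_rate must lie in [20, 240] bpm")
  }
  if (duration <= 0) stop("duration must be positive")
  if (rr_jitter < 0 || rr_jitter >= 0.5) stop("rr_jitter must be in [0, 0.5)")
  for (q in c(apc_prematurity, vpc_prematurity)) {
    if (q <= 0 || q >= 1) stop("prematurity fractions must be in (0, 1)")
  }
  if (min(apc_rate, vpc_rate, artefact_rate) < 0) {
    stop("event rates must be non-negative")
  }
  structure(list(base_heart_rate = base_heart_rate, duration = duration,
                 rr_jitter = rr_jitter, apc_rate = apc_rate,
                 vpc_rate = vpc_rate, artefact_rate = artefact_rate,
                 apc_prematurity = apc_prematurity,
                 vpc_prematurity = vpc_prematurity,
                 seed = as.integer(seed)),
            class = "rhythm_spec")
}

#' Noise specification for the simulator
#'
#' @param baseline_wander_amplitude Amplitude (mV) of the sub-1 Hz baseline
#'   drift emulating movement and breathing.
#' @param baseline_wander_freq Fundamental wander frequency in Hz (< 1).
#' @param white_noise_sd Standard deviation (mV) of additive white noise.
#' @param powerline_freq Optional mains frequency (Hz) for a 0.02 mV
#'   powerline tone, or `NULL`.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(baseline_wander_amplitude = 0,
                       baseline_wander_freq = 0.33,
                       white_noise_sd = 0, powerline_freq = NULL) {
  if (baseline_wander_freq >= 1) {
    stop("baseline_wander_freq must be below 1 Hz")
  }
  if (baseline_wander_amplitude < 0 || white_noise_sd < 0) {
    stop("noise amplitudes must be non-negative")
  }
  structure(list(baseline_wander_amplitude = baseline_wander_amplitude,
                 baseline_wander_freq = baseline_wander_freq,
                 white_noise_sd = white_noise_sd,
                 powerline_freq = powerline_freq),
            class = "noise_spec")
}

#' Named noise presets
#'
#' `"clean"`: no noise. `"clinic"`: mild wander (0.15 mV at 0.33 Hz) and
#' 0.02 mV white noise, typical of a resting recording in a stable.
#' `"exercise"`: strong wander (0.40 mV at 0.6 Hz) and 0.05 mV white noise.
#'
#' @param preset Preset name.
#' @return A [noise_spec()].
#' @export
noise_preset <- function(preset = c("clean", "clinic", "exercise")) {
  switch(match.arg(preset),
         clean = noise_spec(0, 0.33, 0),
         clinic = noise_spec(0.15, 0.33, 0.02),
         exercise = noise_spec(0.40, 0.60, 0.05))
}

#' Generate a synthetic two-lead ECG record
#'
#' Places beats by a jittered renewal process at the requested heart rate,
#' injects premature atrial (APC) and ventricular (VPC) beats and
#' high-frequency artefact bursts at Poisson-drawn counts, renders each beat
#' from the template, and adds baseline wander and white noise. A VPC is
#' followed by a full compensatory pause. Lead II carries the template
#' morphology; lead I is a scaled (0.6x) projection of the same activity.
#'
#' @param template A [beat_template()].
#' @param rhythm A [rhythm_spec()].
#' @param noise A [noise_spec()] (default: clean).
#' @return An [ecg_record()] at 500 Hz with two leads (`I`, `II`) and one
#'   annotation per placed beat/artefact, indexed at the dominant-peak
#'   sample (burst center for artefacts).
#' @export
generate_record <- function(template, rhythm, noise = noise_preset("clean")) {
  stopifnot(inherits(template, "beat_template"),
            inherits(rhythm, "rhythm_spec"),
            inherits(noise, "noise_spec"))
  fs <- .sim_fs
  .with_seed(rhythm$seed, {
    rr_mean <- 60 / rhythm$base_heart_rate
    dur <- rhythm$duration
    # trailing margin so a complete beat (through its T wave) fits
    margin <- 0.50
    if (dur < rr_mean / 2 + margin) {
      stop("duration too short to hold a single complete beat")
    }
    n_slots <- ceiling(dur / rr_mean) + 8L
    rr <- rr_mean * (1 + rhythm$rr_jitter * stats::runif(n_slots, -1, 1))

    classes <- rep("N", n_slots)
    n_apc <- stats::rpois(1L, rhythm$apc_rate * dur / 60)
    n_vpc <- stats::rpois(1L, rhythm$vpc_rate * dur / 60)
    eligible <- 3:(n_slots - 2L)
    want <- n_apc + n_vpc
    if (want > 0 && length(eligible)) {
      # premature beats need a normal predecessor and successor slot:
      # enforce a 2-slot spacing between chosen event slots
      picked <- integer(0)
      pool <- eligible
      draws <- pool[sample.int(length(pool))]
      for (s in draws) {
        if (length(picked) >= want) break
        if (all(abs(picked - s) > 2L)) picked <- c(picked, s)
      }
      picked <- picked[sample.int(length(picked))]  # shuffle before assigning
      apc_slots <- utils::head(picked, min(n_apc, length(picked)))
      vpc_slots <- utils::tail(picked, max(0L, length(picked) - n_apc))
      classes[apc_slots] <- "APC"
      classes[vpc_slots] <- "VPC"
    }

    for (s in which(classes != "N")) {
      q <- if (classes[s] == "APC") rhythm$apc_prematurity
           else rhythm$vpc_prematurity
      rr[s - 1L] <- (1 - q) * rr_mean * stats::runif(1, 0.85, 0.95)
      if (classes[s] == "VPC") rr[s] <- 2 * rr_mean - rr[s - 1L]
    }

    t_beat <- rr_mean / 2 + c(0, cumsum(rr[-n_slots]))
    keep <- t_beat <= dur - margin & t_beat >= 0.4
    t_beat <- t_beat[keep]
    classes <- classes[keep]
    if (!length(t_beat)) stop("duration too short to hold a single beat")

    n <- round(dur * fs)
    sig2 <- numeric(n)
    peak_idx <- integer(length(t_beat))
    for (i in seq_along(t_beat)) {
      p <- round(t_beat[i] * fs) + 1L
      peak_idx[i] <- p
      wf <- .render_beat(template, classes[i])
      pos <- p + wf$offsets
      ok <- pos >= 1L & pos <= n
      sig2[pos[ok]] <- sig2[pos[ok]] + wf$y[ok]
    }

    ann <- data.frame(sample = peak_idx, label = classes,
                      stringsAsFactors = FALSE)

    # artefact bursts: high-amplitude high-frequency transients not aligned
    # to the rhythm
    n_art <- stats::rpois(1L, rhythm$artefact_rate * dur / 60)
    art_idx <- integer(0)
    if (n_art > 0) {
      tries <- 0L
      while (length(art_idx) < n_art && tries < 200L * n_art) {
        tries <- tries + 1L
        cand <- round(stats::runif(1, 0.5, dur - 0.5) * fs) + 1L
        if (all(abs(cand - peak_idx) > 0.25 * fs) &&
            (!length(art_idx) || all(abs(cand - art_idx) > 0.30 * fs))) {
          art_idx <- c(art_idx, cand)
        }
      }
      art_idx <- sort(art_idx)
      n_art <- length(art_idx)   # rejection sampling may place fewer
      for (p in art_idx) {
        off <- seq(-round(0.06 * fs), round(0.06 * fs))
        tt <- off / fs
        burst <- 1.8 * exp(-tt^2 / (2 * 0.02^2)) *
          sin(2 * pi * 45 * tt + stats::runif(1, 0, 2 * pi))
        pos <- p + off
        ok <- pos >= 1L & pos <= n
        sig2[pos[ok]] <- sig2[pos[ok]] + burst[ok]
      }
      if (n_art > 0L) {
        ann <- rbind(ann, data.frame(sample = art_idx, label = "A",
                                     stringsAsFactors = FALSE))
        ann <- ann[order(ann$sample), ]
      }
    }

    sig1 <- 0.6 * sig2
    tt <- (seq_len(n) - 1L) / fs
    if (noise$baseline_wander_amplitude > 0) {
      a <- noise$baseline_wander_amplitude
      f <- noise$baseline_wander_freq
      wander <- a * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) +
        0.4 * a * sin(2 * pi * 0.5 * f * tt + stats::runif(1, 0, 2 * pi))
      sig1 <- sig1 + wander
      sig2 <- sig2 + wander
    }
    if (noise$white_noise_sd > 0) {
      sig1 <- sig1 + stats::rnorm(n, sd = noise$white_noise_sd)
      sig2 <- sig2 + stats::rnorm(n, sd = noise$white_noise_sd)
    }
    if (!is.null(noise$powerline_freq)) {
      pl <- 0.02 * sin(2 * pi * noise$powerline_freq * tt)
      sig1 <- sig1 + pl
      sig2 <- sig2 + pl
    }

    ecg_record(cbind(sig1, sig2), fs = fs, annotations = ann,
               leads = c("I", "II"))
  })
}

#' Ground-truth beat list of a generated record
#'
#' @param record An [ecg_record()].
#' @return Data frame with columns `sample` and `label` -- the reference
#'   beats used for detector scoring and training labels.
#' @export
ideal_annotations <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  record$annotations
}
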