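# The `ecg_record` container used throughout the pipeline.

.beat_classes <- c("N", "APC", "VPC", "A")

#' Construct an ECG record
#'
#' An `ecg_record` bundles a multi-lead sampled signal with its sample rate
#' and (optionally) ground-truth beat annotations. It is the common currency
#' of the simulator, the WFDB reader, the filters and the detector.
#'
#' @param signal Numeric matrix, `samples x leads`, amplitudes in mV.
#' @param fs Sample rate in Hz.
#' @param annotations Data frame with columns `sample` (1-based sample
#'   index) and `label` (one of `"N"`, `"APC"`, `"VPC"`, `"A"`), or `NULL`.
#' @param leads Character vector of lead labels, one per signal column.
#'
#' @return An object of class `ecg_record` with elements `signal`, `fs`,
#'   `leads` and `annotations`.
#' @export
ecg_record <- function(signal, fs, annotations = NULL,
                       leads = paste0("lead", seq_len(ncol(signal)))) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (ncol(signal) < 1L) stop("an ecg_record needs at least one lead")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (length(leads) != ncol(signal)) {
    stop("length(leads) must equal ncol(signal)")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(sample = integer(0),
                              label = character(0),
                              stringsAsFactors = FALSE)
  }
  annotations <- as.data.frame(annotations)
  if (!all(c("sample", "label") %in% names(annotations))) {
    stop("annotations must have columns 'sample' and 'label'")
  }
  annotations$sample <- as.integer(annotations$sample)
  annotations$label <- as.character(annotations$label)
  if (nrow(annotations)) {
    if (any(annotations$sample < 1L | annotations$sample > nrow(signal))) {
      stop("annotation sample indices must lie within the signal")
    }
    if (any(diff(annotations$sample) <= 0L)) {
      stop("annotation sample indices must be strictly increasing")
    }
    bad <- setdiff(unique(annotations$label), .beat_classes)
    if (length(bad)) {
      stop("unknown beat class label(s): ", paste(bad, collapse = ", "))
    }
  }
  colnames(signal) <- leads
  structure(list(signal = signal, fs = fs, leads = leads,
                 annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- nrow(x$signal) / x$fs
  cat(sprintf("<ecg_record> %d leads (%s), %d samples @ %g Hz (%.1f s)\n",
              length(x$leads), paste(x$leads, collapse = ", "),
              nrow(x$signal), x$fs, dur))
  if (nrow(x$annotations)) {
    tab <- table(factor(x$annotations$label, levels = .beat_classes))
    cat("  annotations:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = " "), "\n")
  } else {
    cat("  annotations: none\n")
  }
  invisible(x)
}

#' Number of samples in a record
#' @param record An `ecg_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(record) nrow(record$signal)

#' Extract one lead of a record as a numeric vector
#' @param record An `ecg_record`.
#' @param lead Lead label or column index.
#' @return Numeric vector of amplitudes (mV).
#' @export
record_lead <- function(record, lead) {
  if (is.character(lead)) {
    j <- match(lead, record$leads)
    if (is.na(j)) stop("record has no lead '", lead, "'")
  } else {
    j <- as.integer(lead)
  }
  record$signal[, j]
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}
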