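# Classification metrics: confusion matrix, per-class one-vs-rest
# accuracy/recall/PPV/F1, macro aggregation and report averaging.

#' Confusion matrix over the four beat classes
#'
#' @param true_labels,predicted_labels Vectors of labels in
#'   `{N, APC, VPC, A}` (factors or characters), equal length.
#' @return A 4x4 integer matrix, rows = true class, columns = predicted
#'   class, in class order N, APC, VPC, A.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length")
  }
  tl <- as.character(true_labels)
  pl <- as.character(predicted_labels)
  bad <- setdiff(unique(c(tl, pl)), .beat_classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tf <- factor(tl, levels = .beat_classes)
  pf <- factor(pl, levels = .beat_classes)
  m <- table(tf, pf)
  cm <- matrix(as.integer(m), 4L, 4L,
               dimnames = list(true = .beat_classes,
                               predicted = .beat_classes))
  cm
}

#' Per-class and aggregate metrics from a confusion matrix
#'
#' For each class c (one-vs-rest): TP is the diagonal entry, FP the rest
#' of its column, FN the rest of its row, TN the remainder; recall =
#' TP/(TP+FN), PPV = TP/(TP+FP), F1 their harmonic mean, each in percent.
#' Overall accuracy is the trace over the total. Macro averages are
#' unweighted class means; classes with no true instances have undefined
#' recall and are excluded from the macro averages.
#'
#' @param cm 4x4 confusion matrix from [confusion()].
#' @return An `eval_report`: `per_class` data frame (class, recall, ppv,
#'   f1, in %), `accuracy` (%), `macro_recall`, `macro_ppv`, `macro_f1`,
#'   `confusion`, `n_models_averaged`.
#' @export
compute_metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  per <- data.frame(class = classes, recall = NA_real_, ppv = NA_real_,
                    f1 = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(classes)) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(rec) && !is.na(ppv) && rec + ppv > 0) {
      2 * rec * ppv / (rec + ppv)
    } else NA_real_
    per$recall[k] <- rec
    per$ppv[k] <- ppv
    per$f1[k] <- f1
  }
  structure(list(per_class = per,
                 accuracy = 100 * sum(diag(cm)) / total,
                 macro_recall = mean(per$recall, na.rm = TRUE),
                 macro_ppv = mean(per$ppv, na.rm = TRUE),
                 macro_f1 = mean(per$f1, na.rm = TRUE),
                 confusion = cm,
                 n_models_averaged = 1L),
            class = "eval_report")
}

#' Average several evaluation reports
#'
#' Element-wise arithmetic mean of all metric fields (the confusion
#' matrices are summed), as used when the same network is trained several
#' times with identical initial parameters and the metrics averaged.
#'
#' @param reports List of `eval_report`s with the same class structure.
#' @return The averaged `eval_report` with `n_models_averaged` set.
#' @export
average_reports <- function(reports) {
  if (!length(reports)) stop("average_reports needs at least one report")
  out <- reports[[1L]]
  if (length(reports) == 1L) return(out)
  fields <- c("recall", "ppv", "f1")
  for (f in fields) {
    out$per_class[[f]] <- rowMeans(
      vapply(reports, function(r) r$per_class[[f]], numeric(4L)))
  }
  for (f in c("accuracy", "macro_recall", "macro_ppv", "macro_f1")) {
    out[[f]] <- mean(vapply(reports, `[[`, numeric(1L), f))
  }
  out$confusion <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  out$n_models_averaged <- length(reports)
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.1f%% (n_models=%d)\n",
              x$accuracy, x$n_models_averaged))
  p <- x$per_class
  for (k in seq_len(nrow(p))) {
    cat(sprintf("  %-4s recall %5.1f  PPV %5.1f  F1 %5.1f\n", p$class[k],
                p$recall[k], p$ppv[k], p$f1[k]))
  }
  cat(sprintf("  macro: recall %.1f  PPV %.1f  F1 %.1f\n",
              x$macro_recall, x$macro_ppv, x$macro_f1))
  invisible(x)
}
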