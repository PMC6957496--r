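classes <- c("N", "APC", "VPC", "A")

test_that("confusion matrices tally label pairs", {
  truth <- c("N", "N", "APC", "VPC", "A", "N", "VPC", "APC", "N", "A",
             "VPC", "N")
  pred <- c("N", "APC", "APC", "VPC", "A", "N", "N", "APC", "N", "VPC",
            "VPC", "N")
  cm <- confusion(truth, pred)
  manual <- matrix(0L, 4, 4, dimnames = list(true = classes,
                                             predicted = classes))
  for (i in seq_along(truth)) {
    manual[truth[i], pred[i]] <- manual[truth[i], pred[i]] + 1L
  }
  expect_identical(cm, manual)
  expect_equal(sum(cm), length(truth))

  perfect <- confusion(truth, truth)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  empty <- confusion(character(0), character(0))
  expect_true(all(empty == 0L))
  expect_error(confusion("N", c("N", "APC")), "equal length")
  expect_error(confusion("N", "X"), "unknown label")
})

test_that("metrics follow the one-vs-rest definitions", {
  cm <- diag(c(5L, 3L, 2L, 1L))
  dimnames(cm) <- list(true = classes, predicted = classes)
  rep <- compute_metrics(cm)
  expect_equal(rep$accuracy, 100)
  expect_true(all(rep$per_class$recall == 100))
  expect_true(all(rep$per_class$f1 == 100))

  # class N with TP=8, FN=2, FP=1 (one-vs-rest)
  cm2 <- matrix(0L, 4, 4, dimnames = list(true = classes,
                                          predicted = classes))
  cm2[1, 1] <- 8L; cm2[1, 2] <- 2L; cm2[2, 1] <- 1L; cm2[3, 3] <- 20L
  r2 <- compute_metrics(cm2)
  expect_equal(r2$per_class$recall[1], 80)
  expect_equal(round(r2$per_class$ppv[1], 1), 88.9)
  expect_equal(round(r2$per_class$f1[1], 1), 84.2)
  expect_error(compute_metrics(matrix(0L, 4, 4,
                                      dimnames = list(classes, classes))),
               "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(77)
  for (i in 1:200) {
    cm <- matrix(rpois(16L, 6L), 4, 4,
                 dimnames = list(true = classes, predicted = classes))
    if (sum(cm) == 0) next
    rep <- compute_metrics(cm)
    # micro-averaged recall equals overall accuracy
    tp <- diag(cm)
    micro_recall <- 100 * sum(tp) / sum(cm)
    expect_equal(micro_recall, rep$accuracy, tolerance = 1e-12)
    # per class: TP + FP + FN + TN = total; F1 is the harmonic mean
    for (k in 1:4) {
      fp <- sum(cm[, k]) - cm[k, k]
      fn <- sum(cm[k, ]) - cm[k, k]
      tn <- sum(cm) - cm[k, k] - fp - fn
      expect_equal(cm[k, k] + fp + fn + tn, sum(cm))
      r <- rep$per_class$recall[k]
      p <- rep$per_class$ppv[k]
      if (!is.na(r) && !is.na(p) && r + p > 0) {
        expect_equal(rep$per_class$f1[k], 2 / (1 / r + 1 / p),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("metrics agree with a per-beat recount", {
  set.seed(21)
  for (i in 1:20) {
    n <- 60
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    rep <- compute_metrics(confusion(truth, pred))
    expect_equal(rep$accuracy, 100 * mean(truth == pred))
    for (k in classes) {
      tp <- sum(truth == k & pred == k)
      if (sum(truth == k) > 0) {
        expect_equal(rep$per_class$recall[match(k, classes)],
                     100 * tp / sum(truth == k))
      }
    }
  }
})

test_that("report averaging is the element-wise mean", {
  mk <- function(acc) {
    cm <- diag(c(8L, 8L, 8L, 8L))
    dimnames(cm) <- list(true = classes, predicted = classes)
    rep <- compute_metrics(cm)
    rep$accuracy <- acc
    rep
  }
  reps <- list(mk(90), mk(92), mk(94))
  avg <- average_reports(reps)
  expect_equal(avg$accuracy, 92)
  expect_equal(avg$n_models_averaged, 3L)
  one <- average_reports(list(mk(88)))
  expect_equal(one$accuracy, 88)
  same <- average_reports(list(mk(90), mk(90), mk(90)))
  expect_equal(same$accuracy, 90)
  expect_error(average_reports(list()), "at least one")
})
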