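tiny_config <- function(dropout = 0, use_timing = TRUE) {
  network_config(
    morph_path1 = list(conv_block(2, 2, 3), conv_block(2, 3, 4)),
    morph_path2 = list(conv_block(4, 2, 2), conv_block(1, 2, 3)),
    timing_path = list(conv_block(4, 3, 3), conv_block(2, 2, 2)),
    dense_units = 8L, final_dense_units = 5L, dropout = dropout,
    l2_lambda = 0.001, use_timing_path = use_timing,
    morph_window = 20L, timing_length = 40L)
}

tiny_inputs <- function(n = 4L) {
  set.seed(1)
  list(Xm = array(rnorm(n * 2 * 20), c(n, 2, 20)),
       Xt = matrix(as.double(rbinom(n * 40, 1, 0.2)), n, 40),
       y = rep_len(1:4, n))
}

test_that("the optimized architectures build with deterministic sizes", {
  m_eecg <- build_network(network_config_eecg(), seed = 1)
  m_mit <- build_network(network_config_mitbih(), seed = 1)
  expect_gt(n_parameters(m_eecg), 0)
  expect_equal(n_parameters(m_eecg),
               n_parameters(build_network(network_config_eecg(), seed = 9)))
  expect_gt(n_parameters(m_mit), 0)
  # ablation variant is a strict sub-network
  m_abl <- build_network(network_config_eecg(use_timing_path = FALSE),
                         seed = 1)
  expect_lt(n_parameters(m_abl), n_parameters(m_eecg))
})

test_that("forward passes produce probability distributions over 4 classes", {
  model <- build_network(network_config_eecg(), seed = 2)
  n <- 3L
  set.seed(5)
  Xm <- array(rnorm(n * 2 * 500), c(n, 2, 500))
  Xt <- matrix(as.double(rbinom(n * 2000, 1, 0.02)), n, 2000)
  fw <- .net_forward(model, Xm, Xt, training = FALSE)
  expect_equal(dim(fw$probs), c(n, 4L))
  expect_equal(rowSums(fw$probs), rep(1, n), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config(dropout = 0)
  model <- build_network(cfg, seed = 3)
  ti <- tiny_inputs()
  onehot <- diag(4)[ti$y, , drop = FALSE]
  loss_fn <- function(m) {
    fw <- .net_forward(m, ti$Xm, ti$Xt, training = TRUE)
    l <- .ce_loss(fw$probs, ti$y)
    for (nm in grep("_W$", names(m$params), value = TRUE)) {
      l <- l + cfg$l2_lambda * sum(m$params[[nm]]^2)
    }
    l
  }
  fw <- .net_forward(model, ti$Xm, ti$Xt, training = TRUE)
  grads <- .net_backward(model, fw, onehot)
  eps <- 1e-5
  set.seed(8)
  for (nm in c("m1_conv1_W", "m1_bn2_gamma", "m2_conv2_W", "m2_short_W",
               "t_conv1_W", "morph_dense_W", "timing_dense_W", "final_W",
               "out_b")) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3L, length(p)))) {
      up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      numeric_grad <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(grads[[nm]][i], numeric_grad, tolerance = 1e-5)
    }
  }
})

test_that("inference is deterministic and zero learning rate is a no-op", {
  model <- build_network(tiny_config(dropout = 0.3), seed = 4)
  ds <- toy_beat_dataset(12, "separable", window = 20L,
                         timing_length = 40L, seed = 2)
  p1 <- predict_beats(model, ds)
  p2 <- predict_beats(model, ds)
  expect_identical(p1$probs, p2$probs)
  expect_equal(rowSums(p1$probs), rep(1, 12), tolerance = 1e-9)

  frozen <- train_network(model, ds,
                          cfg = train_config(learning_rate = 0,
                                             batch_size = 6L,
                                             epochs = 1L, seed = 1))
  expect_identical(frozen$params, model$params)
})

test_that("training reduces the loss on a learnable toy problem", {
  ds <- toy_beat_dataset(80, "separable", window = 20L,
                         timing_length = 40L, noise_sd = 0.05, seed = 3)
  model <- build_network(tiny_config(dropout = 0.1), seed = 5)
  model <- train_network(model, ds,
                         cfg = train_config(learning_rate = 2e-3,
                                            batch_size = 16L,
                                            epochs = 8L, seed = 5))
  h <- model$history
  expect_lt(h$loss[nrow(h)], h$loss[1L])
  expect_gt(h$train_acc[nrow(h)], 60)
})

test_that("freeze-mode transfer leaves feature extractor bytes untouched", {
  ds <- toy_beat_dataset(40, "separable", window = 20L,
                         timing_length = 40L, seed = 6)
  src <- train_network(build_network(tiny_config(0.1), seed = 6), ds,
                       cfg = train_config(learning_rate = 1e-3,
                                          batch_size = 16L, epochs = 3L,
                                          seed = 6))
  feat <- .feature_param_names(src$params)
  before <- serialize(src$params[feat], NULL)
  bn_before <- serialize(src$bn_state, NULL)
  ft <- transfer(src, ds, mode = "freeze_features",
                 cfg = train_config(learning_rate = 1e-3,
                                    batch_size = 16L, epochs = 3L,
                                    seed = 7))
  expect_identical(serialize(ft$params[feat], NULL), before)
  expect_identical(serialize(ft$bn_state, NULL), bn_before)
  expect_false(identical(ft$params$final_W, src$params$final_W))

  # full fine-tuning with zero epochs returns the source model unchanged
  f0 <- transfer(src, ds, mode = "full_finetune",
                 cfg = train_config(epochs = 0L, seed = 1))
  expect_identical(f0$params, src$params)
})

test_that("transfer initialization does not hurt a related target task", {
  src_ds <- toy_beat_dataset(80, "separable", window = 20L,
                             timing_length = 40L, noise_sd = 0.03,
                             seed = 8)
  tgt_ds <- toy_beat_dataset(80, "separable", window = 20L,
                             timing_length = 40L, noise_sd = 0.10,
                             seed = 9)
  tc <- train_config(learning_rate = 2e-3, batch_size = 16L, epochs = 6L,
                     seed = 3)
  src <- train_network(build_network(tiny_config(0.1), seed = 3), src_ds,
                       cfg = tc)
  fine <- transfer(src, tgt_ds, mode = "full_finetune", cfg = tc)
  cold <- train_network(build_network(tiny_config(0.1), seed = 3), tgt_ds,
                        cfg = tc)
  acc <- function(m) {
    pred <- predict_beats(m, tgt_ds)
    100 * mean(as.character(pred$labels) == as.character(tgt_ds$labels))
  }
  expect_gte(acc(fine), acc(cold) - 5)
})

test_that("ensembles vote by majority with mean-probability tie-breaks", {
  ds <- toy_beat_dataset(10, "separable", window = 20L,
                         timing_length = 40L, seed = 10)
  base <- build_network(tiny_config(0), seed = 11)
  # constant-output models: zero all weights, steer with the output bias
  constant_model <- function(bias) {
    m <- base
    for (nm in names(m$params)) m$params[[nm]][] <- 0
    m$params$out_b <- bias
    m
  }
  n_model <- constant_model(c(2, 0, 0, 0))     # votes N, confident
  v_model <- constant_model(c(0, 0, 1, 0))     # votes VPC, less confident
  same <- ensemble_predict(list(n_model, n_model, n_model,
                                n_model, n_model), ds)
  expect_true(all(same == "N"))
  majority <- ensemble_predict(list(n_model, n_model, v_model), ds)
  expect_true(all(majority == "N"))
  # 1-1 tie: N's mean softmax is higher, so N wins
  tie <- ensemble_predict(list(n_model, v_model), ds)
  expect_true(all(tie == "N"))
  expect_error(ensemble_predict(list(), ds), "at least one")
})

test_that("a class missing from training triggers a warning", {
  ds <- toy_beat_dataset(30, "separable", window = 20L,
                         timing_length = 40L, seed = 12)
  keep <- which(ds$labels != "A")
  ds3 <- equibeat:::.dataset_subset(ds, keep)
  expect_warning(
    train_network(build_network(tiny_config(0), seed = 1), ds3,
                  cfg = train_config(learning_rate = 1e-3,
                                     batch_size = 16L, epochs = 1L,
                                     seed = 1)),
    "absent")
})

test_that("model checkpoints round-trip", {
  model <- build_network(tiny_config(0), seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
})
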