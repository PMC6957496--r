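# The parallel morphology + timing beat classifier.
#
# Two parallel convolutional paths with different kernel geometries ingest
# the same 2 x W two-lead morphology window (weights shared across leads;
# no cross-lead mixing before flattening). Each path is
# [conv -> batch-norm -> ReLU -> dropout] x 2 with a residual shortcut
# that max-pools the path input by the combined stride and is added (after
# a 1x1 channel-matching convolution) before flattening. A third path of
# two plain 1-D convolutions (dropout only) ingests the binary beat-timing
# vector. Each branch feeds its own dense layer; their concatenation feeds
# a final dense layer and a 4-class softmax. The timing branch can be
# ablated (`use_timing_path = FALSE`).

#' Convolutional block hyperparameters
#'
#' Kernel size is `2 * convolution_width` samples; `subsampling` is the
#' convolution stride.
#'
#' @param subsampling Stride factor (>= 1).
#' @param convolution_width Kernel half-size basis (>= 1).
#' @param filters Number of filters (>= 1).
#' @return A `conv_block` list.
#' @export
conv_block <- function(subsampling, convolution_width, filters) {
  v <- c(subsampling, convolution_width, filters)
  if (any(v < 1)) stop("conv_block parameters must all be >= 1")
  structure(list(subsampling = as.integer(subsampling),
                 convolution_width = as.integer(convolution_width),
                 filters = as.integer(filters)),
            class = "conv_block")
}

#' Network architecture configuration
#'
#' Defaults are the genetic-algorithm-optimized equine architecture; see
#' [network_config_mitbih()] for the human-ECG counterpart.
#'
#' @param morph_path1,morph_path2 Lists of two [conv_block()]s for the two
#'   parallel morphology paths.
#' @param timing_path List of two [conv_block()]s for the timing path.
#' @param dense_units Units in each per-pathway dense layer (default 512).
#' @param final_dense_units Units in the final shared dense layer
#'   (default 32).
#' @param dropout Dropout fraction in [0, 1) (default 0.2).
#' @param l2_lambda L2 weight-penalty coefficient (default 0.001).
#' @param use_timing_path If `FALSE`, builds the ablation variant without
#'   the timing branch.
#' @param morph_window Morphology window length W (default 500).
#' @param timing_length Timing vector length T (default 2000).
#' @return A `network_config` list (`n_classes` is fixed at 4).
#' @export
network_config <- function(morph_path1 = list(conv_block(8, 10, 16),
                                              conv_block(4, 50, 64)),
                           morph_path2 = list(conv_block(2, 30, 8),
                                              conv_block(16, 20, 64)),
                           timing_path = list(conv_block(32, 50, 64),
                                              conv_block(16, 30, 4)),
                           dense_units = 512L, final_dense_units = 32L,
                           dropout = 0.2, l2_lambda = 0.001,
                           use_timing_path = TRUE,
                           morph_window = 500L, timing_length = 2000L) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  for (p in list(morph_path1, morph_path2, timing_path)) {
    if (length(p) != 2L || !all(vapply(p, inherits, TRUE, "conv_block"))) {
      stop("each path needs exactly two conv_block specs")
    }
  }
  structure(list(morph_path1 = morph_path1, morph_path2 = morph_path2,
                 timing_path = timing_path,
                 dense_units = as.integer(dense_units),
                 final_dense_units = as.integer(final_dense_units),
                 dropout = dropout, l2_lambda = l2_lambda,
                 use_timing_path = isTRUE(use_timing_path),
                 n_classes = 4L,
                 morph_window = as.integer(morph_window),
                 timing_length = as.integer(timing_length)),
            class = "network_config")
}

#' @rdname network_config
#' @export
network_config_eecg <- function(...) network_config(...)

#' @rdname network_config
#' @export
network_config_mitbih <- function(...) {
  network_config(morph_path1 = list(conv_block(4, 60, 16),
                                    conv_block(16, 30, 16)),
                 morph_path2 = list(conv_block(2, 20, 40),
                                    conv_block(16, 20, 32)),
                 timing_path = list(conv_block(128, 300, 4),
                                    conv_block(8, 100, 8)),
                 ...)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.0001).
#' @param batch_size Minibatch size (default 500).
#' @param epochs Training epochs (default 20).
#' @param early_stop_patience Stop when training accuracy has not improved
#'   for this many epochs (`NULL` disables; the architecture search uses
#'   50 epochs with patience 3).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 500L,
                         epochs = 20L, early_stop_patience = NULL,
                         seed = 1L) {
  if (learning_rate < 0 || batch_size < 1L || epochs < 0L) {
    stop("invalid training configuration")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

# conv output length under "same" padding
.conv_len <- function(L, stride) as.integer(ceiling(L / stride))

#' Build an untrained network
#'
#' Weights use variance-scaling (He) initialization under the seed.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `trained_model` (untrained): `config`, `params` (named list
#'   of weight arrays), `bn_state`, `history`, `provenance`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  params <- list()
  bn_state <- list()
  add_morph_path <- function(prefix, blocks, W_in) {
    b1 <- blocks[[1L]]; b2 <- blocks[[2L]]
    k1 <- 2L * b1$convolution_width
    k2 <- 2L * b2$convolution_width
    L1 <- .conv_len(W_in, b1$subsampling)
    L2 <- .conv_len(L1, b2$subsampling)
    Lsc <- as.integer(ceiling(W_in / (b1$subsampling * b2$subsampling)))
    if (Lsc != L2) {
      stop("residual shortcut length (", Lsc, ") does not match the ",
           "convolution stack output (", L2, ") in path ", prefix)
    }
    params[[paste0(prefix, "_conv1_W")]] <<- .he_init(c(b1$filters, 1L, k1), k1)
    params[[paste0(prefix, "_conv1_b")]] <<- numeric(b1$filters)
    params[[paste0(prefix, "_bn1_gamma")]] <<- rep(1, b1$filters)
    params[[paste0(prefix, "_bn1_beta")]] <<- numeric(b1$filters)
    params[[paste0(prefix, "_conv2_W")]] <<-
      .he_init(c(b2$filters, b1$filters, k2), b1$filters * k2)
    params[[paste0(prefix, "_conv2_b")]] <<- numeric(b2$filters)
    params[[paste0(prefix, "_bn2_gamma")]] <<- rep(1, b2$filters)
    params[[paste0(prefix, "_bn2_beta")]] <<- numeric(b2$filters)
    params[[paste0(prefix, "_short_W")]] <<- .he_init(c(b2$filters, 1L, 1L), 1)
    params[[paste0(prefix, "_short_b")]] <<- numeric(b2$filters)
    bn_state[[paste0(prefix, "_bn1")]] <<-
      list(mean = numeric(b1$filters), var = rep(1, b1$filters))
    bn_state[[paste0(prefix, "_bn2")]] <<-
      list(mean = numeric(b2$filters), var = rep(1, b2$filters))
    2L * b2$filters * L2   # flattened width (2 leads)
  }
  .with_seed(seed, {
    d1 <- add_morph_path("m1", cfg$morph_path1, cfg$morph_window)
    d2 <- add_morph_path("m2", cfg$morph_path2, cfg$morph_window)
    params$morph_dense_W <- .he_init(c(d1 + d2, cfg$dense_units), d1 + d2)
    params$morph_dense_b <- numeric(cfg$dense_units)
    concat_units <- cfg$dense_units
    if (cfg$use_timing_path) {
      b1 <- cfg$timing_path[[1L]]; b2 <- cfg$timing_path[[2L]]
      k1 <- 2L * b1$convolution_width
      k2 <- 2L * b2$convolution_width
      L1 <- .conv_len(cfg$timing_length, b1$subsampling)
      L2 <- .conv_len(L1, b2$subsampling)
      params$t_conv1_W <- .he_init(c(b1$filters, 1L, k1), k1)
      params$t_conv1_b <- numeric(b1$filters)
      params$t_conv2_W <- .he_init(c(b2$filters, b1$filters, k2),
                                   b1$filters * k2)
      params$t_conv2_b <- numeric(b2$filters)
      dt <- b2$filters * L2
      params$timing_dense_W <- .he_init(c(dt, cfg$dense_units), dt)
      params$timing_dense_b <- numeric(cfg$dense_units)
      concat_units <- concat_units + cfg$dense_units
    }
    params$final_W <- .he_init(c(concat_units, cfg$final_dense_units),
                               concat_units)
    params$final_b <- numeric(cfg$final_dense_units)
    params$out_W <- .he_init(c(cfg$final_dense_units, cfg$n_classes),
                             cfg$final_dense_units)
    params$out_b <- numeric(cfg$n_classes)
  })
  structure(list(config = cfg, params = params, bn_state = bn_state,
                 history = NULL,
                 provenance = list(init_seed = as.integer(seed))),
            class = "trained_model")
}

#' Total number of learnable parameters
#' @param model A `trained_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

# names of the feature-extractor parameters (conv, batch-norm, shortcut);
# the complement -- the dense layers -- is what freeze_features retrains
.feature_param_names <- function(params) {
  grep("^(m1|m2|t)_", names(params), value = TRUE)
}

# ---- forward / backward ---------------------------------------------------

.morph_path_fwd <- function(P, bn_state, prefix, Xf, blocks, dropout,
                            training, bn_update) {
  s1 <- blocks[[1L]]$subsampling
  s2 <- blocks[[2L]]$subsampling
  g <- function(nm) P[[paste0(prefix, "_", nm)]]
  c1 <- .conv1d_fwd(Xf, g("conv1_W"), g("conv1_b"), s1)
  b1 <- .bn_fwd(c1$Y, g("bn1_gamma"), g("bn1_beta"),
                bn_state[[paste0(prefix, "_bn1")]],
                training = training && bn_update)
  r1 <- .relu_fwd(b1$Y)
  dr1 <- .dropout_fwd(r1$Y, dropout, training)
  c2 <- .conv1d_fwd(dr1$Y, g("conv2_W"), g("conv2_b"), s2)
  b2 <- .bn_fwd(c2$Y, g("bn2_gamma"), g("bn2_beta"),
                bn_state[[paste0(prefix, "_bn2")]],
                training = training && bn_update)
  r2 <- .relu_fwd(b2$Y)
  dr2 <- .dropout_fwd(r2$Y, dropout, training)
  mp <- .maxpool_fwd(Xf, s1 * s2)
  sc <- .conv1d_fwd(mp$Y, g("short_W"), g("short_b"), 1L)
  out <- dr2$Y + sc$Y
  list(out = out,
       bn_states = stats::setNames(list(b1$state, b2$state),
                                   paste0(prefix, c("_bn1", "_bn2"))),
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    dr1 = dr1$cache, c2 = c2$cache, b2 = b2$cache,
                    r2 = r2$cache, dr2 = dr2$cache, mp = mp$cache,
                    sc = sc$cache))
}

.morph_path_bwd <- function(P, prefix, dOut, cache) {
  g <- function(nm) P[[paste0(prefix, "_", nm)]]
  grads <- list()
  sc <- .conv1d_bwd(dOut, g("short_W"), cache$sc)
  grads[[paste0(prefix, "_short_W")]] <- sc$dW
  grads[[paste0(prefix, "_short_b")]] <- sc$db
  dXf_short <- .maxpool_bwd(sc$dX, cache$mp)

  d <- dOut
  if (!is.null(cache$dr2)) d <- d * cache$dr2
  d <- d * cache$r2
  bn2 <- .bn_bwd(d, cache$b2)
  grads[[paste0(prefix, "_bn2_gamma")]] <- bn2$dgamma
  grads[[paste0(prefix, "_bn2_beta")]] <- bn2$dbeta
  c2 <- .conv1d_bwd(bn2$dX, g("conv2_W"), cache$c2)
  grads[[paste0(prefix, "_conv2_W")]] <- c2$dW
  grads[[paste0(prefix, "_conv2_b")]] <- c2$db
  d <- c2$dX
  if (!is.null(cache$dr1)) d <- d * cache$dr1
  d <- d * cache$r1
  bn1 <- .bn_bwd(d, cache$b1)
  grads[[paste0(prefix, "_bn1_gamma")]] <- bn1$dgamma
  grads[[paste0(prefix, "_bn1_beta")]] <- bn1$dbeta
  c1 <- .conv1d_bwd(bn1$dX, g("conv1_W"), cache$c1)
  grads[[paste0(prefix, "_conv1_W")]] <- c1$dW
  grads[[paste0(prefix, "_conv1_b")]] <- c1$db
  grads$.dXf <- c1$dX + dXf_short
  grads
}

# Full forward pass. Xm: (n, 2, W); Xt: (n, T) or NULL.
# `bn_update` FALSE keeps batch-norm in inference mode (frozen features).
.net_forward <- function(model, Xm, Xt, training, bn_update = TRUE) {
  cfg <- model$config
  P <- model$params
  n <- dim(Xm)[1L]
  Xf <- Xm
  dim(Xf) <- c(2L * n, 1L, cfg$morph_window)
  p1 <- .morph_path_fwd(P, model$bn_state, "m1", Xf, cfg$morph_path1,
                        cfg$dropout, training, bn_update)
  p2 <- .morph_path_fwd(P, model$bn_state, "m2", Xf, cfg$morph_path2,
                        cfg$dropout, training, bn_update)
  flat <- function(out) {
    d <- dim(out)
    dim(out) <- c(n, 2L * d[2L] * d[3L])
    out
  }
  f1 <- flat(p1$out)
  f2 <- flat(p2$out)
  morph_in <- cbind(f1, f2)
  md <- .dense_fwd(morph_in, P$morph_dense_W, P$morph_dense_b)
  mr <- .relu_fwd(md$Y)
  concat <- mr$Y
  tcache <- NULL
  if (cfg$use_timing_path) {
    Xt3 <- Xt
    dim(Xt3) <- c(n, 1L, cfg$timing_length)
    tc1 <- .conv1d_fwd(Xt3, P$t_conv1_W, P$t_conv1_b,
                       cfg$timing_path[[1L]]$subsampling)
    tdr1 <- .dropout_fwd(tc1$Y, cfg$dropout, training)
    tc2 <- .conv1d_fwd(tdr1$Y, P$t_conv2_W, P$t_conv2_b,
                       cfg$timing_path[[2L]]$subsampling)
    tdr2 <- .dropout_fwd(tc2$Y, cfg$dropout, training)
    tout <- tdr2$Y
    dt <- dim(tout)
    dim(tout) <- c(n, dt[2L] * dt[3L])
    td <- .dense_fwd(tout, P$timing_dense_W, P$timing_dense_b)
    tr <- .relu_fwd(td$Y)
    concat <- cbind(concat, tr$Y)
    tcache <- list(tc1 = tc1$cache, tdr1 = tdr1$cache, tc2 = tc2$cache,
                   tdr2 = tdr2$cache, td = td$cache, tr = tr$cache,
                   tflat_dim = dt)
  }
  fd <- .dense_fwd(concat, P$final_W, P$final_b)
  fr <- .relu_fwd(fd$Y)
  od <- .dense_fwd(fr$Y, P$out_W, P$out_b)
  probs <- .softmax(od$Y)
  list(probs = probs,
       bn_states = c(p1$bn_states, p2$bn_states),
       cache = list(p1 = p1$cache, p2 = p2$cache, md = md$cache,
                    mr = mr$cache, t = tcache, fd = fd$cache,
                    fr = fr$cache, od = od$cache,
                    dims = list(n = n, f1 = ncol(f1), f2 = ncol(f2))))
}

.net_backward <- function(model, fw, y_onehot) {
  cfg <- model$config
  P <- model$params
  cache <- fw$cache
  n <- cache$dims$n
  grads <- list()

  dlogits <- (fw$probs - y_onehot) / n
  od <- .dense_bwd(dlogits, P$out_W, cache$od)
  grads$out_W <- od$dW
  grads$out_b <- od$db
  d <- od$dX * cache$fr
  fd <- .dense_bwd(d, P$final_W, cache$fd)
  grads$final_W <- fd$dW
  grads$final_b <- fd$db
  dconcat <- fd$dX

  du <- cfg$dense_units
  dmorph <- dconcat[, seq_len(du), drop = FALSE]
  if (cfg$use_timing_path) {
    dtiming <- dconcat[, du + seq_len(du), drop = FALSE]
    t <- cache$t
    d <- dtiming * t$tr
    td <- .dense_bwd(d, P$timing_dense_W, t$td)
    grads$timing_dense_W <- td$dW
    grads$timing_dense_b <- td$db
    dtout <- td$dX
    dim(dtout) <- c(n, t$tflat_dim[2L], t$tflat_dim[3L])
    if (!is.null(t$tdr2)) dtout <- dtout * t$tdr2
    tc2 <- .conv1d_bwd(dtout, P$t_conv2_W, t$tc2)
    grads$t_conv2_W <- tc2$dW
    grads$t_conv2_b <- tc2$db
    d <- tc2$dX
    if (!is.null(t$tdr1)) d <- d * t$tdr1
    tc1 <- .conv1d_bwd(d, P$t_conv1_W, t$tc1)
    grads$t_conv1_W <- tc1$dW
    grads$t_conv1_b <- tc1$db
  }

  d <- dmorph * cache$mr
  md <- .dense_bwd(d, P$morph_dense_W, cache$md)
  grads$morph_dense_W <- md$dW
  grads$morph_dense_b <- md$db
  dflat <- md$dX
  d1 <- cache$dims$f1
  df1 <- dflat[, seq_len(d1), drop = FALSE]
  df2 <- dflat[, d1 + seq_len(cache$dims$f2), drop = FALSE]
  # recover path output dims from the shortcut conv cache
  to_path <- function(dfl, pcache) {
    Fn <- pcache$sc$Fn
    L <- pcache$sc$L_out
    dim(dfl) <- c(2L * n, Fn, L)
    dfl
  }
  g1 <- .morph_path_bwd(P, "m1", to_path(df1, cache$p1), cache$p1)
  g2 <- .morph_path_bwd(P, "m2", to_path(df2, cache$p2), cache$p2)
  dXf <- g1$.dXf + g2$.dXf
  g1$.dXf <- NULL
  g2$.dXf <- NULL
  grads <- c(grads, g1, g2)

  # L2 penalty on convolution and dense weight matrices
  if (cfg$l2_lambda > 0) {
    for (nm in grep("_W$", names(P), value = TRUE)) {
      grads[[nm]] <- grads[[nm]] + 2 * cfg$l2_lambda * P[[nm]]
    }
  }
  grads$.dXm <- dXf
  grads
}

# ---- training / inference -------------------------------------------------

.dataset_tensors <- function(dataset, cfg) {
  keep <- !is.na(dataset$labels)
  morph <- dataset$morphology[keep, , , drop = FALSE]
  w <- dim(morph)[3L]
  if (w != cfg$morph_window) {
    if (w > cfg$morph_window) {
      stop("dataset window (", w, ") exceeds the network input (",
           cfg$morph_window, ")")
    }
    pad <- array(0, c(dim(morph)[1L], 2L, cfg$morph_window))
    off <- (cfg$morph_window - w) %/% 2L
    pad[, , off + seq_len(w)] <- morph
    morph <- pad
  }
  timing <- NULL
  if (cfg$use_timing_path) {
    timing <- dataset$timing[keep, , drop = FALSE]
    tl <- ncol(timing)
    if (tl != cfg$timing_length) {
      if (tl > cfg$timing_length) {
        stop("timing length (", tl, ") exceeds the network input (",
             cfg$timing_length, ")")
      }
      pad <- matrix(0, nrow(timing), cfg$timing_length)
      off <- (cfg$timing_length - tl) %/% 2L
      pad[, off + seq_len(tl)] <- timing
      timing <- pad
    }
    storage.mode(timing) <- "double"
  }
  list(morph = morph, timing = timing,
       y = as.integer(dataset$labels[keep]))
}

.ce_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

#' Train a network
#'
#' Minibatch Adam on the softmax cross-entropy (plus the configured L2
#' penalty). With `early_stop_patience` set, training stops once the
#' training accuracy has not improved for that many epochs.
#'
#' @param model A `trained_model` from [build_network()] (or a previously
#'   trained one).
#' @param train_set,val_set `beat_dataset`s (`val_set` may be `NULL`).
#' @param cfg A [train_config()].
#' @param freeze_features Internal: train only the dense layers and keep
#'   batch-norm in inference mode.
#' @return The trained `trained_model`; `$history` holds per-epoch
#'   training loss/accuracy and validation accuracy.
#' @export
train_network <- function(model, train_set, val_set = NULL,
                          cfg = train_config(), freeze_features = FALSE) {
  stopifnot(inherits(model, "trained_model"),
            inherits(cfg, "train_config"))
  net_cfg <- model$config
  tt <- .dataset_tensors(train_set, net_cfg)
  n <- length(tt$y)
  if (n == 0L) stop("training set is empty")
  missing_cls <- setdiff(seq_len(net_cfg$n_classes), unique(tt$y))
  if (length(missing_cls)) {
    warning("class(es) absent from the training set: ",
            paste(.beat_classes[missing_cls], collapse = ", "),
            "; their metrics will be undefined")
  }
  trainable <- lapply(model$params, function(p) TRUE)
  names(trainable) <- names(model$params)
  if (freeze_features) {
    for (nm in .feature_param_names(model$params)) trainable[[nm]] <- FALSE
  }
  opt <- .adam_init(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  y_onehot_all <- diag(net_cfg$n_classes)[tt$y, , drop = FALSE]

  .with_seed(cfg$seed, {
    best_acc <- -Inf
    stall <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      ep_correct <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        Xm <- tt$morph[idx, , , drop = FALSE]
        Xt <- if (net_cfg$use_timing_path) {
          tt$timing[idx, , drop = FALSE]
        } else NULL
        fw <- .net_forward(model, Xm, Xt, training = TRUE,
                           bn_update = !freeze_features)
        if (!freeze_features) {
          for (nm in names(fw$bn_states)) {
            model$bn_state[[nm]] <- fw$bn_states[[nm]]
          }
        }
        yb <- tt$y[idx]
        ep_loss <- ep_loss + .ce_loss(fw$probs, yb) * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(fw$probs, ties.method = "first") == yb)
        if (cfg$learning_rate > 0) {
          grads <- .net_backward(model, fw,
                                 y_onehot_all[idx, , drop = FALSE])
          st <- .adam_step(model$params, grads, opt, cfg$learning_rate,
                           trainable)
          model$params <- st$params
          opt <- st$opt
        }
      }
      train_acc <- 100 * ep_correct / n
      val_acc <- NA_real_
      if (!is.null(val_set) && n_beats(val_set) > 0L) {
        val_acc <- .model_accuracy(model, val_set)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / n,
                                  train_acc = train_acc,
                                  val_acc = val_acc))
      if (!is.null(cfg$early_stop_patience)) {
        if (train_acc > best_acc + 1e-9) {
          best_acc <- train_acc
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$early_stop_patience) break
        }
      }
    }
  })
  model$history <- history
  model$provenance$train_seed <- cfg$seed
  model$provenance$n_train <- n
  model
}

#' Class probabilities and labels for a dataset
#'
#' Inference is deterministic: dropout is disabled and batch
#' normalization uses its running statistics.
#'
#' @param model A trained `trained_model`.
#' @param dataset A `beat_dataset`.
#' @param chunk Samples per forward chunk (memory control).
#' @return List with `probs` (n x 4 matrix, rows sum to 1) and `labels`
#'   (factor).
#' @export
predict_beats <- function(model, dataset, chunk = 256L) {
  cfg <- model$config
  keep_labels <- dataset$labels
  dataset$labels <- factor(rep("N", n_beats(dataset)),
                           levels = .beat_classes)
  tt <- .dataset_tensors(dataset, cfg)
  n <- length(tt$y)
  probs <- matrix(0, n, cfg$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    Xm <- tt$morph[idx, , , drop = FALSE]
    Xt <- if (cfg$use_timing_path) tt$timing[idx, , drop = FALSE] else NULL
    fw <- .net_forward(model, Xm, Xt, training = FALSE)
    probs[idx, ] <- fw$probs
  }
  colnames(probs) <- .beat_classes
  list(probs = probs,
       labels = factor(.beat_classes[max.col(probs, ties.method = "first")],
                       levels = .beat_classes))
}

.model_accuracy <- function(model, dataset) {
  keep <- !is.na(dataset$labels)
  ds <- .dataset_subset(dataset, which(keep))
  pred <- predict_beats(model, ds)
  100 * mean(as.character(pred$labels) == as.character(ds$labels))
}

#' Transfer learning between datasets
#'
#' `"full_finetune"` uses the source weights as initialization and updates
#' every parameter. `"freeze_features"` trains only the dense layers: the
#' convolutional, batch-norm and shortcut parameters (and the batch-norm
#' running statistics) are bit-identical before and after.
#'
#' @param model A trained source `trained_model`.
#' @param target_train,target_val `beat_dataset`s of the target domain.
#' @param mode `"full_finetune"` or `"freeze_features"`.
#' @param cfg A [train_config()].
#' @return The adapted `trained_model`.
#' @export
transfer <- function(model, target_train, target_val = NULL,
                     mode = c("full_finetune", "freeze_features"),
                     cfg = train_config()) {
  mode <- match.arg(mode)
  out <- train_network(model, target_train, target_val, cfg,
                       freeze_features = (mode == "freeze_features"))
  out$provenance$transfer_mode <- mode
  out
}

#' Majority-vote ensemble prediction
#'
#' Each model votes with its argmax label; ties are broken by the highest
#' mean softmax probability among the tied labels.
#'
#' @param models Non-empty list of `trained_model`s with identical input
#'   shapes.
#' @param dataset A `beat_dataset`.
#' @return Factor of predicted labels.
#' @export
ensemble_predict <- function(models, dataset) {
  if (!length(models)) stop("ensemble_predict needs at least one model")
  preds <- lapply(models, predict_beats, dataset = dataset)
  n <- n_beats(dataset)
  mean_probs <- Reduce(`+`, lapply(preds, `[[`, "probs")) / length(models)
  votes <- vapply(preds, function(p) as.integer(p$labels), integer(n))
  votes <- matrix(votes, nrow = n)
  out <- integer(n)
  for (i in seq_len(n)) {
    tab <- tabulate(votes[i, ], nbins = 4L)
    top <- which(tab == max(tab))
    out[i] <- if (length(top) == 1L) top
              else top[which.max(mean_probs[i, top])]
  }
  factor(.beat_classes[out], levels = .beat_classes)
}

#' Save / load a model checkpoint
#'
#' Single-file archive: config and provenance as JSON-compatible fields
#' plus the weight arrays (RDS container).
#'
#' @param model A `trained_model`.
#' @param path Checkpoint path.
#' @return `save_model`: `path`, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, %d parameters%s\n",
              if (x$config$use_timing_path) "parallel morphology+timing"
              else "morphology-only",
              n_parameters(x),
              if (is.null(x$history)) " (untrained)" else ""))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs, final loss %.4f, train acc %.1f%%\n",
                nrow(x$history), last$loss, last$train_acc))
  }
  invisible(x)
}
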