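# NSGA-II search over the network architecture hyperparameters.
#
# The genome covers, for each of the six convolutional blocks, the
# subsampling stride, convolution width and filter count, plus the dense
# width, the L2 coefficient and the dropout fraction. Counts are encoded
# on a log2 scale (the optimized architectures use powers of two),
# continuous rates linearly / log10. Individuals live in [0,1]^d and are
# decoded against the search-space bounds; variation uses simulated
# binary crossover and polynomial mutation; selection is binary
# tournament on (non-domination rank, crowding distance). Validation
# accuracy is the fitness; an optional second objective (parameter count)
# exploits the multi-objective nature of the algorithm and is off by
# default.

#' Hyperparameter search space
#'
#' @param subsampling,convolution_width,filters Length-2 integer bounds
#'   applied to every convolutional block.
#' @param dense_units Length-2 bounds for the per-pathway dense width.
#' @param l2_lambda Length-2 bounds (log10-spaced decoding).
#' @param dropout Length-2 bounds for the dropout fraction.
#' @return A `search_space` list.
#' @export
search_space <- function(subsampling = c(1L, 32L),
                         convolution_width = c(5L, 300L),
                         filters = c(4L, 64L),
                         dense_units = c(32L, 1024L),
                         l2_lambda = c(1e-5, 1e-2),
                         dropout = c(0, 0.5)) {
  chk <- function(b, nm) {
    if (length(b) != 2L || b[1L] > b[2L]) {
      stop("bounds for ", nm, " must be (lower, upper) with lower <= upper")
    }
    b
  }
  structure(list(subsampling = chk(subsampling, "subsampling"),
                 convolution_width = chk(convolution_width,
                                         "convolution_width"),
                 filters = chk(filters, "filters"),
                 dense_units = chk(dense_units, "dense_units"),
                 l2_lambda = chk(l2_lambda, "l2_lambda"),
                 dropout = chk(dropout, "dropout")),
            class = "search_space")
}

#' Genetic-algorithm configuration
#'
#' @param population_size Individuals per generation (default 20).
#' @param generations Number of generations (default 10).
#' @param inner_epochs Epochs for each fitness training (default 50).
#' @param inner_patience Early-stopping patience on training accuracy
#'   (default 3).
#' @param batch_size,learning_rate Inner-training settings.
#' @param use_size_objective Add parameter count as a second (minimized)
#'   objective.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 20L, generations = 10L,
                      inner_epochs = 50L, inner_patience = 3L,
                      batch_size = 500L, learning_rate = 1e-4,
                      use_size_objective = FALSE, seed = 1L) {
  if (population_size < 2L) stop("population_size must be >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 inner_epochs = as.integer(inner_epochs),
                 inner_patience = as.integer(inner_patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 use_size_objective = isTRUE(use_size_objective),
                 seed = as.integer(seed)),
            class = "ga_config")
}

.n_genes <- 21L  # 6 blocks x (sub, width, filters) + dense + l2 + dropout

# decode a [0,1]^21 genome into a network_config
.decode_genes <- function(u, space, window, timing_length,
                          final_dense_units = 32L) {
  log2_int <- function(v, b) {
    as.integer(round(2^(log2(b[1L]) + v * (log2(b[2L]) - log2(b[1L])))))
  }
  lin_int <- function(v, b) as.integer(round(b[1L] + v * (b[2L] - b[1L])))
  blocks <- vector("list", 6L)
  for (k in seq_len(6L)) {
    o <- (k - 1L) * 3L
    blocks[[k]] <- conv_block(
      subsampling = log2_int(u[o + 1L], space$subsampling),
      convolution_width = lin_int(u[o + 2L], space$convolution_width),
      filters = log2_int(u[o + 3L], space$filters))
  }
  dense <- log2_int(u[19L], space$dense_units)
  l2b <- space$l2_lambda
  l2 <- 10^(log10(l2b[1L]) + u[20L] * (log10(l2b[2L]) - log10(l2b[1L])))
  drop <- space$dropout[1L] +
    u[21L] * (space$dropout[2L] - space$dropout[1L])
  network_config(morph_path1 = blocks[1:2], morph_path2 = blocks[3:4],
                 timing_path = blocks[5:6], dense_units = dense,
                 final_dense_units = final_dense_units,
                 dropout = drop, l2_lambda = l2,
                 morph_window = window, timing_length = timing_length)
}

#' Evaluate one individual
#'
#' Builds the network decoded from the genome, trains it with early
#' stopping on training accuracy, and returns the validation accuracy in
#' percent. Gene combinations that cannot be built score 0.
#'
#' @param genes Numeric vector in `[0,1]^21`.
#' @param train_set,val_set `beat_dataset`s.
#' @param space A [search_space()].
#' @param cfg A [ga_config()].
#' @return Fitness (validation accuracy, %).
#' @export
evaluate_individual <- function(genes, train_set, val_set, space, cfg) {
  window <- dim(train_set$morphology)[3L]
  timing_length <- ncol(train_set$timing)
  net_cfg <- tryCatch(
    .decode_genes(genes, space, window, timing_length),
    error = function(e) NULL)
  if (is.null(net_cfg)) return(0)
  fit <- tryCatch({
    model <- build_network(net_cfg, seed = cfg$seed)
    tc <- train_config(learning_rate = cfg$learning_rate,
                       batch_size = cfg$batch_size,
                       epochs = cfg$inner_epochs,
                       early_stop_patience = cfg$inner_patience,
                       seed = cfg$seed)
    model <- train_network(model, train_set, cfg = tc)
    .model_accuracy(model, val_set)
  }, error = function(e) {
    message("individual failed to evaluate: ", conditionMessage(e))
    0
  })
  fit
}

# fast non-dominated sort; objectives: rows = individuals, minimized
.nds <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  dominated_by <- vector("list", n)
  dom_count <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- unique(nxt)
    r <- r + 1L
  }
  rank
}

.crowding <- function(obj, rank) {
  n <- nrow(obj)
  dist <- numeric(n)
  for (r in unique(rank)) {
    idx <- which(rank == r)
    if (length(idx) <= 2L) {
      dist[idx] <- Inf
      next
    }
    for (m in seq_len(ncol(obj))) {
      o <- obj[idx, m]
      ord <- order(o)
      rng <- max(o) - min(o)
      dist[idx[ord[1L]]] <- Inf
      dist[idx[ord[length(ord)]]] <- Inf
      if (rng > 0) {
        for (k in 2L:(length(ord) - 1L)) {
          dist[idx[ord[k]]] <- dist[idx[ord[k]]] +
            (o[ord[k + 1L]] - o[ord[k - 1L]]) / rng
        }
      }
    }
  }
  dist
}

.sbx_crossover <- function(p1, p2, eta = 15, pc = 0.9) {
  d <- length(p1)
  c1 <- p1
  c2 <- p2
  if (stats::runif(1) < pc) {
    for (i in seq_len(d)) {
      if (stats::runif(1) < 0.5 && abs(p1[i] - p2[i]) > 1e-14) {
        u <- stats::runif(1)
        beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
                else (1 / (2 * (1 - u)))^(1 / (eta + 1))
        c1[i] <- 0.5 * ((1 + beta) * p1[i] + (1 - beta) * p2[i])
        c2[i] <- 0.5 * ((1 - beta) * p1[i] + (1 + beta) * p2[i])
      }
    }
  }
  list(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

.poly_mutation <- function(x, eta = 20, pm = 1 / length(x)) {
  for (i in seq_along(x)) {
    if (stats::runif(1) < pm) {
      u <- stats::runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
               else 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[i] <- min(max(x[i] + delta, 0), 1)
    }
  }
  x
}

#' Run the NSGA-II architecture search
#'
#' @param train_set,val_set `beat_dataset`s; validation accuracy is the
#'   fitness.
#' @param space A [search_space()].
#' @param cfg A [ga_config()].
#' @param log_file Optional path for a JSON-lines evaluation log.
#' @return List with `best_genes`, `best_config` (decoded
#'   [network_config()]), `best_fitness`, `trajectory` (per-generation
#'   best/mean fitness) and `n_evaluations` (cache-deduplicated).
#' @export
run_search <- function(train_set, val_set, space = search_space(),
                       cfg = ga_config(), log_file = NULL) {
  window <- dim(train_set$morphology)[3L]
  timing_length <- ncol(train_set$timing)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(u) {
    key <- paste(signif(u, 12), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- evaluate_individual(u, train_set, val_set, space, cfg)
    n_eval <<- n_eval + 1L
    cache[[key]] <- fit
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(list(genes = round(u, 6), fitness = fit),
                           auto_unbox = TRUE),
          "\n", file = log_file, append = TRUE)
    }
    fit
  }
  objectives <- function(pop, fits) {
    obj <- matrix(-fits, ncol = 1L)
    if (cfg$use_size_objective) {
      sizes <- vapply(seq_len(nrow(pop)), function(i) {
        nc <- tryCatch(.decode_genes(pop[i, ], space, window,
                                     timing_length),
                       error = function(e) NULL)
        if (is.null(nc)) Inf
        else as.numeric(n_parameters(build_network(nc, seed = 1L)))
      }, numeric(1))
      obj <- cbind(obj, sizes)
    }
    obj
  }

  .with_seed(cfg$seed, {
    np <- cfg$population_size
    pop <- matrix(stats::runif(np * .n_genes), np, .n_genes)
    fits <- apply(pop, 1L, evaluate)
    trajectory <- data.frame(generation = integer(0), best = numeric(0),
                             mean = numeric(0))
    for (gen in seq_len(cfg$generations)) {
      obj <- objectives(pop, fits)
      rank <- .nds(obj)
      crowd <- .crowding(obj, rank)
      tournament <- function() {
        ij <- sample.int(np, 2L)
        i <- ij[1L]; j <- ij[2L]
        if (rank[i] < rank[j]) i
        else if (rank[j] < rank[i]) j
        else if (crowd[i] >= crowd[j]) i else j
      }
      children <- matrix(0, np, .n_genes)
      k <- 1L
      while (k <= np) {
        cs <- .sbx_crossover(pop[tournament(), ], pop[tournament(), ])
        children[k, ] <- .poly_mutation(cs[[1L]])
        if (k + 1L <= np) children[k + 1L, ] <- .poly_mutation(cs[[2L]])
        k <- k + 2L
      }
      child_fits <- apply(children, 1L, evaluate)
      # environmental selection over the combined population (elitist)
      all_pop <- rbind(pop, children)
      all_fits <- c(fits, child_fits)
      all_obj <- objectives(all_pop, all_fits)
      all_rank <- .nds(all_obj)
      all_crowd <- .crowding(all_obj, all_rank)
      keep <- order(all_rank, -all_crowd)[seq_len(np)]
      pop <- all_pop[keep, , drop = FALSE]
      fits <- all_fits[keep]
      trajectory <- rbind(trajectory,
                          data.frame(generation = gen, best = max(fits),
                                     mean = mean(fits)))
    }
    best <- which.max(fits)
    list(best_genes = pop[best, ],
         best_config = .decode_genes(pop[best, ], space, window,
                                     timing_length),
         best_fitness = fits[best],
         trajectory = trajectory,
         n_evaluations = n_eval)
  })
}
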