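# Genetic algorithm: binary chromosomes, roulette/tournament selection,
# single-point crossover, per-bit mutation, elitism. Drives wrapper feature
# selection (weighted accuracy / feature-count objective) and SVM/SVR
# hyper-parameter tuning.

#' GA configuration
#'
#' Defaults follow the study setting: population 20 and 50 generations, with
#' classic fitness-proportional (roulette) selection, single-point crossover
#' at probability 0.8, per-bit mutation at 0.01 and one elite individual
#' carried over unchanged (which makes the best-so-far fitness
#' non-decreasing).
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param crossover_prob single-point crossover probability.
#' @param mutation_prob per-bit mutation probability.
#' @param selection `"roulette"` or `"tournament"`.
#' @param tournament_size tournament size when `selection = "tournament"`.
#' @param elitism number of elites copied unchanged each generation.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 20, generations = 50, crossover_prob = 0.8,
                      mutation_prob = 0.01,
                      selection = c("roulette", "tournament"),
                      tournament_size = 3, elitism = 1, seed = NULL) {
  if (pop_size < 2) stop_input("`pop_size` must be >= 2")
  if (generations < 1) stop_input("`generations` must be >= 1")
  if (crossover_prob < 0 || crossover_prob > 1 || mutation_prob < 0 || mutation_prob > 1) {
    stop_input("probabilities must be in [0, 1]")
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 selection = match.arg(selection),
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism), seed = seed),
            class = "ga_config")
}

#' Fixed-point decoding of a bit chromosome segment
#'
#' Decodes a Gray-coded `n`-bit unsigned integer and maps it linearly onto
#' `[low, high]`: `low + int / (2^n - 1) * (high - low)`. Gray coding makes
#' adjacent grid points differ by a single bit, so small mutations make small
#' parameter moves and the encoding has no Hamming cliffs. [encode_real()]
#' is the inverse up to grid rounding: `decode_real(encode_real(p))` is the
#' grid point nearest `p`.
#'
#' @param bits 0/1 vector (most significant bit first).
#' @param low,high range bounds.
#' @return decoded real value.
#' @export
decode_real <- function(bits, low, high) {
  n <- length(bits)
  # Gray -> binary: cumulative xor from the most significant bit
  binary <- cumsum(bits) %% 2
  int <- sum(binary * 2^((n - 1):0))
  low + int / (2^n - 1) * (high - low)
}

#' @rdname decode_real
#' @param value real value to encode.
#' @param n_bits number of bits.
#' @export
encode_real <- function(value, low, high, n_bits) {
  int <- round((min(max(value, low), high) - low) / (high - low) * (2^n_bits - 1))
  binary <- as.integer(intToBits(int))[n_bits:1]
  # binary -> Gray: bit i xor bit i-1
  as.integer(xor(binary, c(0L, binary[-n_bits])))
}

#' Run the genetic algorithm
#'
#' Generational loop: evaluate, select, crossover, mutate, elitist
#' replacement. Returns the best-ever individual; with `elitism >= 1` the
#' best-so-far fitness history is non-decreasing. An objective that fails on
#' an individual contributes the worst fitness of its generation so the GA
#' can recover; if the whole first generation fails, an optimisation error is
#' raised.
#'
#' @param objective function taking a 0/1 chromosome vector, returning a
#'   finite fitness to maximise.
#' @param n_bits chromosome length.
#' @param config a [ga_config()].
#' @return list with `best_bits`, `best_fitness`, `history` (data.frame of
#'   per-generation best/mean/best-so-far) and `evaluations`.
#' @export
#' @examples
#' f <- function(bits) 1 - (decode_real(bits, 0, 1) - 0.5)^2
#' res <- ga_run(f, n_bits = 10, ga_config(seed = 1))
#' res$best_fitness
ga_run <- function(objective, n_bits, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  if (n_bits < 1) stop_input("`n_bits` must be >= 1")
  with_seed_(config$seed, ga_run_impl(objective, as.integer(n_bits), config))
}

ga_run_impl <- function(objective, n_bits, config) {
  np <- config$pop_size
  pop <- matrix(sample(0:1, np * n_bits, replace = TRUE), nrow = np)
  evals <- 0L
  eval_pop <- function(pop) {
    f <- apply(pop, 1L, function(bits) {
      tryCatch(as.numeric(objective(bits)), error = function(e) NA_real_)
    })
    evals <<- evals + nrow(pop)
    if (all(is.na(f))) stop_input("objective failed on every individual; optimisation aborted")
    f[is.na(f) | !is.finite(f)] <- min(f, na.rm = TRUE)
    f
  }
  fit <- eval_pop(pop)
  best_i <- which.max(fit)
  best_bits <- pop[best_i, ]; best_fit <- fit[best_i]
  hist <- data.frame(generation = 0L, best = max(fit), mean = mean(fit),
                     best_so_far = best_fit)

  select_one <- function(fit) {
    if (config$selection == "roulette") {
      w <- fit - min(fit) + 1e-12
      sample.int(np, 1L, prob = w)
    } else {
      cand <- sample.int(np, config$tournament_size, replace = TRUE)
      cand[which.max(fit[cand])]
    }
  }

  for (g in seq_len(config$generations)) {
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(min(config$elitism, np))]
    children <- matrix(0L, nrow = np, ncol = n_bits)
    nk <- length(elite_idx)
    if (nk > 0) children[seq_len(nk), ] <- pop[elite_idx, , drop = FALSE]
    i <- nk
    while (i < np) {
      p1 <- pop[select_one(fit), ]; p2 <- pop[select_one(fit), ]
      if (runif(1) < config$crossover_prob && n_bits > 1) {
        cut <- sample.int(n_bits - 1L, 1L)
        tmp <- p1
        p1 <- c(p1[1:cut], p2[(cut + 1):n_bits])
        p2 <- c(p2[1:cut], tmp[(cut + 1):n_bits])
      }
      for (child in list(p1, p2)) {
        if (i >= np) break
        i <- i + 1L
        flip <- runif(n_bits) < config$mutation_prob
        child[flip] <- 1L - child[flip]
        children[i, ] <- child
      }
    }
    pop <- children
    fit <- eval_pop(pop)
    if (max(fit) > best_fit) {
      best_fit <- max(fit); best_bits <- pop[which.max(fit), ]
    }
    hist <- rbind(hist, data.frame(generation = g, best = max(fit),
                                   mean = mean(fit), best_so_far = best_fit))
  }
  list(best_bits = as.integer(best_bits), best_fitness = best_fit,
       history = hist, evaluations = evals)
}

#' Feature-selection objective: weighted accuracy and parsimony
#'
#' `f = W * Acc + (1 - W) / Nf`, where `Acc` is the classification accuracy
#' on the evaluation split using only the masked feature columns and `Nf` is
#' the number of selected features. An empty mask scores 0 (worse than any
#' non-empty mask) rather than raising, so the GA can recover from it.
#'
#' @param mask 0/1 vector over feature columns.
#' @param x_train,y_train,x_eval,y_eval train/evaluation split.
#' @param spec classifier spec ([svm_spec()] or [rf_spec()]).
#' @param W accuracy weight in `[0, 1]` (default 0.9).
#' @param seed seed forwarded to [fit_rf()] when `spec` is an `rf_spec`.
#' @return objective value `f`.
#' @export
#' @examples
#' # W = 0.9, Acc = 0.95, Nf = 10 -> 0.865 (direct substitution)
eval_feature_mask <- function(mask, x_train, y_train, x_eval, y_eval,
                              spec = svm_spec(), W = 0.9, seed = 1) {
  if (W < 0 || W > 1) stop_input("`W` must be in [0, 1]")
  mask <- as.logical(mask)
  nf <- sum(mask)
  if (nf == 0) return(0)
  xtr <- as_feature_matrix(x_train)[, mask, drop = FALSE]
  xev <- as_feature_matrix(x_eval)[, mask, drop = FALSE]
  model <- if (inherits(spec, "rf_spec")) fit_rf(xtr, y_train, spec, seed = seed)
           else fit_svm(xtr, y_train, spec)
  acc <- mean(predict(model, xev) == as_binary_labels(y_eval))
  W * acc + (1 - W) / nf
}

# Seeded 70/30 row split used by the wrapper objectives.
inner_split <- function(n, train_fraction, seed) {
  idx <- with_seed_(seed, sample.int(n))
  ntr <- max(1L, floor(train_fraction * n))
  list(train = idx[seq_len(ntr)], eval = idx[(ntr + 1L):n])
}

#' GA wrapper feature selection
#'
#' Runs [ga_run()] over binary feature masks with the
#' [eval_feature_mask()] objective, evaluated on a seeded internal
#' train/validation split of the supplied data.
#'
#' @param x feature matrix (>= 2 columns).
#' @param y binary 0/1 labels.
#' @param spec classifier spec.
#' @param W accuracy weight.
#' @param config a [ga_config()] (its seed drives both the split and the GA).
#' @param train_fraction internal split fraction.
#' @return list with `mask` (logical), `fitness`, `n_features`, `history`.
#' @export
select_features <- function(x, y, spec = svm_spec(), W = 0.9,
                            config = ga_config(), train_fraction = 0.7) {
  x <- as_feature_matrix(x)
  if (ncol(x) < 2) stop_input("need at least 2 feature columns")
  sp <- inner_split(nrow(x), train_fraction, config$seed)
  obj <- function(bits) {
    eval_feature_mask(bits, x[sp$train, , drop = FALSE], y[sp$train],
                      x[sp$eval, , drop = FALSE], y[sp$eval],
                      spec = spec, W = W, seed = config$seed %||% 1)
  }
  res <- ga_run(obj, n_bits = ncol(x), config)
  list(mask = as.logical(res$best_bits), fitness = res$best_fitness,
       n_features = sum(res$best_bits), history = res$history)
}

default_tune_ranges <- function(model) {
  if (model == "svr") {
    list(C = c(0.01, 10), epsilon = c(0.001, 1), sigma_sq = c(0.1, 50))
  } else {
    list(C = c(0.01, 10), kernel_width = c(0.1, 5))
  }
}

#' GA hyper-parameter tuning for SVM or SVR
#'
#' Encodes each free parameter as a fixed-point binary segment
#' (`bits_per_param` bits, linear over its declared range), concatenates the
#' segments into one chromosome and maximises validation performance on a
#' seeded internal split: classification accuracy for `"svm"`, the
#' R-squared convention of [regression_metrics()] (as a fraction) for
#' `"svr"`. A degenerate range (`low == high`) fixes that parameter and
#' excludes it from the chromosome.
#'
#' @param model `"svm"` or `"svr"`.
#' @param x feature matrix.
#' @param y labels (svm) or numeric targets (svr).
#' @param ranges named list of `c(low, high)` ranges; defaults: C in
#'   `[0.01, 10]`, epsilon in `[0.001, 1]`, sigma_sq in `[0.1, 50]` for SVR
#'   (wide enough to cover the median-heuristic width of typical feature
#'   spaces), and C in `[0.01, 10]`, kernel_width in `[0.1, 5]` for SVM.
#' @param config a [ga_config()].
#' @param bits_per_param bits per encoded parameter (default 10).
#' @param train_fraction internal split fraction.
#' @return list with `spec` (tuned [svm_spec()]/[svr_spec()]), `params`
#'   (named vector), `fitness`, `history`.
#' @export
tune_parameters <- function(model = c("svr", "svm"), x, y,
                            ranges = NULL, config = ga_config(),
                            bits_per_param = 10, train_fraction = 0.7) {
  model <- match.arg(model)
  ranges <- ranges %||% default_tune_ranges(model)
  x <- as_feature_matrix(x)
  free <- names(ranges)[vapply(ranges, function(r) r[2] > r[1], logical(1))]
  fixed <- setdiff(names(ranges), free)
  if (!length(free)) stop_input("all parameter ranges are degenerate")
  sp <- inner_split(nrow(x), train_fraction, config$seed)

  decode_params <- function(bits) {
    p <- numeric(0)
    for (i in seq_along(free)) {
      seg <- bits[((i - 1L) * bits_per_param + 1L):(i * bits_per_param)]
      p[free[i]] <- decode_real(seg, ranges[[free[i]]][1], ranges[[free[i]]][2])
    }
    for (nm in fixed) p[nm] <- ranges[[nm]][1]
    p
  }
  make_spec <- function(p) {
    if (model == "svr") svr_spec(C = p[["C"]], epsilon = p[["epsilon"]],
                                 sigma_sq = p[["sigma_sq"]])
    else svm_spec(C = p[["C"]], kernel_width = p[["kernel_width"]])
  }
  obj <- function(bits) {
    p <- decode_params(bits)
    spec <- make_spec(p)
    if (model == "svm") {
      fit <- fit_svm(x[sp$train, , drop = FALSE], y[sp$train], spec)
      mean(predict(fit, x[sp$eval, , drop = FALSE]) == as_binary_labels(y[sp$eval]))
    } else {
      fit <- fit_svr(x[sp$train, , drop = FALSE], y[sp$train], spec)
      pr <- predict(fit, x[sp$eval, , drop = FALSE])
      regression_metrics(y[sp$eval], pr)$r2_pct / 100
    }
  }
  res <- ga_run(obj, n_bits = length(free) * bits_per_param, config)
  params <- decode_params(res$best_bits)
  list(spec = make_spec(params), params = params,
       fitness = res$best_fitness, history = res$history)
}
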