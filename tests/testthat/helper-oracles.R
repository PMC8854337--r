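# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths (and e1071) so that
# comparisons are genuine cross-checks.

# Brute-force epsilon-SVR solver for tiny problems (n = 3): maximises the
# dual  W(beta) = -0.5 t(beta) K beta - eps * sum|beta| + sum(y * beta)
# subject to sum(beta) = 0 and |beta_i| <= C, by nested grid refinement over
# (beta1, beta2) with beta3 = -(beta1 + beta2). Returns the expansion
# coefficients and the bias recovered from a free support vector.
qp_svr_oracle <- function(K, y, C, eps, levels = 5, grid_n = 81) {
  stopifnot(nrow(K) == 3, length(y) == 3)
  W <- function(b1, b2) {
    b <- c(b1, b2, -(b1 + b2))
    if (abs(b[3]) > C) return(-Inf)
    -0.5 * sum(b * (K %*% b)) - eps * sum(abs(b)) + sum(y * b)
  }
  lo1 <- lo2 <- -C; hi1 <- hi2 <- C
  best <- c(0, 0)
  for (lv in seq_len(levels)) {
    g1 <- seq(lo1, hi1, length.out = grid_n)
    g2 <- seq(lo2, hi2, length.out = grid_n)
    vals <- outer(g1, g2, Vectorize(W))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(g1[idx[1]], g2[idx[2]])
    step1 <- (hi1 - lo1) / (grid_n - 1)
    step2 <- (hi2 - lo2) / (grid_n - 1)
    lo1 <- max(-C, best[1] - 1.5 * step1); hi1 <- min(C, best[1] + 1.5 * step1)
    lo2 <- max(-C, best[2] - 1.5 * step2); hi2 <- min(C, best[2] + 1.5 * step2)
  }
  beta <- c(best, -sum(best))
  # bias from the freest support vector: y_i - sum_j beta_j K_ij - sign * eps
  slack <- C - abs(beta)
  free <- which(abs(beta) > 1e-8 & slack > 1e-8)
  i <- if (length(free)) free[which.max(slack[free])] else which.max(abs(beta))
  b <- y[i] - sum(beta * K[, i]) - sign(beta[i]) * eps
  list(beta = beta, bias = b)
}

gaussian_kernel_matrix <- function(X, sigma_sq) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma_sq))
  }
  K
}

# Two-class Gaussian clouds: `d_inf` informative dimensions (class means
# separated by `sep`), `d_noise` pure-noise dimensions.
make_clouds <- function(n_per_class, d_inf = 3, d_noise = 3, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(rnorm(n * (d_inf + d_noise)), nrow = n)
    y <- rep(c(0L, 1L), each = n_per_class)
    x[y == 1, seq_len(d_inf)] <- x[y == 1, seq_len(d_inf)] + sep
    colnames(x) <- c(paste0("inf", seq_len(d_inf)), paste0("noise", seq_len(d_noise)))
    list(x = x, y = y)
  })
}

# Pooled windowed feature tables for a simulated cohort (quiet).
cohort_feature_table <- function(n_subjects, seed, ...) {
  cohort <- generate_cohort(n_subjects, seed = seed, ...)
  tabs <- lapply(cohort, function(rec) {
    env <- suppressMessages(preprocess_emg(rec))
    frc <- preprocess_force(rec)
    frc <- align_force(frc, estimate_delay(env, frc), env$sampling_rate)
    build_feature_matrix(env, frc)
  })
  do.call(rbind, tabs)
}

quiet_protocol <- function(...) suppressMessages(run_protocol(...))
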