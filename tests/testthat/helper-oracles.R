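# Independent oracles the decoder is checked against. These share no code
# with the package internals: the Kalman filter is the textbook recursion
# written with explicit solve()s, and the grid filter integrates the
# mixture recursions numerically on a dense grid.

# Textbook Kalman filter: predict/update with explicit matrix inversion.
# Returns per-bin means, covariances, and log marginal likelihood.
oracle_kalman <- function(Y, A, b, Q, H, p, V, mean0, cov0) {
  Y <- as.matrix(Y)
  d <- length(mean0)
  means <- matrix(NA_real_, nrow(Y), d)
  covs <- vector("list", nrow(Y))
  loglik <- 0
  m <- mean0; P <- cov0
  for (t in seq_len(nrow(Y))) {
    if (t > 1) {
      m <- drop(A %*% m) + b
      P <- A %*% P %*% t(A) + Q
    }
    S <- H %*% P %*% t(H) + V
    innov <- Y[t, ] - (drop(H %*% m) + p)
    Sinv <- solve(S)
    loglik <- loglik - 0.5 * (length(innov) * log(2 * pi) +
                                determinant(S)$modulus[1] +
                                drop(t(innov) %*% Sinv %*% innov))
    K <- P %*% t(H) %*% Sinv
    m <- m + drop(K %*% innov)
    P <- P - K %*% H %*% P
    P <- (P + t(P)) / 2
    means[t, ] <- m
    covs[[t]] <- P
  }
  list(means = means, covs = covs, loglik = loglik)
}

# Dense-grid mixture filter for 1D state, arbitrary regimes: numerically
# integrates the predict step and accumulates per-regime marginal
# likelihood mass, then forms the collapsed mixture mean per bin.
oracle_grid_mixture <- function(Y, regimes, prior, mean0, var0,
                                lo = -15, hi = 15, n_grid = 3001) {
  x <- seq(lo, hi, length.out = n_grid)
  dx <- x[2] - x[1]
  M <- length(regimes)
  dens <- lapply(seq_len(M), function(m) dnorm(x, mean0, sqrt(var0)))
  logmass <- rep(0, M)
  Y <- as.matrix(Y)
  coll_mean <- numeric(nrow(Y))
  weights <- matrix(NA_real_, nrow(Y), M)
  for (t in seq_len(nrow(Y))) {
    for (m in seq_len(M)) {
      r <- regimes[[m]]
      if (t > 1) {
        # transition kernel applied by dense quadrature
        K <- outer(x, x, function(xp, xprev)
          dnorm(xp, r$a * xprev + r$b, sqrt(r$q)))
        dens[[m]] <- drop(K %*% dens[[m]]) * dx
      }
      lik <- vapply(x, function(xi)
        prod(dnorm(Y[t, ], r$h * xi + r$p, sqrt(r$v))), numeric(1))
      dens[[m]] <- dens[[m]] * lik
      mass <- sum(dens[[m]]) * dx
      logmass[m] <- logmass[m] + log(mass)
      dens[[m]] <- dens[[m]] / mass
    }
    lw <- log(prior) + logmass
    w <- exp(lw - max(lw)); w <- w / sum(w)
    weights[t, ] <- w
    mu_m <- vapply(dens, function(d) sum(x * d) * dx, numeric(1))
    coll_mean[t] <- sum(w * mu_m)
  }
  list(mean = coll_mean, weights = weights)
}

# Wrap bare per-regime parameter lists into the model-set structure the
# decoder consumes (any state dimension).
make_model_set <- function(models, mean0, cov0, n_units) {
  structure(list(models = models, M = length(models),
                 keying = "target_and_opening",
                 initial_mean = mean0, initial_cov = cov0,
                 n_units = n_units, start = "bottom",
                 regimes = NULL),
            class = "oa_model_set")
}

# Random stable regime model in d state dims, n units.
random_regime_model <- function(d = 2, n = 6) {
  A <- diag(d) * runif(1, 0.8, 0.99) + matrix(rnorm(d * d, sd = 0.05), d, d)
  Qr <- matrix(rnorm(d * d, sd = 0.3), d, d)
  H <- matrix(rnorm(n * d, sd = 0.5), n, d)
  Vr <- matrix(rnorm(n * n, sd = 0.2), n, n)
  list(A = A, b = rnorm(d, sd = 0.5), Q = crossprod(Qr) + diag(0.05, d),
       H = H, p = rnorm(n), V = crossprod(Vr) + diag(0.2, n))
}

# Simulate a state/observation sequence from one linear-Gaussian model.
simulate_lgss <- function(model, T_bins, mean0, cov0) {
  d <- length(mean0)
  X <- matrix(NA_real_, T_bins, d)
  Y <- matrix(NA_real_, T_bins, nrow(model$H))
  x <- drop(mtmdecode:::rmvn(1, mean0, cov0))
  for (t in seq_len(T_bins)) {
    if (t > 1) x <- drop(model$A %*% x) + model$b +
        drop(mtmdecode:::rmvn(1, rep(0, d), model$Q))
    X[t, ] <- x
    Y[t, ] <- drop(model$H %*% x) + model$p +
      drop(mtmdecode:::rmvn(1, rep(0, nrow(model$H)), model$V))
  }
  list(X = X, Y = Y)
}

# Build a minimal trial object directly from matrices (movement-only
# analyses); rest/delay/hold get padded stationary bins.
make_trial <- function(counts_move, positions_move, condition,
                       n_rest = 5, n_delay1 = 3, n_delay2 = 5, n_hold = 2,
                       counts_still = NULL, start_pos = c(0, 0)) {
  n <- ncol(counts_move)
  n_pre <- n_rest + n_delay1 + n_delay2
  still <- counts_still %||% matrix(0, n_pre + n_hold, n)
  counts <- rbind(still[seq_len(n_pre), , drop = FALSE], counts_move,
                  still[n_pre + seq_len(n_hold), , drop = FALSE])
  pos_pre <- matrix(rep(start_pos, each = n_pre), n_pre, 2)
  pos_hold <- matrix(rep(positions_move[nrow(positions_move), ], each = n_hold),
                     n_hold, 2)
  T_move <- nrow(counts_move)
  ends <- cumsum(c(n_rest, n_delay1, n_delay2, T_move, n_hold))
  epochs <- Map(function(e, l) seq.int(e - l + 1L, e), ends,
                c(n_rest, n_delay1, n_delay2, T_move, n_hold))
  names(epochs) <- c("rest", "delay1", "delay2", "movement", "hold")
  structure(list(counts = counts,
                 positions = rbind(pos_pre, positions_move, pos_hold),
                 epochs = epochs, condition = condition,
                 session_id = "unit-test", trial_id = 1L),
            class = "oa_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_condition <- list(start = "bottom", target = "top",
                          opening = "ccw", regime_id = 4L)
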