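test_that("predict step propagates Gaussians exactly", {
  # identity dynamics, no noise: posterior unchanged
  post <- list(mean = c(1, 2), cov = diag(c(0.5, 0.2)))
  m_id <- list(A = diag(2), b = c(0, 0), Q = matrix(0, 2, 2))
  expect_equal(predict_step(post, m_id), post, tolerance = 1e-12)
  # 1D embed: variances add under a random walk
  p1 <- predict_step(list(mean = 0, cov = matrix(1, 1, 1)),
                     list(A = matrix(1, 1, 1), b = 0, Q = matrix(1, 1, 1)))
  expect_equal(p1$mean, 0)
  expect_equal(p1$cov[1, 1], 2)
  # pure translation shifts the mean and adds Q
  m_tr <- list(A = diag(2), b = c(1, 0), Q = diag(0.1, 2))
  p2 <- predict_step(post, m_tr)
  expect_equal(p2$mean, c(2, 2))
  expect_equal(p2$cov, post$cov + diag(0.1, 2))
})

test_that("measurement update matches the closed-form 1D Kalman update", {
  pred <- list(mean = 0, cov = matrix(2, 1, 1))
  model <- list(H = matrix(1, 1, 1), p = 0, V = matrix(1, 1, 1))
  up <- update_step(pred, 2, model)
  expect_equal(up$mean, 4 / 3, tolerance = 1e-12)
  expect_equal(up$cov[1, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(up$log_likelihood_increment, dnorm(2, 0, sqrt(3), log = TRUE),
               tolerance = 1e-12)
  # an uninformative observation leaves the prediction unchanged
  up2 <- update_step(pred, 2, list(H = matrix(1, 1, 1), p = 0,
                                   V = matrix(1e12, 1, 1)))
  expect_equal(up2$mean, 0, tolerance = 1e-6)
  expect_equal(up2$cov[1, 1], 2, tolerance = 1e-6)
  # H = 0 decouples the observation from the state
  up3 <- update_step(pred, 5, list(H = matrix(0, 1, 1), p = 0,
                                   V = matrix(1, 1, 1)))
  expect_equal(up3$mean, 0)
  expect_equal(up3$cov[1, 1], 2)
  expect_equal(up3$log_likelihood_increment, dnorm(5, 0, 1, log = TRUE),
               tolerance = 1e-12)
})

test_that("mixture collapse returns the exact mixture moments", {
  shared <- list(mean = c(1, -1), cov = diag(c(2, 3)))
  out <- collapse_mixture(list(shared, shared, shared), rep(1 / 3, 3))
  expect_equal(out$mean, shared$mean)
  expect_equal(out$cov, shared$cov)
  # two point masses at +-1: mean 0, variance 1
  pm <- collapse_mixture(list(list(mean = 1, cov = matrix(0, 1, 1)),
                              list(mean = -1, cov = matrix(0, 1, 1))),
                         c(0.5, 0.5))
  expect_equal(pm$mean, 0)
  expect_equal(pm$cov[1, 1], 1)
  # degenerate weights select one component
  one <- collapse_mixture(list(shared, list(mean = c(9, 9), cov = diag(2))),
                          c(1, 0))
  expect_equal(one$mean, shared$mean)
  expect_equal(one$cov, shared$cov)
})

test_that("a single-regime mixture equals the textbook Kalman filter", {
  set.seed(301)
  for (k in 1:10) {
    model <- random_regime_model(d = 2, n = 5)
    mean0 <- rnorm(2); cov0 <- diag(runif(2, 0.5, 2))
    sim <- simulate_lgss(model, 8, mean0, cov0)
    ms <- make_model_set(list(`1` = model), mean0, cov0, 5)
    post <- mtm_filter(sim$Y, ms)
    orc <- oracle_kalman(sim$Y, model$A, model$b, model$Q, model$H, model$p,
                         model$V, mean0, cov0)
    for (t in seq_len(8)) {
      expect_equal(post[[t]]$collapsed_mean, orc$means[t, ], tolerance = 1e-9)
      expect_equal(post[[t]]$collapsed_cov, orc$covs[[t]], tolerance = 1e-9)
      expect_equal(post[[t]]$weights, 1)
    }
  }
})

test_that("a point-mass prior reduces the mixture to that regime's filter", {
  set.seed(302)
  m1 <- random_regime_model(2, 4); m2 <- random_regime_model(2, 4)
  mean0 <- c(0, 0); cov0 <- diag(2)
  sim <- simulate_lgss(m2, 6, mean0, cov0)
  ms <- make_model_set(list(`1` = m1, `2` = m2), mean0, cov0, 4)
  post <- mtm_filter(sim$Y, ms, decode_config(prior = c(0, 1)))
  orc <- oracle_kalman(sim$Y, m2$A, m2$b, m2$Q, m2$H, m2$p, m2$V, mean0, cov0)
  for (t in seq_len(6)) {
    expect_equal(post[[t]]$weights[2], 1, tolerance = 1e-12)
    expect_equal(post[[t]]$collapsed_mean, orc$means[t, ], tolerance = 1e-9)
  }
})

test_that("collapsed means match dense numerical integration of the mixture recursions", {
  # 1D toy: 2 regimes, 3 bins, 2 units, small-integer parameters
  regA <- list(a = 1, b = 0.5, q = 0.5, h = c(1, 0.5), p = c(0, 1), v = c(1, 2))
  regB <- list(a = 0.8, b = -0.5, q = 1, h = c(-1, 1), p = c(1, 0), v = c(2, 1))
  Y <- rbind(c(1, 2), c(2, 1), c(0, 3))
  to_model <- function(r) list(A = matrix(r$a, 1, 1), b = r$b,
                               Q = matrix(r$q, 1, 1),
                               H = matrix(r$h, 2, 1), p = r$p,
                               V = diag(r$v))
  for (prior in list(c(0.5, 0.5), c(0.8, 0.2))) {
    ms <- make_model_set(list(`1` = to_model(regA), `2` = to_model(regB)),
                         0, matrix(2, 1, 1), 2)
    post <- mtm_filter(Y, ms, decode_config(prior = prior))
    grid <- oracle_grid_mixture(Y, list(regA, regB), prior, 0, 2)
    for (t in 1:3) {
      expect_equal(post[[t]]$collapsed_mean, grid$mean[t], tolerance = 1e-3)
      expect_equal(post[[t]]$weights, grid$weights[t, ], tolerance = 1e-3)
    }
  }
})

test_that("static weights stay at the prior while likelihood weights adapt", {
  set.seed(303)
  m1 <- random_regime_model(2, 4); m2 <- random_regime_model(2, 4)
  mean0 <- c(0, 0); cov0 <- diag(2)
  sim <- simulate_lgss(m1, 10, mean0, cov0)
  ms <- make_model_set(list(`1` = m1, `2` = m2), mean0, cov0, 4)
  stat <- mtm_filter(sim$Y, ms, decode_config(prior = c(0.3, 0.7),
                                              weight_update = "static"))
  for (t in 1:10) expect_equal(stat[[t]]$weights, c(0.3, 0.7))
  lik <- mtm_filter(sim$Y, ms, decode_config(prior = c(0.3, 0.7)))
  # data generated from regime 1: the likelihood should overturn the prior
  expect_gt(lik[[10]]$weights[1], 0.5)
})

test_that("weights normalize and covariances stay PSD on fuzzed inputs", {
  set.seed(304)
  for (k in 1:50) {
    M <- sample(2:3, 1)
    n <- sample(3:6, 1)
    models <- setNames(lapply(seq_len(M), function(m) random_regime_model(2, n)),
                       seq_len(M))
    ms <- make_model_set(models, rnorm(2), diag(runif(2, 0.2, 2)), n)
    Y <- matrix(rnorm(5 * n, sd = sample(c(1, 10, 50), 1)), 5, n)
    prior <- runif(M); prior <- prior / sum(prior)
    post <- mtm_filter(Y, ms, decode_config(prior = prior))
    for (t in 1:5) {
      expect_lt(abs(sum(post[[t]]$weights) - 1), 1e-9)
      ev <- eigen(post[[t]]$collapsed_cov, symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
    }
  }
})

test_that("sharpening the prior on the true regime never hurts decoding accuracy", {
  geom <- task_geometry()
  sess <- generate_session(generator_config(n_units = 20, n_trials = 60, seed = 31),
                           geom)
  ms <- fit_model_set(sess)
  trials <- sess$trials[1:20]
  mse_at <- function(alpha, wu) {
    mean(vapply(trials, function(tr) {
      prior <- rep((1 - alpha) / 6, 6)
      prior[tr$condition$regime_id] <- prior[tr$condition$regime_id] + alpha
      path <- decoded_path(decode_trial(tr, ms, decode_config(
        prior = prior, weight_update = wu)))$mean
      mean(rowSums((path - tr$positions[tr$epochs$movement, ])^2))
    }, numeric(1)))
  }
  # with static weights the prior is the only regime information, and
  # sharpening it on the true regime is monotonically beneficial
  sweep_static <- vapply(c(0, 0.5, 0.9, 1), mse_at, numeric(1), wu = "static")
  expect_true(all(diff(sweep_static) <= 1e-8))
  # with likelihood-updated weights the data also identify the regime, so
  # only the endpoint comparison is guaranteed: a certain prior on the
  # true regime cannot be worse than no prior
  expect_lte(mse_at(1, "likelihood"), mse_at(0, "likelihood"))
})

test_that("credible bands widen with the credible level and cover the mean", {
  geom <- task_geometry()
  sess <- generate_session(generator_config(n_units = 10, n_trials = 30, seed = 32),
                           geom)
  ms <- fit_model_set(sess)
  post <- decode_trial(sess$trials[[1]], ms)
  p95 <- decoded_path(post, level = 0.95)
  p50 <- decoded_path(post, level = 0.50)
  expect_true(all(p95$upper - p95$lower >= p50$upper - p50$lower))
  expect_true(all(p95$lower <= p95$mean & p95$mean <= p95$upper))
  # prior length must match the number of regimes
  expect_error(decode_trial(sess$trials[[1]], ms,
                            decode_config(prior = c(0.5, 0.5))),
               "does not match")
})
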