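# Trial whose count in every bin equals the bin index, to pin down which
# bins each analysis window averages.
indexed_trial <- function(n_rest = 5, n_delay2 = 6) {
  T_bins <- n_rest + 3 + n_delay2 + 4 + 2
  counts <- matrix(seq_len(T_bins), T_bins, 2)
  pos <- matrix(0, T_bins, 2)
  ends <- cumsum(c(n_rest, 3, n_delay2, 4, 2))
  epochs <- Map(function(e, l) seq.int(e - l + 1L, e), ends,
                c(n_rest, 3, n_delay2, 4, 2))
  names(epochs) <- c("rest", "delay1", "delay2", "movement", "hold")
  structure(list(counts = counts, positions = pos, epochs = epochs,
                 condition = default_condition, session_id = "x",
                 trial_id = 1L), class = "oa_trial")
}

test_that("analysis windows average exactly the prescribed bins", {
  tr <- indexed_trial()
  # target window: 5 rest + 3 delay-1 + first delay-2 bin = bins 1..9
  expect_equal(unname(extract_window_features(tr, "target")),
               rep(mean(1:9), 2))
  # selection window: delay-2 bins 2..5 = bins 10..13
  expect_equal(unname(extract_window_features(tr, "selection")),
               rep(mean(10:13), 2))
  # constant counts give the constant back
  tr$counts[] <- 7
  expect_equal(unname(extract_window_features(tr, "target")), c(7, 7))
  tr$counts[1, 1] <- NA
  expect_error(classify_features(extract_window_features(tr, "target"),
                                 fit_prior_model(list(indexed_trial(),
                                                      indexed_trial()),
                                                 labels = c("a", "a"),
                                                 which = "target")),
               regexp = "non-finite|fewer than 2")
})

test_that("maximum-likelihood class parameters and flooring behave as specified", {
  mk <- function(v) {
    tr <- indexed_trial()
    tr$counts[] <- v
    tr
  }
  trials <- list(mk(0), mk(0), mk(2), mk(2))
  labels <- c("a", "a", "b", "b")
  pm <- fit_prior_model(trials, "target", labels = labels)
  expect_equal(unname(pm$mu[, "a"]), c(0, 0))
  expect_equal(unname(pm$mu[, "b"]), c(2, 2))
  expect_equal(unname(pm$sigma2[, "a"]), rep(1e-4, 2))  # zero variance floored
  # identical classes give identical columns
  pm2 <- fit_prior_model(list(mk(1), mk(1), mk(1), mk(1)), "target",
                         labels = labels)
  expect_equal(pm2$mu[, "a"], pm2$mu[, "b"])
  expect_error(fit_prior_model(trials, "target", labels = c("a", "b", "b", "b")),
               "fewer than 2")
})

test_that("posterior probabilities follow Bayes' rule for Gaussian classes", {
  model <- structure(list(classes = c("c1", "c2"),
                          mu = matrix(c(0, 2), 1, 2,
                                      dimnames = list(NULL, c("c1", "c2"))),
                          sigma2 = matrix(1, 1, 2),
                          which = "target", var_floor = 1e-4),
                     class = "oa_prior_model")
  # equidistant feature: symmetric posterior
  expect_equal(unname(classify_features(1, model)), c(0.5, 0.5))
  # y = 0: density ratio e^2 : 1
  expect_equal(unname(classify_features(0, model))[1],
               exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # identical classes: uniform posterior whatever the feature
  model$mu[1, ] <- c(1, 1)
  expect_equal(unname(classify_features(5, model)), c(0.5, 0.5))
  # a non-uniform class prior shifts the posterior accordingly
  expect_equal(unname(classify_features(5, model, prior = c(0.9, 0.1))),
               c(0.9, 0.1))
})

test_that("log-domain classification equals direct density computation", {
  set.seed(401)
  for (k in 1:20) {
    n <- 5
    model <- structure(list(classes = c("a", "b", "c"),
                            mu = matrix(rnorm(3 * n), n, 3,
                                        dimnames = list(NULL, c("a", "b", "c"))),
                            sigma2 = matrix(runif(3 * n, 0.5, 2), n, 3),
                            which = "target", var_floor = 1e-4),
                       class = "oa_prior_model")
    y <- rnorm(n)
    direct <- vapply(1:3, function(j)
      prod(dnorm(y, model$mu[, j], sqrt(model$sigma2[, j]))), numeric(1))
    direct <- direct / sum(direct)
    expect_equal(unname(classify_features(y, model)), direct, tolerance = 1e-12)
  }
})

test_that("priors combine over the six regimes by independent products", {
  cat6 <- regime_catalogue(task_geometry(), "bottom")
  u3 <- setNames(rep(1 / 3, 3), c("left", "top", "right"))
  u2 <- setNames(c(0.5, 0.5), c("cw", "ccw"))
  expect_equal(unname(combine_priors(u3, u2, cat6)), rep(1 / 6, 6))
  tp <- setNames(c(0.6, 0.3, 0.1), c("left", "top", "right"))
  sp <- setNames(c(0.7, 0.3), c("cw", "ccw"))
  comb <- combine_priors(tp, sp, cat6)
  expect_equal(sum(comb), 1)
  for (r in seq_len(nrow(cat6)))
    expect_equal(unname(comb[cat6$regime_id[r]]),
                 tp[[cat6$target[r]]] * sp[[cat6$opening[r]]])
  # point masses concentrate on the unique regime
  dt <- setNames(c(0, 1, 0), c("left", "top", "right"))
  ds <- setNames(c(1, 0), c("cw", "ccw"))
  dd <- combine_priors(dt, ds, cat6)
  expect_equal(unname(dd[regime_id_for(cat6, "bottom", "top", "cw")]), 1)
  # broken catalogue is rejected
  bad <- cat6; bad$regime_id[2] <- bad$regime_id[1]
  expect_error(combine_priors(tp, sp, bad), "bijection")
  # target-only expansion halves each target's mass over its openings
  exp6 <- expand_target_prior(tp, cat6)
  expect_equal(unname(exp6[regime_id_for(cat6, "bottom", "left", "cw")]), 0.3)
  expect_equal(sum(exp6), 1)
})

test_that("LOOCV expectation sits at chance for permuted labels and high for separated classes", {
  geom <- task_geometry()
  sess <- generate_session(generator_config(n_units = 15, n_trials = 90, seed = 42),
                           geom)
  # permuted labels destroy the class structure: expectation ~ chance
  set.seed(43)
  perm_t <- sample(vapply(sess$trials, function(tr) tr$condition$target, ""))
  lo_t <- loocv_expectation(sess$trials, "target", labels = perm_t)
  expect_lt(abs(lo_t$mean - 1 / 3), 3 * lo_t$sd / sqrt(90) + 0.02)
  perm_s <- sample(vapply(sess$trials, function(tr) tr$condition$opening, ""))
  lo_s <- loocv_expectation(sess$trials, "selection", labels = perm_s)
  expect_lt(abs(lo_s$mean - 1 / 2), 3 * lo_s$sd / sqrt(90) + 0.02)
  # true labels on well-separated classes: expectation near 1
  sep <- generate_session(generator_config(n_units = 15, n_trials = 90, seed = 44,
                                           plan_speed = 60, sel_gain = 2),
                          geom)
  expect_gt(loocv_expectation(sep$trials, "target")$mean, 0.9)
  expect_gt(loocv_expectation(sep$trials, "selection")$mean, 0.9)
  # expectations are probabilities
  expect_true(all(lo_t$expectations >= 0 & lo_t$expectations <= 1))
})

test_that("expectation increases with class separation and is flat under the null", {
  geom <- task_geometry()
  means <- vapply(c(5, 15, 30, 60), function(sp) {
    sess <- generate_session(generator_config(n_units = 12, n_trials = 60,
                                              seed = 45, plan_speed = sp),
                             geom)
    loocv_expectation(sess$trials, "target")$mean
  }, numeric(1))
  expect_true(all(diff(means) >= -0.02))
  expect_gt(means[4], means[1])
  # identically distributed classes: t-test against chance non-significant
  sess0 <- generate_session(generator_config(n_units = 12, n_trials = 60,
                                             seed = 46, plan_speed = 0,
                                             sel_gain = 0), geom)
  lo0 <- loocv_expectation(sess0$trials, "selection")
  expect_gt(lo0$p_value, 0.05)
})
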