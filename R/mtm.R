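# Mixture of trajectory models: M parallel Kalman filters, one per
# movement regime, mixed by posterior regime probabilities
#   P(x_t | y_1..t) = sum_m P(x_t | y_1..t, m) P(m | y_1..t)
# where the regime weights combine the prior P(m) (uniform, or decoded
# from delay-period activity) with the accumulated per-regime marginal
# likelihoods P(y_1..t | m). Under the linear-Gaussian regime models the
# per-regime posteriors are exact Gaussians, so the per-regime recursion
# is the textbook Kalman predict/update and the mixture is collapsed to
# its exact first two moments for reporting.

#' Decoder configuration
#'
#' @param prior prior probability vector over regimes \code{P(m)};
#'   \code{NULL} means uniform (no prior knowledge).
#' @param weight_update \code{"likelihood"}: regime weights follow
#'   \code{w_m(t) proportional to P(y_1..t | m) P(m)}, accumulated
#'   recursively from per-bin innovation likelihoods; \code{"static"}:
#'   weights stay frozen at \code{P(m)} for every bin (ablation mode).
#' @param credible_level level of the per-coordinate credible intervals
#'   derived from the collapsed posterior covariance.
#' @return list of class \code{"oa_decode_config"}.
#' @export
decode_config <- function(prior = NULL,
                          weight_update = c("likelihood", "static"),
                          credible_level = 0.95) {
  weight_update <- match.arg(weight_update)
  if (!is.null(prior)) {
    stopifnot(all(prior >= 0), abs(sum(prior) - 1) < 1e-6)
    prior <- prior / sum(prior)
  }
  structure(list(prior = prior, weight_update = weight_update,
                 credible_level = credible_level),
            class = "oa_decode_config")
}

#' One-step prediction of a regime posterior
#'
#' Exact Gaussian propagation through the regime's random-walk dynamics:
#' \code{mean' = A mean + b}, \code{cov' = A cov A' + Q}.
#'
#' @param post list with \code{mean} and \code{cov} (posterior at t-1).
#' @param model regime model with \code{A}, \code{b}, \code{Q}.
#' @return list with predicted \code{mean} and \code{cov}.
#' @export
predict_step <- function(post, model) {
  list(mean = drop(model$A %*% post$mean) + model$b,
       cov = make_psd(model$A %*% post$cov %*% t(model$A) + model$Q))
}

#' Measurement update of a regime posterior
#'
#' Conditions the predicted Gaussian on the observed count vector under
#' the regime's observation model (the Kalman update), and returns the
#' log innovation likelihood
#' \code{log N(y; H mean + p, H cov H' + V)} used to update the regime
#' weights.
#'
#' @param pred list with predicted \code{mean} and \code{cov}.
#' @param y observed count vector (length n).
#' @param model regime model with \code{H}, \code{p}, \code{V}.
#' @return list with \code{mean}, \code{cov}, and
#'   \code{log_likelihood_increment}.
#' @export
update_step <- function(pred, y, model) {
  H <- model$H
  yhat <- drop(H %*% pred$mean) + model$p
  PHt <- pred$cov %*% t(H)
  S <- H %*% PHt + model$V
  S <- (S + t(S)) / 2
  R <- tryCatch(chol(S), error = function(e)
    stop("singular innovation covariance; check the observation noise floor"))
  loglik <- {
    z <- backsolve(R, y - yhat, transpose = TRUE)
    -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
  }
  # K = P H' S^{-1} via two triangular solves
  K <- t(backsolve(R, backsolve(R, t(PHt), transpose = TRUE)))
  mean_new <- pred$mean + drop(K %*% (y - yhat))
  cov_new <- make_psd(pred$cov - K %*% t(PHt))
  list(mean = mean_new, cov = cov_new, log_likelihood_increment = loglik)
}

#' Collapse a Gaussian mixture to its exact first two moments
#'
#' @param per_regime list of regime posteriors, each with \code{mean} and
#'   \code{cov}.
#' @param weights normalized mixture weights.
#' @return list with the mixture \code{mean} and \code{cov}
#'   (\code{sum w_m (cov_m + mu_m mu_m') - mean mean'}).
#' @export
collapse_mixture <- function(per_regime, weights) {
  stopifnot(length(per_regime) == length(weights),
            abs(sum(weights) - 1) < 1e-6)
  d <- length(per_regime[[1]]$mean)
  mean_mix <- rep(0, d)
  for (m in seq_along(per_regime))
    mean_mix <- mean_mix + weights[m] * per_regime[[m]]$mean
  cov_mix <- matrix(0, d, d)
  for (m in seq_along(per_regime)) {
    mu <- per_regime[[m]]$mean
    cov_mix <- cov_mix + weights[m] * (per_regime[[m]]$cov + tcrossprod(mu))
  }
  cov_mix <- cov_mix - tcrossprod(mean_mix)
  list(mean = mean_mix, cov = make_psd(cov_mix))
}

#' Run the mixture filter on a raw observation sequence
#'
#' Lower-level entry point used by [decode_trial()] and by oracle tests:
#' filters a bins x units count matrix through all regime models. At the
#' first bin each regime filter starts from the model set's initial state
#' (no dynamics step); afterwards each bin applies predict then update.
#' Regime weights are accumulated in the log domain with max-subtraction
#' before normalization.
#'
#' @param Y T x n matrix of observations.
#' @param models an \code{oa_model_set} (any state dimension).
#' @param cfg an \code{oa_decode_config}.
#' @return list of per-bin mixture posteriors; each element has
#'   \code{per_regime} (list of \code{mean}/\code{cov} per regime),
#'   \code{weights}, \code{collapsed_mean}, \code{collapsed_cov}.
#' @export
mtm_filter <- function(Y, models, cfg = decode_config()) {
  Y <- as.matrix(Y)
  M <- models$M
  prior <- cfg$prior %||% rep(1 / M, M)
  if (length(prior) != M)
    stop("prior length ", length(prior), " does not match M = ", M)
  log_prior <- log(pmax(prior, 1e-300))
  d <- length(models$initial_mean)
  states <- lapply(seq_len(M), function(m)
    list(mean = models$initial_mean, cov = models$initial_cov))
  log_cum <- rep(0, M)
  out <- vector("list", nrow(Y))
  for (t in seq_len(nrow(Y))) {
    y <- Y[t, ]
    for (m in seq_len(M)) {
      pred <- if (t == 1) states[[m]] else
        predict_step(states[[m]], models$models[[m]])
      states[[m]] <- update_step(pred, y, models$models[[m]])
      log_cum[m] <- log_cum[m] + states[[m]]$log_likelihood_increment
    }
    lw <- if (cfg$weight_update == "likelihood") log_prior + log_cum else log_prior
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    coll <- collapse_mixture(states, w)
    out[[t]] <- list(per_regime = lapply(states, function(s)
      list(mean = s$mean, cov = s$cov)),
      weights = w, collapsed_mean = coll$mean, collapsed_cov = coll$cov)
  }
  attr(out, "credible_level") <- cfg$credible_level
  out
}

#' Decode the movement trajectory of one trial
#'
#' Runs the mixture filter on the trial's movement-epoch spike counts.
#'
#' @param trial an \code{oa_trial}.
#' @param models an \code{oa_model_set}.
#' @param cfg an \code{oa_decode_config}; its \code{prior} is typically
#'   the delay-period regime posterior (see [combine_priors()]), or
#'   \code{NULL} for no prior knowledge.
#' @return as [mtm_filter()], one element per movement bin.
#' @export
decode_trial <- function(trial, models, cfg = decode_config()) {
  mv <- trial$epochs$movement
  if (length(mv) == 0) stop("trial has no movement-epoch bins")
  if (ncol(trial$counts) != models$n_units)
    stop("unit count mismatch between trial and model set")
  mtm_filter(trial$counts[mv, , drop = FALSE], models, cfg)
}

#' Extract the decoded path and credible band from filter output
#'
#' @param posteriors output of [decode_trial()] / [mtm_filter()].
#' @param level credible level; defaults to the level recorded by the
#'   decoder configuration.
#' @return list with \code{mean} (T x d), \code{lower}/\code{upper}
#'   (per-coordinate bands \code{mean +- z sqrt(diag(cov))}), and
#'   \code{weights} (T x M).
#' @export
decoded_path <- function(posteriors, level = NULL) {
  level <- level %||% attr(posteriors, "credible_level") %||% 0.95
  z <- stats::qnorm(1 - (1 - level) / 2)
  mean_mat <- t(vapply(posteriors, `[[`, numeric(length(posteriors[[1]]$collapsed_mean)),
                       "collapsed_mean"))
  sd_mat <- t(vapply(posteriors, function(p)
    sqrt(pmax(diag(p$collapsed_cov), 0)), numeric(ncol(mean_mat))))
  weights <- t(vapply(posteriors, `[[`, numeric(length(posteriors[[1]]$weights)),
                      "weights"))
  list(mean = mean_mat, lower = mean_mat - z * sd_mat,
       upper = mean_mat + z * sd_mat, weights = weights)
}
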