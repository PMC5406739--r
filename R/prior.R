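# Decoding of prior knowledge from the planning epochs: target direction
# from the delay-1 window and intended movement selection (clockwise vs
# counterclockwise around the obstacle) from the delay-2 window, each via
# a per-unit Gaussian naive-Bayes classifier
#   y | m  ~  prod_i N(y_i; mu_{i,m}, sigma2_{i,m})
# with maximum-likelihood class parameters, and their combination under
# independence, P(m | y) = P(m1 | y1) P(m2 | y2).

#' Window-averaged firing-rate features of a trial
#'
#' Per-unit mean spike count over the analysis window of the requested
#' prior: the target-direction window spans the whole rest and delay-1
#' epochs plus the first delay-2 bin (0--900 ms; the extra bin absorbs the
#' causal response delay), and the movement-selection window spans
#' delay-2 bins 2--5 (100--500 ms after obstacle onset).
#'
#' @param trial an \code{oa_trial}.
#' @param which \code{"target"} or \code{"selection"}.
#' @return numeric vector of length n_units (spikes/bin).
#' @export
extract_window_features <- function(trial, which = c("target", "selection")) {
  which <- match.arg(which)
  ep <- trial$epochs
  bins <- if (which == "target") {
    c(ep$rest, ep$delay1, ep$delay2[1])
  } else {
    if (length(ep$delay2) < 5)
      stop("selection window needs at least 5 delay-2 bins")
    ep$delay2[2:5]
  }
  if (any(bins > nrow(trial$counts)))
    stop("analysis window extends past the trial's bins")
  colMeans(trial$counts[bins, , drop = FALSE])
}

#' Fit the Gaussian naive-Bayes prior model
#'
#' Maximum-likelihood per-unit, per-class parameters of the window
#' features: class sample means and ML (1/n) variances, with variances
#' floored so silent units keep a proper density.
#'
#' @param trials list of trials; class labels are taken from each trial's
#'   condition (\code{target} label or \code{opening}), or supplied via
#'   \code{labels}.
#' @param which \code{"target"} or \code{"selection"}.
#' @param labels optional character vector of class labels, one per trial.
#' @param var_floor lower bound on the per-unit variances.
#' @return object of class \code{"oa_prior_model"}: \code{classes},
#'   \code{mu} (units x classes), \code{sigma2} (units x classes),
#'   \code{which}, \code{var_floor}.
#' @export
fit_prior_model <- function(trials, which = c("target", "selection"),
                            labels = NULL, var_floor = 1e-4) {
  which <- match.arg(which)
  if (is.null(labels))
    labels <- vapply(trials, function(tr)
      if (which == "target") tr$condition$target else tr$condition$opening, "")
  stopifnot(length(labels) == length(trials))
  classes <- sort(unique(labels))
  tab <- table(labels)
  if (any(tab < 2))
    stop("class(es) with fewer than 2 trials: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  feats <- t(vapply(trials, extract_window_features,
                    numeric(ncol(trials[[1]]$counts)), which = which))
  mu <- sapply(classes, function(cl) colMeans(feats[labels == cl, , drop = FALSE]))
  sigma2 <- sapply(classes, function(cl) {
    Fc <- feats[labels == cl, , drop = FALSE]
    colMeans(sweep(Fc, 2, colMeans(Fc))^2)       # ML variance
  })
  mu <- matrix(mu, ncol = length(classes), dimnames = list(NULL, classes))
  sigma2 <- matrix(pmax(sigma2, var_floor), ncol = length(classes),
                   dimnames = list(NULL, classes))
  structure(list(classes = classes, mu = mu, sigma2 = sigma2,
                 which = which, var_floor = var_floor),
            class = "oa_prior_model")
}

#' Posterior class probabilities of a feature vector
#'
#' Bayes' rule under the naive-Bayes model, computed in the log domain:
#' \code{P(m | y) proportional to prior_m prod_i N(y_i; mu_{i,m},
#' sigma2_{i,m})}, normalized over classes. The class prior is uniform by
#' default, matching the balanced task design.
#'
#' @param features per-unit feature vector (see
#'   [extract_window_features()]).
#' @param model an \code{oa_prior_model}.
#' @param prior optional prior over classes.
#' @return named probability vector over \code{model$classes}.
#' @export
classify_features <- function(features, model, prior = NULL) {
  stopifnot(inherits(model, "oa_prior_model"),
            length(features) == nrow(model$mu))
  if (!all(is.finite(features))) stop("non-finite feature value")
  K <- length(model$classes)
  prior <- prior %||% rep(1 / K, K)
  stopifnot(length(prior) == K)
  loglik <- vapply(seq_len(K), function(k)
    sum(stats::dnorm(features, model$mu[, k], sqrt(model$sigma2[, k]),
                     log = TRUE)), numeric(1))
  lp <- loglik + log(pmax(prior, 1e-300))
  post <- exp(lp - log_sum_exp(lp))
  stats::setNames(post / sum(post), model$classes)
}

#' Combine target and selection posteriors over the six movement regimes
#'
#' Under the independence assumption the regime posterior factorizes as
#' \code{P(m | y) = P(m1 | y1) P(m2 | y2)}: each regime -- a (target,
#' opening) pair -- receives the product of its target and opening
#' probabilities. The catalogue must map (target, opening) to regime ids
#' bijectively.
#'
#' @param target_probs named probability vector over target labels.
#' @param selection_probs named probability vector over openings
#'   (\code{"cw"}, \code{"ccw"}).
#' @param catalogue single-start regime catalogue from
#'   [regime_catalogue()].
#' @return probability vector over regime ids 1..6 (named).
#' @export
combine_priors <- function(target_probs, selection_probs, catalogue) {
  stopifnot(abs(sum(target_probs) - 1) < 1e-6,
            abs(sum(selection_probs) - 1) < 1e-6)
  if (anyDuplicated(catalogue[, c("target", "opening")]) ||
      anyDuplicated(catalogue$regime_id))
    stop("catalogue is not a bijection between (target, opening) and regime id")
  out <- numeric(nrow(catalogue))
  for (r in seq_len(nrow(catalogue))) {
    row <- catalogue[r, ]
    out[row$regime_id] <- target_probs[[row$target]] *
      selection_probs[[row$opening]]
  }
  stats::setNames(out, sort(catalogue$regime_id))
}

#' Expand a target-only posterior over the six regimes
#'
#' For the target-only decoder each target's probability mass is split
#' equally across its two obstacle openings.
#' @inheritParams combine_priors
#' @return probability vector over regime ids 1..6.
#' @export
expand_target_prior <- function(target_probs, catalogue) {
  sel <- stats::setNames(c(0.5, 0.5), c("cw", "ccw"))
  combine_priors(target_probs, sel, catalogue)
}

#' Leave-one-out expectation of correct classification
#'
#' For every trial the prior model is refitted on all other trials and the
#' posterior probability assigned to the trial's true class is recorded --
#' the "expectation of selecting the right class". Reports the mean, SD,
#' hard-classification accuracy, and a two-sided one-sample Student's
#' t-test of the expectations against the chance level (1/3 for the three
#' targets, 1/2 for the two openings).
#'
#' @param trials list of trials.
#' @param which \code{"target"} or \code{"selection"}.
#' @param labels optional label override (one per trial).
#' @param var_floor passed to [fit_prior_model()].
#' @return list with \code{expectations} (per-trial posterior on the true
#'   class), \code{mean}, \code{sd}, \code{accuracy}, \code{chance},
#'   \code{p_value}.
#' @export
loocv_expectation <- function(trials, which = c("target", "selection"),
                              labels = NULL, var_floor = 1e-4) {
  which <- match.arg(which)
  if (is.null(labels))
    labels <- vapply(trials, function(tr)
      if (which == "target") tr$condition$target else tr$condition$opening, "")
  n <- length(trials)
  expectations <- numeric(n)
  hard <- logical(n)
  for (i in seq_len(n)) {
    model <- fit_prior_model(trials[-i], which = which, labels = labels[-i],
                             var_floor = var_floor)
    post <- classify_features(extract_window_features(trials[[i]], which),
                              model)
    if (!labels[i] %in% model$classes)
      stop("held-out label not present in training classes: ", labels[i])
    expectations[i] <- post[[labels[i]]]
    hard[i] <- names(post)[which.max(post)] == labels[i]
  }
  chance <- 1 / length(unique(labels))
  # (near-)constant expectations: the t statistic is undefined, but the
  # verdict is clear -- at chance or not
  degenerate_p <- function() if (abs(mean(expectations) - chance) < 1e-9) 1 else 0
  p <- if (stats::sd(expectations) < 1e-12) degenerate_p() else
    tryCatch(stats::t.test(expectations, mu = chance)$p.value,
             error = function(e) degenerate_p())
  list(expectations = expectations, mean = mean(expectations),
       sd = stats::sd(expectations), accuracy = mean(hard),
       chance = chance, p_value = p)
}
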