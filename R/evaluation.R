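# Trajectory scoring: correlation / MSE against the true path, task
# success (obstacle clearance + target acquisition), and the paired
# comparison of decoders run with different prior knowledge.

# Liang-Barsky clip: does the closed segment p->q intersect the closed
# axis-aligned rectangle c(xmin, xmax, ymin, ymax)?
#' @keywords internal
#' @noRd
segment_hits_rect <- function(p, q, rect) {
  d <- q - p
  tmin <- 0; tmax <- 1
  for (axis in 1:2) {
    lo <- rect[2 * axis - 1]; hi <- rect[2 * axis]
    if (abs(d[axis]) < .Machine$double.eps) {
      if (p[axis] < lo || p[axis] > hi) return(FALSE)
    } else {
      t1 <- (lo - p[axis]) / d[axis]
      t2 <- (hi - p[axis]) / d[axis]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      tmin <- max(tmin, t1); tmax <- min(tmax, t2)
      if (tmin > tmax) return(FALSE)
    }
  }
  TRUE
}

#' Does a polyline touch an axis-aligned rectangle?
#'
#' Checks every segment between consecutive path points against the closed
#' rectangle.
#' @param path n x 2 matrix of points.
#' @param rect numeric \code{c(xmin, xmax, ymin, ymax)}.
#' @return logical.
#' @export
path_hits_rect <- function(path, rect) {
  if (nrow(path) == 1)
    return(path[1, 1] >= rect[1] && path[1, 1] <= rect[2] &&
             path[1, 2] >= rect[3] && path[1, 2] <= rect[4])
  for (i in seq_len(nrow(path) - 1))
    if (segment_hits_rect(path[i, ], path[i + 1, ], rect)) return(TRUE)
  FALSE
}

#' Correlation and mean squared error of a decoded trajectory
#'
#' Pearson correlation is computed per coordinate against the true
#' trajectory and averaged; MSE is the mean squared Euclidean error per
#' bin. By convention both trajectories are first normalized to the unit
#' square using the workspace extent (so MSE is comparable across
#' sessions); pass \code{normalize = NULL} to score in raw cm.
#'
#' @param decoded,true equal-size T x 2 (or T x d) position matrices.
#' @param normalize either \code{NULL} (raw coordinates) or a length-2
#'   numeric \code{c(min, max)} giving the workspace extent per axis
#'   (default the 20 cm workspace, \code{c(-10, 10)}).
#' @return list with \code{cc} (per-coordinate vector), \code{cc_mean},
#'   and \code{mse}. A coordinate whose true trace has zero variance is
#'   dropped from the correlation average with a warning.
#' @examples
#' p <- cbind(1:5, 5:1)
#' trajectory_cc_mse(p, p, normalize = NULL)$cc_mean  # 1
#' @export
trajectory_cc_mse <- function(decoded, true, normalize = c(-10, 10)) {
  decoded <- as.matrix(decoded); true <- as.matrix(true)
  stopifnot(all(dim(decoded) == dim(true)), nrow(true) >= 3)
  if (!is.null(normalize)) {
    span <- diff(normalize)
    decoded <- (decoded - normalize[1]) / span
    true <- (true - normalize[1]) / span
  }
  cc <- vapply(seq_len(ncol(true)), function(j) {
    if (stats::sd(true[, j]) == 0) NA_real_ else
      stats::cor(decoded[, j], true[, j])
  }, numeric(1))
  if (anyNA(cc)) warning("zero-variance true coordinate excluded from CC")
  list(cc = cc, cc_mean = mean(cc, na.rm = TRUE),
       mse = mean(rowSums((decoded - true)^2)))
}

#' Task success of a decoded trajectory
#'
#' A decoded reach counts as successful when it steers around the obstacle
#' and acquires the target: no segment between consecutive decoded points
#' intersects the obstacle rectangle of the trial's condition, and the
#' final decoded point lies within the target radius of the target centre.
#'
#' @param decoded T x 2 decoded positions, cm.
#' @param geometry an \code{oa_geometry}.
#' @param condition list with \code{start} and \code{target} labels.
#' @return logical.
#' @export
success_check <- function(decoded, geometry, condition) {
  rect <- obstacle_rect(geometry, condition$start, condition$target)
  if (path_hits_rect(as.matrix(decoded), rect)) return(FALSE)
  tgt <- geometry$positions[[condition$target]]
  last <- decoded[nrow(decoded), ]
  sqrt(sum((last - tgt)^2)) <= geometry$target_radius
}

#' Paired two-sided Student's t-test
#'
#' Thin wrapper around [stats::t.test()] for paired per-trial scores, with
#' an explicit convention for the degenerate zero-variance case: if all
#' paired differences are exactly zero the p-value is reported as 1; a
#' constant non-zero difference is an error.
#'
#' @param scores_a,scores_b equal-length numeric vectors of paired scores.
#' @return two-sided p-value.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(1)
    stop("constant non-zero paired difference: t statistic undefined")
  }
  stats::t.test(scores_a, scores_b, paired = TRUE)$p.value
}

# Decode one trial under a given regime prior and score it.
#' @keywords internal
#' @noRd
score_decoded_trial <- function(trial, models, prior, geometry,
                                weight_update = "likelihood") {
  cfg <- decode_config(prior = prior, weight_update = weight_update)
  post <- decode_trial(trial, models, cfg)
  path <- decoded_path(post)$mean
  true <- trial$positions[trial$epochs$movement, , drop = FALSE]
  sc <- trajectory_cc_mse(path, true, normalize = geometry$workspace)
  list(cc_x = sc$cc[1], cc_y = sc$cc[2], cc_mean = sc$cc_mean, mse = sc$mse,
       success = success_check(path, geometry, trial$condition))
}

#' Compare decoders with no prior, target-only prior, and combined prior
#'
#' Runs the full leave-one-out three-decoder comparison on a session: for
#' every trial, regime models and delay-period prior models are fitted on
#' all other trials, the held-out trial's delay activity is classified
#' into target / selection posteriors, and the movement trajectory is
#' decoded three times -- with a uniform regime prior (\code{none}), with
#' the delay-1 target posterior spread over the two openings of each
#' target (\code{target}), and with the combined target x selection
#' posterior (\code{both}). Each decode is scored by per-trial CC, MSE and
#' task success.
#'
#' @param session an \code{oa_session} whose trials share one start
#'   position.
#' @param weight_update regime-weight update rule passed to the decoder,
#'   \code{"likelihood"} (default) or \code{"static"}.
#' @param conditions decoder conditions to run, subset of
#'   \code{c("none", "target", "both")}.
#' @param override_priors optional named list mapping a decoder condition
#'   to a fixed regime prior (length-6 probability vector, or the string
#'   \code{"uniform"}) used for every trial; used for controls and
#'   ablations.
#' @param progress print a dot every 25 trials.
#' @return An object of class \code{"oa_comparison"}: \code{trials} (a
#'   per-trial data frame of scores per decoder condition) and
#'   \code{summary} (per-condition mean CC, mean MSE, success rate,
#'   pairwise paired t-test p-values on CC and MSE, and percentage changes
#'   between conditions: CC ascending rate, MSE descending rate, and
#'   success-rate ascending rate).
#' @export
compare_decoders <- function(session, weight_update = "likelihood",
                             conditions = c("none", "target", "both"),
                             override_priors = NULL, progress = FALSE) {
  stopifnot(inherits(session, "oa_session"))
  trials <- session$trials
  geometry <- session$geometry
  starts <- unique(vapply(trials, function(tr) tr$condition$start, ""))
  if (length(starts) != 1)
    stop("three-decoder comparison requires a single-start session; filter first")
  catalogue <- regime_catalogue(geometry, starts)
  full_fit <- fit_model_set(trials, keying = "target_and_opening",
                            catalogue = catalogue)
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    train <- trials[-i]
    test <- trials[[i]]
    models <- refit_model_set_without(full_fit, trials, i, catalogue)
    priors <- list()
    if ("none" %in% conditions) priors$none <- rep(1 / 6, 6)
    if (any(c("target", "both") %in% conditions)) {
      tgt_model <- fit_prior_model(train, which = "target")
      tgt_post <- classify_features(
        extract_window_features(test, "target"), tgt_model)
      if ("target" %in% conditions)
        priors$target <- expand_target_prior(tgt_post, catalogue)
      if ("both" %in% conditions) {
        sel_model <- fit_prior_model(train, which = "selection")
        sel_post <- classify_features(
          extract_window_features(test, "selection"), sel_model)
        priors$both <- combine_priors(tgt_post, sel_post, catalogue)
      }
    }
    if (!is.null(override_priors)) {
      for (nm in names(override_priors)) {
        ov <- override_priors[[nm]]
        priors[[nm]] <- if (identical(ov, "uniform")) rep(1 / 6, 6) else ov
      }
    }
    res <- lapply(conditions, function(cnd)
      score_decoded_trial(test, models, priors[[cnd]], geometry,
                          weight_update))
    rows[[i]] <- data.frame(trial_id = test$trial_id,
                            decoder = conditions,
                            regime_id = test$condition$regime_id,
                            do.call(rbind, lapply(res, as.data.frame)))
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  per_trial <- do.call(rbind, rows)
  summarize_comparison(per_trial, conditions)
}

#' @keywords internal
#' @noRd
summarize_comparison <- function(per_trial, conditions) {
  agg <- do.call(rbind, lapply(conditions, function(cnd) {
    d <- per_trial[per_trial$decoder == cnd, ]
    data.frame(decoder = cnd, n_trials = nrow(d),
               cc_mean = mean(d$cc_mean), mse_mean = mean(d$mse),
               success_rate = mean(d$success))
  }))
  pairs <- if (length(conditions) >= 2)
    utils::combn(conditions, 2, simplify = FALSE) else list()
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- per_trial[per_trial$decoder == pr[1], ]
    b <- per_trial[per_trial$decoder == pr[2], ]
    data.frame(a = pr[1], b = pr[2],
               p_cc = paired_ttest(a$cc_mean, b$cc_mean),
               p_mse = paired_ttest(a$mse, b$mse),
               p_success = paired_ttest(as.numeric(a$success),
                                        as.numeric(b$success)))
  }))
  # percentage-change conventions: ascending rate for CC / success
  # ((new - old) / old * 100), descending rate for MSE ((old - new) / old)
  pct <- NULL
  if (all(c("none", "target", "both") %in% conditions)) {
    g <- function(cnd, col) agg[agg$decoder == cnd, col]
    pct <- data.frame(
      comparison = c("both_vs_none", "both_vs_target"),
      cc_ascending_pct = c(
        (g("both", "cc_mean") - g("none", "cc_mean")) / g("none", "cc_mean"),
        (g("both", "cc_mean") - g("target", "cc_mean")) / g("target", "cc_mean")) * 100,
      mse_descending_pct = c(
        (g("none", "mse_mean") - g("both", "mse_mean")) / g("none", "mse_mean"),
        (g("target", "mse_mean") - g("both", "mse_mean")) / g("target", "mse_mean")) * 100,
      success_ascending_pct = c(
        (g("both", "success_rate") - g("none", "success_rate")) /
          max(g("none", "success_rate"), .Machine$double.eps),
        (g("both", "success_rate") - g("target", "success_rate")) /
          max(g("target", "success_rate"), .Machine$double.eps)) * 100)
  }
  structure(list(trials = per_trial, summary = agg, tests = tests,
                 percent_change = pct),
            class = "oa_comparison")
}

#' @export
print.oa_comparison <- function(x, digits = 3, ...) {
  cat("Three-decoder comparison (leave-one-out)\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  if (!is.null(x$percent_change)) {
    cat("Percentage changes (combined prior vs baseline):\n")
    print(format(x$percent_change, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
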