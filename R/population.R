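# Encoding analyses of the planning epochs: velocity-based population
# vectors (PVs) across rest/delay bins, and PCA of delay-2 activity.

#' Fit velocity tuning of every unit
#'
#' Velocities are first differences of movement-epoch positions divided by
#' the bin width (cm/s); each unit's counts are regressed on (v_x, v_y)
#' with an intercept. The coefficient vector is the unit's (unnormalized)
#' preferred direction: strongly tuned units keep proportionally larger
#' weights in the population vector. Each unit's baseline is its mean
#' rest-epoch rate, used for deviation-from-baseline PV weighting.
#'
#' @param trials list of trials (movement epochs provide the regression
#'   data; rest epochs provide the baselines).
#' @param bin_s bin width in seconds.
#' @return object of class \code{"oa_tuning"}: \code{coef} (units x 2),
#'   \code{baseline} (units), \code{pd} (preferred-direction angles, rad),
#'   \code{weight} (coefficient magnitudes).
#' @export
fit_velocity_tuning <- function(trials, bin_s = 0.1) {
  if (inherits(trials, "oa_trial")) trials <- list(trials)
  V <- list(); Y <- list(); R <- list()
  for (tr in trials) {
    mv <- tr$epochs$movement
    if (length(mv) >= 2) {
      pos <- tr$positions[mv, , drop = FALSE]
      V[[length(V) + 1]] <- diff(pos) / bin_s
      Y[[length(Y) + 1]] <- tr$counts[mv[-1], , drop = FALSE]
    }
    R[[length(R) + 1]] <- tr$counts[tr$epochs$rest, , drop = FALSE]
  }
  V <- do.call(rbind, V); Y <- do.call(rbind, Y)
  if (is.null(V) || nrow(V) < 3) stop("fewer than 3 movement bins available")
  Z <- cbind(V, 1)
  theta <- pinv(Z) %*% Y                       # 3 x n
  coef <- t(theta[1:2, , drop = FALSE])
  baseline <- colMeans(do.call(rbind, R))
  structure(list(coef = coef, baseline = baseline,
                 pd = atan2(coef[, 2], coef[, 1]),
                 weight = sqrt(rowSums(coef^2))),
            class = "oa_tuning")
}

#' Population vector of one bin's activity
#'
#' Sum of the units' preferred-direction (velocity-coefficient) vectors
#' weighted by the deviation of each unit's rate from its rest baseline:
#' \code{PV = sum_i (rate_i - baseline_i) coef_i}. At baseline activity
#' the PV is the zero vector.
#'
#' @param bin_counts count vector (length n_units).
#' @param tuning an \code{oa_tuning}.
#' @return 2-vector.
#' @export
population_vector <- function(bin_counts, tuning) {
  stopifnot(length(bin_counts) == nrow(tuning$coef))
  drop((bin_counts - tuning$baseline) %*% tuning$coef)
}

#' Temporal evolution of population vectors across rest and delay
#'
#' For a set of trials of one condition, computes the per-bin PV over the
#' five rest bins, three delay-1 bins and the first delay-2 bin, and sums
#' it across trials (summation over ~20 same-condition trials stabilizes
#' the direction estimate).
#'
#' @param trials list of trials sharing one condition.
#' @param tuning an \code{oa_tuning}.
#' @return object of class \code{"oa_pv_series"}: \code{pv} (9 x 2
#'   matrix), \code{epoch} (factor of bin epochs), \code{n_trials}.
#' @export
pv_evolution <- function(trials, tuning) {
  conds <- unique(t(vapply(trials, function(tr)
    c(tr$condition$start, tr$condition$target, tr$condition$opening),
    character(3))))
  if (nrow(conds) != 1) stop("trials must share a single condition")
  pv <- matrix(0, 9, 2)
  for (tr in trials) {
    bins <- c(tr$epochs$rest[1:5], tr$epochs$delay1, tr$epochs$delay2[1])
    for (j in seq_along(bins))
      pv[j, ] <- pv[j, ] + population_vector(tr$counts[bins[j], ], tuning)
  }
  structure(list(pv = pv,
                 epoch = factor(rep(c("rest", "delay1", "delay2"), c(5, 3, 1)),
                                levels = c("rest", "delay1", "delay2")),
                 n_trials = length(trials)),
            class = "oa_pv_series")
}

#' PCA of delay-2 neural patterns
#'
#' Mean-centred principal component analysis of per-bin count vectors from
#' the movement-selection window (delay-2 bins 2--5): each 100 ms bin of
#' each trial is one sample. Used to visualize whether the clockwise and
#' counterclockwise avoidance plans occupy separable regions of the
#' population state space.
#'
#' @param trials list of trials.
#' @param labels optional per-trial labels (defaults to the obstacle
#'   opening); replicated over each trial's window bins.
#' @return list with \code{scores} (samples x 2, first two PCs),
#'   \code{loadings} (units x 2), \code{explained} (variance ratios of all
#'   components), \code{labels}, \code{center}.
#' @export
pca_delay2 <- function(trials, labels = NULL) {
  if (is.null(labels))
    labels <- vapply(trials, function(tr) tr$condition$opening, "")
  X <- list(); lab <- list()
  for (i in seq_along(trials)) {
    ep <- trials[[i]]$epochs
    bins <- ep$delay2[2:min(5, length(ep$delay2))]
    X[[i]] <- trials[[i]]$counts[bins, , drop = FALSE]
    lab[[i]] <- rep(labels[i], length(bins))
  }
  X <- do.call(rbind, X)
  if (nrow(X) < 3) stop("need at least 3 delay-2 samples for PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pc$x[, 1:2, drop = FALSE],
       loadings = pc$rotation[, 1:2, drop = FALSE],
       explained = pc$sdev^2 / sum(pc$sdev^2),
       labels = unlist(lab), center = pc$center,
       prcomp = pc)
}
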