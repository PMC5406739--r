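# Per-regime linear-Gaussian state-space models of the reach:
#   x_t | x_{t-1}, m ~ N(A_m x_{t-1} + b_m, Q_m)     (random-walk kinematics)
#   y_t | x_t, m     ~ N(H_m x_t + p_m, V_m)         (Gaussian observation)
# fitted by least squares on labelled movement-epoch data and kept fixed
# at test time.

#' Fit the state-transition model of one movement regime
#'
#' Least-squares fit of \code{x_t = A x_(t-1) + b} over all consecutive
#' movement-epoch position pairs of the supplied trials. The regression is
#' solved in displacement form: \code{x_t - x_(t-1)} is regressed on
#' \code{x_(t-1)} through an SVD pseudo-inverse, so for degenerate inputs
#' (e.g. constant positions) the minimum-norm solution is \code{A = I},
#' \code{b = 0} -- the random walk. \code{Q} is the covariance of the
#' one-step residuals (maximum-likelihood normalization), symmetrized.
#'
#' @param trials list of trials of one regime (each with \code{positions}
#'   and \code{epochs$movement}), or a single trial.
#' @return list with \code{A} (d x d), \code{b} (d), \code{Q} (d x d).
#' @export
fit_state_model <- function(trials) {
  if (inherits(trials, "oa_trial")) trials <- list(trials)
  pairs <- lapply(trials, function(tr) {
    mv <- tr$epochs$movement
    x <- tr$positions[mv, , drop = FALSE]
    if (nrow(x) < 2) return(NULL)
    list(prev = x[-nrow(x), , drop = FALSE], next_ = x[-1, , drop = FALSE])
  })
  pairs <- Filter(Negate(is.null), pairs)
  X_prev <- do.call(rbind, lapply(pairs, `[[`, "prev"))
  X_next <- do.call(rbind, lapply(pairs, `[[`, "next_"))
  if (is.null(X_prev) || nrow(X_prev) < 4)
    stop("fewer than 4 state-transition pairs: regime underdetermined")
  d <- ncol(X_prev)
  Z <- cbind(X_prev, 1)                       # [x_{t-1}, 1]
  D <- X_next - X_prev                        # displacements
  theta <- pinv(Z) %*% D                      # (d+1) x d, min-norm
  A <- diag(d) + t(theta[seq_len(d), , drop = FALSE])
  b <- as.numeric(theta[d + 1, ])
  resid <- X_next - (X_prev %*% t(A) + matrix(b, nrow(X_prev), d, byrow = TRUE))
  Q <- make_psd(crossprod(resid) / nrow(resid))
  list(A = A, b = b, Q = Q)
}

#' Fit the observation model of one movement regime
#'
#' Per-unit least squares of movement-epoch spike counts on hand position
#' with intercept: \code{y_t = H x_t + p + eps}. The noise covariance
#' \code{V} is the residual covariance; by default only its diagonal is
#' kept (unit-independent noise), which is far better conditioned than a
#' full units x units covariance at typical trial counts. Diagonal
#' entries are floored at \code{var_floor} so silent units cannot produce
#' a degenerate density.
#'
#' @param trials list of trials of one regime, or a single trial.
#' @param diagonal_V keep only the diagonal of the residual covariance.
#' @param var_floor lower bound on the diagonal of \code{V}.
#' @return list with \code{H} (n x d), \code{p} (n), \code{V} (n x n).
#' @export
fit_observation_model <- function(trials, diagonal_V = TRUE,
                                  var_floor = 1e-6) {
  if (inherits(trials, "oa_trial")) trials <- list(trials)
  X <- do.call(rbind, lapply(trials, function(tr)
    tr$positions[tr$epochs$movement, , drop = FALSE]))
  Y <- do.call(rbind, lapply(trials, function(tr)
    tr$counts[tr$epochs$movement, , drop = FALSE]))
  if (is.null(X) || nrow(X) < ncol(X) + 2)
    stop("too few movement bins to fit the observation model")
  d <- ncol(X)
  Z <- cbind(X, 1)
  theta <- pinv(Z) %*% Y                      # (d+1) x n
  H <- t(theta[seq_len(d), , drop = FALSE])
  p <- as.numeric(theta[d + 1, ])
  resid <- Y - Z %*% theta
  V <- crossprod(resid) / nrow(resid)
  if (diagonal_V) V <- diag(pmax(diag(V), var_floor), ncol(Y))
  else V <- make_psd(V, floor = var_floor)
  diag(V) <- pmax(diag(V), var_floor)
  list(H = H, p = p, V = V)
}

#' Fit one state-space model per movement regime
#'
#' Groups a session's trials by movement regime under the chosen keying --
#' six regimes (target x obstacle opening) or three (target only) -- and
#' fits state and observation models for each. All trials must share one
#' start position, since regimes are defined within a start. The initial
#' state is the empirical mean and covariance of movement-onset positions
#' across all trials.
#'
#' @param trials list of trials (or an \code{oa_session}).
#' @param keying \code{"target_and_opening"} (M = 6) or
#'   \code{"target_only"} (M = 3).
#' @param catalogue regime catalogue for the session's start position;
#'   built automatically when a session is supplied.
#' @param min_trials minimum trials per regime.
#' @param geometry required when \code{trials} is a bare list and no
#'   catalogue is given.
#' @param ... passed to [fit_observation_model()].
#' @return An object of class \code{"oa_model_set"}: \code{models} (list
#'   indexed by regime id, each with \code{A, b, Q, H, p, V}), \code{M},
#'   \code{keying}, \code{initial_mean}, \code{initial_cov},
#'   \code{regimes} (data frame mapping regime id to target/opening), and
#'   \code{n_units}.
#' @export
fit_model_set <- function(trials, keying = c("target_and_opening", "target_only"),
                          catalogue = NULL, min_trials = 5,
                          geometry = NULL, ...) {
  keying <- match.arg(keying)
  if (inherits(trials, "oa_session")) {
    geometry <- trials$geometry
    trials <- trials$trials
  }
  starts <- unique(vapply(trials, function(tr) tr$condition$start, ""))
  if (length(starts) != 1)
    stop("all trials must share one start position (got: ",
         paste(starts, collapse = ", "), ")")
  if (is.null(catalogue)) {
    if (is.null(geometry)) geometry <- task_geometry()
    catalogue <- regime_catalogue(geometry, starts)
  }
  key_of <- function(tr) regime_key(tr$condition, catalogue, keying)
  keys <- vapply(trials, key_of, integer(1))
  all_keys <- if (keying == "target_and_opening") 1:6 else 1:3
  counts <- table(factor(keys, levels = all_keys))
  missing <- all_keys[counts == 0]
  if (length(missing))
    stop("no trials for regime(s): ", paste(missing, collapse = ", "))
  low <- all_keys[counts < min_trials]
  if (length(low))
    stop("fewer than ", min_trials, " trials for regime(s): ",
         paste(low, collapse = ", "))
  models <- lapply(all_keys, function(k) {
    grp <- trials[keys == k]
    c(fit_state_model(grp), fit_observation_model(grp, ...))
  })
  names(models) <- as.character(all_keys)
  onset <- t(vapply(trials, function(tr)
    tr$positions[tr$epochs$movement[1], ], numeric(2)))
  regimes <- regime_table(catalogue, keying)
  structure(list(models = models, M = length(all_keys), keying = keying,
                 initial_mean = colMeans(onset),
                 initial_cov = make_psd(stats::cov(onset), floor = 1e-8),
                 regimes = regimes, n_units = ncol(trials[[1]]$counts),
                 start = starts, catalogue = catalogue),
            class = "oa_model_set")
}

# Regime index of one condition under a keying: the catalogue regime_id for
# target_and_opening, or the target's index (1..3) for target_only.
#' @keywords internal
#' @noRd
regime_key <- function(condition, catalogue, keying) {
  if (keying == "target_and_opening")
    return(as.integer(regime_id_for(catalogue, condition$start,
                                    condition$target, condition$opening)))
  tgts <- unique(catalogue$target[order(catalogue$regime_id)])
  match(condition$target, tgts)
}

#' @keywords internal
#' @noRd
regime_table <- function(catalogue, keying) {
  if (keying == "target_and_opening") {
    out <- catalogue[order(catalogue$regime_id),
                     c("regime_id", "target", "opening")]
    rownames(out) <- NULL
    return(out)
  }
  tgts <- unique(catalogue$target[order(catalogue$regime_id)])
  data.frame(regime_id = seq_along(tgts), target = tgts, opening = NA)
}

# Leave-one-out refit: only the regime containing the held-out trial
# changes, so the other regime models are reused as-is. The initial state
# is recomputed without the held-out trial.
#' @keywords internal
#' @noRd
refit_model_set_without <- function(full_fit, trials, i, catalogue) {
  ms <- full_fit
  k <- regime_key(trials[[i]]$condition, catalogue, ms$keying)
  keys <- vapply(trials, function(tr)
    regime_key(tr$condition, catalogue, ms$keying), integer(1))
  grp <- trials[keys == k & seq_along(trials) != i]
  ms$models[[as.character(k)]] <- c(fit_state_model(grp),
                                    fit_observation_model(grp))
  onset <- t(vapply(trials[-i], function(tr)
    tr$positions[tr$epochs$movement[1], ], numeric(2)))
  ms$initial_mean <- colMeans(onset)
  ms$initial_cov <- make_psd(stats::cov(onset), floor = 1e-8)
  ms
}

#' @export
print.oa_model_set <- function(x, ...) {
  cat(sprintf("Regime model set: M = %d (%s), %d units, start = %s\n",
              x$M, x$keying, x$n_units, x$start))
  invisible(x)
}

#' Serialize / load a regime model set as JSON
#'
#' Matrices are stored as nested arrays together with the keying, start
#' position and regime table, so a model set can be refit once and reused.
#' @param models an \code{oa_model_set}.
#' @param path file path.
#' @return \code{read_model_set} returns an \code{oa_model_set}.
#' @export
write_model_set <- function(models, path) {
  stopifnot(inherits(models, "oa_model_set"))
  payload <- list(
    format = "mtmdecode-models", version = 1L,
    keying = models$keying, M = models$M, n_units = models$n_units,
    start = models$start,
    initial_mean = models$initial_mean,
    initial_cov = models$initial_cov,
    regimes = models$regimes,
    models = lapply(models$models, function(m)
      list(A = m$A, b = m$b, Q = m$Q, H = m$H, p = m$p, V = m$V)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "mtmdecode-models"))
    stop("not a mtmdecode model-set file")
  if (!identical(as.integer(x$version), 1L))
    stop("unsupported model-set version: ", x$version)
  models <- lapply(x$models, function(m)
    list(A = as.matrix(m$A), b = as.numeric(m$b), Q = as.matrix(m$Q),
         H = as.matrix(m$H), p = as.numeric(m$p), V = as.matrix(m$V)))
  structure(list(models = models, M = as.integer(x$M), keying = x$keying,
                 initial_mean = as.numeric(x$initial_mean),
                 initial_cov = as.matrix(x$initial_cov),
                 regimes = as.data.frame(x$regimes),
                 n_units = as.integer(x$n_units), start = x$start),
            class = "oa_model_set")
}
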