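#' Configuration of the synthetic session generator
#'
#' Bundles every knob of the synthetic obstacle-avoidance session: the unit
#' population (baselines, position- and velocity-tuning gain vectors), the
#' delay-period modulation, the count noise, and the trial timeline. The
#' defaults emulate the recording statistics of the task the package
#' models: ~40 sorted units, ~300 trials per session, 100 ms bins, a
#' 500 ms rest, a 300 ms delay-1 (target visible), a 500--800 ms delay-2
#' (obstacle visible) and a 1--1.5 s movement.
#'
#' Per-unit rates (spikes/bin) are built as
#' \deqn{rate = baseline + H x + G v + modulation}
#' where \code{x} is cursor position (cm), \code{v} velocity (cm/s), and
#' \code{H}, \code{G} per-unit gain row-vectors. During the delay epochs
#' the cursor is still, and planning modulation stands in for movement:
#' delay-1 and delay-2 rates add \code{G (v_plan * d_target)} -- the unit's
#' response to a virtual movement at \code{plan_speed} cm/s toward the
#' target -- and delay-2 additionally adds \code{sel_gain * s_i * o}, where
#' \code{s_i} is a per-unit selection weight and \code{o = +1/-1} for a
#' counterclockwise/clockwise opening. Counts are Gaussian around these
#' rates, rounded and clipped at zero (disable with
#' \code{round_counts = FALSE} to obtain the continuous model exactly).
#'
#' @param n_units number of units.
#' @param n_trials trials per session, balanced over the condition
#'   catalogue.
#' @param starts start positions to include; the default decoding benchmark
#'   uses a single start so regimes are keyed 1..6.
#' @param baseline_range range of per-unit baseline rates, spikes/bin.
#' @param pos_gain_range range of position-gain magnitudes, spikes/bin/cm.
#' @param velocity_gain_range range of velocity-gain magnitudes,
#'   spikes/bin/(cm/s); \code{c(0, 0)} removes velocity tuning so movement
#'   counts follow the pure position observation model.
#' @param plan_speed virtual planning speed, cm/s, scaling delay-period
#'   target modulation.
#' @param sel_gain amplitude of delay-2 movement-selection modulation,
#'   spikes/bin.
#' @param count_sd per-bin Gaussian count noise SD, spikes/bin.
#' @param kinematic_noise_sd positional noise added to trajectories, cm.
#' @param rest_bins,delay1_bins number of 100 ms bins in rest and delay 1.
#' @param delay2_bins_range,move_bins_range inclusive integer ranges from
#'   which delay-2 and movement durations are drawn uniformly per trial.
#' @param hold_bins bins held at the target after the reach.
#' @param round_counts round and clip counts to non-negative integers.
#' @param seed integer seed; the same seed and config give a bit-identical
#'   session.
#' @return An object of class \code{"oa_config"}.
#' @export
generator_config <- function(n_units = 40, n_trials = 300,
                             starts = "bottom",
                             baseline_range = c(0.5, 3),
                             pos_gain_range = c(0.05, 0.15),
                             velocity_gain_range = c(0.02, 0.08),
                             plan_speed = 20,
                             sel_gain = 0.5,
                             count_sd = 1,
                             kinematic_noise_sd = 0.1,
                             rest_bins = 5, delay1_bins = 3,
                             delay2_bins_range = c(5L, 8L),
                             move_bins_range = c(10L, 15L),
                             hold_bins = 5,
                             round_counts = TRUE,
                             seed = 1L) {
  stopifnot(n_units >= 1, n_trials >= 1, count_sd > 0,
            delay1_bins == 3,
            all(starts %in% position_labels),
            diff(baseline_range) >= 0, diff(delay2_bins_range) >= 0)
  cfg <- as.list(environment())
  cfg$bin_s <- 0.1
  class(cfg) <- "oa_config"
  cfg
}

# Draw the per-unit population (baselines, gain vectors, selection
# weights) from a config; called once per session under the session seed.
#' @keywords internal
#' @noRd
draw_population <- function(config) {
  n <- config$n_units
  ang_pos <- stats::runif(n, 0, 2 * pi)
  ang_vel <- stats::runif(n, 0, 2 * pi)
  list(
    baseline = stats::runif(n, config$baseline_range[1], config$baseline_range[2]),
    H = cbind(cos(ang_pos), sin(ang_pos)) *
      stats::runif(n, config$pos_gain_range[1], config$pos_gain_range[2]),
    G = cbind(cos(ang_vel), sin(ang_vel)) *
      stats::runif(n, config$velocity_gain_range[1], config$velocity_gain_range[2]),
    sel_w = stats::rnorm(n))
}

#' Default synthetic decoding benchmark configuration
#'
#' The documented study-condition session used by the package's decoder
#' comparison: one start position (bottom, six movement regimes), 240
#' balanced trials, 40 units, default modulation and noise levels, seed 0.
#' @param seed integer seed (default 0).
#' @return an \code{oa_config}.
#' @export
benchmark_config <- function(seed = 0L) {
  generator_config(n_units = 40, n_trials = 240, starts = "bottom",
                   seed = seed)
}

#' Expected delay-period rate for a condition
#'
#' The class-conditional mean rate vector the generator draws delay counts
#' around, for a given epoch. Used to check generator honesty (sample
#' means converge to these values) and to reason about class separation.
#'
#' @param population population list as stored in a generated session.
#' @param config the \code{oa_config} used.
#' @param geometry an \code{oa_geometry}.
#' @param start,target,opening condition labels.
#' @param epoch \code{"delay1"} (target modulation only) or \code{"delay2"}
#'   (target plus selection modulation).
#' @return numeric vector of length \code{n_units}, spikes/bin.
#' @export
delay_rate_mean <- function(population, config, geometry,
                            start, target, opening = NULL,
                            epoch = c("delay1", "delay2")) {
  epoch <- match.arg(epoch)
  fr <- segment_frame(geometry, start, target)
  x_rest <- geometry$positions[[start]]
  rate <- population$baseline + drop(population$H %*% x_rest) +
    drop(population$G %*% (config$plan_speed * fr$u))
  if (epoch == "delay2") {
    if (is.null(opening)) stop("opening required for delay-2 rates")
    o <- if (opening == "ccw") 1 else -1
    rate <- rate + config$sel_gain * population$sel_w * o
  }
  rate
}

#' Generate one avoidance trajectory
#'
#' Builds a smooth curved path from start to target through the avoidance
#' via-point of the condition: a quadratic Bezier curve constrained to pass
#' through the via-point at its midpoint, traversed with a minimum-jerk
#' speed profile (slow-fast-slow). At zero noise the path clears the
#' obstacle by construction; Gaussian positional noise of SD
#' \code{noise_sd} cm is added to the interior samples.
#'
#' @param geometry an \code{oa_geometry}.
#' @param start,target,opening condition labels.
#' @param duration_bins number of 100 ms samples (>= 3).
#' @param noise_sd positional noise SD, cm.
#' @return \code{duration_bins x 2} matrix of positions, cm. Row 1 is the
#'   start position; the last row lies within the target radius.
#' @export
generate_trajectory <- function(geometry, start, target, opening,
                                duration_bins, noise_sd = 0) {
  stopifnot(duration_bins >= 3)
  p0 <- geometry$positions[[start]]
  p2 <- geometry$positions[[target]]
  via <- via_point(geometry, start, target, opening)
  rect <- obstacle_rect(geometry, start, target)
  # control point placing the curve on the via-point at u = 1/2
  ctrl <- 2 * via - (p0 + p2) / 2
  u_of <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5  # min-jerk profile
  tau <- seq(0, 1, length.out = duration_bins)
  u <- u_of(tau)
  path <- outer((1 - u)^2, p0) + outer(2 * u * (1 - u), ctrl) + outer(u^2, p2)
  if (path_hits_rect(path, rect))
    stop("no collision-free opening exists for this condition/geometry")
  if (noise_sd > 0) {
    idx <- 2:(duration_bins - 1)
    path[idx, ] <- path[idx, ] +
      matrix(stats::rnorm(length(idx) * 2, sd = noise_sd), ncol = 2)
  }
  path
}

# Mean rate matrix (bins x units) for one trial given its kinematics.
#' @keywords internal
#' @noRd
trial_rate_matrix <- function(pop, config, geometry, start, target, opening,
                              epochs, positions) {
  T_bins <- nrow(positions)
  n <- config$n_units
  rate <- matrix(pop$baseline, T_bins, n, byrow = TRUE) +
    positions %*% t(pop$H)
  # velocity term: first differences / bin width; zero in the first bin
  vel <- rbind(c(0, 0), diff(positions)) / config$bin_s
  rate <- rate + vel %*% t(pop$G)
  fr <- segment_frame(geometry, start, target)
  plan <- drop(pop$G %*% (config$plan_speed * fr$u))
  dbins <- c(epochs$delay1, epochs$delay2)
  rate[dbins, ] <- rate[dbins, ] + matrix(plan, length(dbins), n, byrow = TRUE)
  o <- if (opening == "ccw") 1 else -1
  sel <- config$sel_gain * pop$sel_w * o
  rate[epochs$delay2, ] <- rate[epochs$delay2, ] +
    matrix(sel, length(epochs$delay2), n, byrow = TRUE)
  rate
}

#' Generate a synthetic recording session
#'
#' Simulates a full session of the delayed obstacle-avoidance task under
#' the statistical model the decoder assumes: per-trial epochs
#' (rest / delay 1 / delay 2 / movement / hold) in 100 ms bins, cursor
#' positions, and per-unit spike counts (class-conditional Gaussian rates
#' in the delay epochs; linear position + velocity tuning during movement).
#' Conditions are balanced over the catalogue restricted to
#' \code{config$starts}, and the whole session is reproducible from
#' \code{config$seed}.
#'
#' @param config an \code{oa_config}.
#' @param geometry an \code{oa_geometry}.
#' @return An object of class \code{"oa_session"}: a list with
#'   \code{trials} (a list of trial objects), the \code{geometry},
#'   \code{config}, the drawn \code{population}, and a \code{catalogue}
#'   data frame. Each trial holds \code{counts} (bins x units),
#'   \code{positions} (bins x 2, cm), \code{epochs} (named list of 1-based
#'   bin-index vectors), and \code{condition}.
#' @examples
#' sess <- generate_session(generator_config(n_units = 8, n_trials = 12, seed = 1),
#'                          task_geometry())
#' length(sess$trials)
#' @export
generate_session <- function(config, geometry) {
  stopifnot(inherits(config, "oa_config"), inherits(geometry, "oa_geometry"))
  set.seed(config$seed)
  pop <- draw_population(config)
  cat_all <- do.call(rbind, lapply(config$starts, function(s)
    regime_catalogue(geometry, s)))
  n_cond <- nrow(cat_all)
  # balanced condition sequence, shuffled
  reps <- ceiling(config$n_trials / n_cond)
  cond_idx <- sample(rep(seq_len(n_cond), reps)[seq_len(config$n_trials)])
  trials <- vector("list", config$n_trials)
  for (k in seq_len(config$n_trials)) {
    cnd <- cat_all[cond_idx[k], ]
    d2 <- sample(config$delay2_bins_range[1]:config$delay2_bins_range[2], 1)
    mv <- sample(config$move_bins_range[1]:config$move_bins_range[2], 1)
    lens <- c(rest = config$rest_bins, delay1 = config$delay1_bins,
              delay2 = d2, movement = mv, hold = config$hold_bins)
    ends <- cumsum(lens)
    epochs <- Map(function(e, l) seq.int(e - l + 1L, e), ends, lens)
    T_bins <- ends[length(ends)]
    start_pos <- geometry$positions[[cnd$start]]
    tgt_pos <- geometry$positions[[cnd$target]]
    positions <- matrix(rep(start_pos, each = T_bins), T_bins, 2)
    jitter_sd <- min(config$kinematic_noise_sd, 0.05)
    still <- c(epochs$rest, epochs$delay1, epochs$delay2)
    positions[still, ] <- positions[still, ] +
      matrix(stats::rnorm(2 * length(still), sd = jitter_sd), ncol = 2)
    positions[epochs$movement, ] <- generate_trajectory(
      geometry, cnd$start, cnd$target, cnd$opening, mv,
      noise_sd = config$kinematic_noise_sd)
    positions[epochs$hold, ] <- matrix(rep(tgt_pos, each = config$hold_bins),
                                       ncol = 2) +
      matrix(stats::rnorm(2 * config$hold_bins, sd = jitter_sd), ncol = 2)
    rate <- trial_rate_matrix(pop, config, geometry, cnd$start, cnd$target,
                              cnd$opening, epochs, positions)
    counts <- rate + matrix(stats::rnorm(length(rate), sd = config$count_sd),
                            nrow(rate), ncol(rate))
    if (config$round_counts) counts <- pmax(round(counts), 0)
    trials[[k]] <- structure(list(
      counts = counts, positions = positions, epochs = epochs,
      condition = list(start = cnd$start, target = cnd$target,
                       opening = cnd$opening, regime_id = cnd$regime_id),
      session_id = sprintf("synthetic-seed%d", config$seed),
      trial_id = k), class = "oa_trial")
  }
  structure(list(trials = trials, geometry = geometry, config = config,
                 population = pop, catalogue = cat_all),
            class = "oa_session")
}

#' @export
print.oa_session <- function(x, ...) {
  cat(sprintf("Synthetic obstacle-avoidance session: %d trials, %d units, starts: %s\n",
              length(x$trials), x$config$n_units,
              paste(x$config$starts, collapse = ", ")))
  invisible(x)
}

#' Validate a trial's epoch structure
#'
#' Checks the timeline invariants every trial must satisfy: epochs are
#' contiguous, non-overlapping, cover all bins in order
#' rest, delay 1, delay 2, movement, hold; delay 1 spans exactly 3 bins
#' (300 ms) and delay 2 spans 5 to 8 bins (500--800 ms); counts are
#' non-negative with one row per bin.
#'
#' @param trial an \code{oa_trial}.
#' @return Invisibly \code{TRUE}; stops with a message on violation.
#' @export
validate_trial <- function(trial) {
  ep <- trial$epochs
  need <- c("rest", "delay1", "delay2", "movement", "hold")
  if (!all(need %in% names(ep))) stop("missing epoch: ",
                                      paste(setdiff(need, names(ep)), collapse = ", "))
  flat <- unlist(ep[need], use.names = FALSE)
  T_bins <- nrow(trial$counts)
  if (!identical(as.integer(flat), seq_len(T_bins)))
    stop("epoch ranges must be contiguous, non-overlapping and cover all bins")
  if (length(ep$delay1) != 3L) stop("delay 1 must span exactly 3 bins")
  if (length(ep$delay2) < 5L || length(ep$delay2) > 8L)
    stop("delay 2 must span 5-8 bins")
  if (nrow(trial$positions) != T_bins) stop("positions/counts bin mismatch")
  if (any(trial$counts < 0)) stop("negative spike counts")
  invisible(TRUE)
}
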