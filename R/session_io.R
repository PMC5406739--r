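# Plain-text session serialization: a JSON sidecar holding the metadata
# (bin width, unit count, per-trial epoch ranges and condition labels,
# geometry parameters) plus one CSV per trial with the counts and the two
# position columns. The round-trip is lossless for everything downstream
# analyses consume.

SESSION_FORMAT_VERSION <- 1L

#' Write a session to disk
#'
#' Creates \code{dir/session.json} and \code{dir/trial_XXXX.csv} files.
#' Each trial CSV holds one row per 100 ms bin with columns
#' \code{unit_1..unit_n, pos_x, pos_y}; epochs and condition labels live
#' in the sidecar.
#'
#' @param session an \code{oa_session}, or a bare list of trials.
#' @param dir output directory (created if needed).
#' @return invisibly \code{dir}.
#' @export
write_session <- function(session, dir) {
  trials <- if (inherits(session, "oa_session")) session$trials else session
  geometry <- if (inherits(session, "oa_session")) session$geometry else NULL
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "mtmdecode-session", version = SESSION_FORMAT_VERSION,
    bin_ms = 100, n_units = ncol(trials[[1]]$counts),
    n_trials = length(trials),
    geometry = if (!is.null(geometry)) list(
      workspace = geometry$workspace, target_radius = geometry$target_radius,
      obstacle_halfwidth = geometry$obstacle_halfwidth,
      via_distance = geometry$via_distance,
      position_radius = sqrt(sum(geometry$positions$top^2)),
      hold_ms = geometry$hold_ms),
    trials = lapply(trials, function(tr) list(
      trial_id = tr$trial_id, session_id = tr$session_id,
      epochs = lapply(tr$epochs, function(e) c(min(e), max(e))),
      condition = tr$condition)))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    df <- as.data.frame(tr$counts)
    names(df) <- sprintf("unit_%d", seq_len(ncol(tr$counts)))
    df$pos_x <- tr$positions[, 1]
    df$pos_y <- tr$positions[, 2]
    utils::write.csv(df, file.path(dir, sprintf("trial_%04d.csv", i)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session from disk
#'
#' Validates the sidecar (format tag, version, epoch structure) and
#' reconstructs the trial list. Trials whose condition labels are absent
#' are read with the condition marked unknown (\code{NA} labels):
#' trajectory decoding still works, but label-dependent evaluation (e.g.
#' the task success check) will refuse them.
#'
#' @param dir directory written by [write_session()].
#' @return object of class \code{"oa_session"} (geometry reconstructed
#'   from the sidecar when present, otherwise the default geometry).
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) stop("no session.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  if (!identical(meta$format, "mtmdecode-session"))
    stop("parse error: field 'format' is not 'mtmdecode-session'")
  if (!identical(as.integer(meta$version), SESSION_FORMAT_VERSION))
    stop("session format version mismatch: file has ", meta$version,
         ", reader supports ", SESSION_FORMAT_VERSION)
  n_units <- as.integer(meta$n_units)
  geometry <- if (!is.null(meta$geometry)) {
    g <- meta$geometry
    task_geometry(workspace_cm = diff(as.numeric(g$workspace)),
                  position_radius = as.numeric(g$position_radius),
                  target_radius = as.numeric(g$target_radius),
                  obstacle_halfwidth = as.numeric(g$obstacle_halfwidth),
                  via_distance = as.numeric(g$via_distance),
                  hold_ms = as.numeric(g$hold_ms))
  } else task_geometry()
  trials <- vector("list", length(meta$trials))
  for (i in seq_along(meta$trials)) {
    mt <- meta$trials[[i]]
    df <- utils::read.csv(file.path(dir, sprintf("trial_%04d.csv", i)))
    ucols <- sprintf("unit_%d", seq_len(n_units))
    if (!all(c(ucols, "pos_x", "pos_y") %in% names(df)))
      stop("parse error in trial ", i, ": missing unit/position columns")
    epochs <- lapply(mt$epochs, function(e)
      seq.int(as.integer(e[[1]]), as.integer(e[[2]])))
    cond <- mt$condition
    if (is.null(cond) || is.null(cond$target)) {
      cond <- list(start = NA_character_, target = NA_character_,
                   opening = NA_character_, regime_id = NA_integer_)
    } else {
      cond <- list(start = cond$start, target = cond$target,
                   opening = cond$opening,
                   regime_id = as.integer(cond$regime_id))
    }
    trial <- structure(list(
      counts = as.matrix(df[, ucols]),
      positions = cbind(df$pos_x, df$pos_y),
      epochs = epochs,
      condition = cond,
      session_id = mt$session_id, trial_id = mt$trial_id),
      class = "oa_trial")
    flat <- unlist(epochs[c("rest", "delay1", "delay2", "movement", "hold")],
                   use.names = FALSE)
    if (anyDuplicated(flat) || !identical(as.integer(sort(flat)),
                                          seq_len(nrow(trial$counts))))
      stop("parse error in trial ", i,
           ": field 'epochs' has overlapping or non-covering ranges")
    trials[[i]] <- trial
  }
  structure(list(trials = trials, geometry = geometry, config = NULL,
                 population = NULL, catalogue = NULL),
            class = "oa_session")
}
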