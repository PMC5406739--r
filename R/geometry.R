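#' Task geometry for the delayed obstacle-avoidance reaching task
#'
#' Defines the 2D workspace, the four canonical cursor positions (bottom,
#' left, top, right), the obstacle placed between a start--target pair, and
#' the target acceptance radius. The workspace is a 20 x 20 cm square
#' centred at the origin; the four positions sit on the axes at
#' \code{position_radius} cm from the centre. For every start--target pair
#' the obstacle is an axis-aligned square centred on the midpoint of the
#' straight start-to-target segment, so a direct reach always collides and
#' the cursor must pass on one side (clockwise or counterclockwise).
#'
#' @param workspace_cm side length of the square workspace, cm.
#' @param position_radius distance of the four canonical positions from the
#'   workspace centre, cm.
#' @param target_radius acceptance radius around the target centre, cm.
#' @param obstacle_halfwidth half side length of the square obstacle, cm.
#' @param via_distance distance of the avoidance via-point from the obstacle
#'   centre, perpendicular to the start--target segment, cm.
#' @param hold_ms required hold time at the target, ms.
#'
#' @return An object of class \code{"oa_geometry"}: a list with the
#'   workspace extent, a named list \code{positions} of 2-vectors, and the
#'   obstacle/target parameters.
#' @examples
#' geom <- task_geometry()
#' geom$positions$top
#' @export
task_geometry <- function(workspace_cm = 20, position_radius = 6,
                          target_radius = 1.5, obstacle_halfwidth = 1.2,
                          via_distance = 3.5, hold_ms = 500) {
  stopifnot(workspace_cm > 0, position_radius > 0, target_radius > 0,
            obstacle_halfwidth > 0, via_distance > obstacle_halfwidth)
  if (position_radius >= workspace_cm / 2)
    stop("canonical positions must lie strictly inside the workspace")
  r <- position_radius
  geom <- list(
    workspace = c(-workspace_cm / 2, workspace_cm / 2),
    positions = list(bottom = c(0, -r), left = c(-r, 0),
                     top = c(0, r), right = c(r, 0)),
    target_radius = target_radius,
    obstacle_halfwidth = obstacle_halfwidth,
    via_distance = via_distance,
    hold_ms = hold_ms)
  class(geom) <- "oa_geometry"
  geom
}

#' @export
print.oa_geometry <- function(x, ...) {
  cat("Obstacle-avoidance task geometry\n")
  cat(sprintf("  workspace: [%g, %g] cm per axis\n", x$workspace[1], x$workspace[2]))
  cat(sprintf("  positions: %s at %g cm from centre\n",
              paste(names(x$positions), collapse = ", "),
              sqrt(sum(x$positions$top^2))))
  cat(sprintf("  obstacle half-width %g cm, target radius %g cm\n",
              x$obstacle_halfwidth, x$target_radius))
  invisible(x)
}

position_labels <- c("bottom", "left", "top", "right")

#' Axis-aligned obstacle rectangle for a start--target pair
#'
#' The obstacle is a square of half side \code{geometry$obstacle_halfwidth}
#' centred on the midpoint of the straight segment from start to target, so
#' it always intersects the direct path.
#'
#' @param geometry an \code{oa_geometry}.
#' @param start,target position labels (\code{"bottom"}, \code{"left"},
#'   \code{"top"}, \code{"right"}).
#' @return Named numeric vector \code{c(xmin, xmax, ymin, ymax)}.
#' @export
obstacle_rect <- function(geometry, start, target) {
  stopifnot(inherits(geometry, "oa_geometry"))
  p0 <- geometry$positions[[start]]
  p1 <- geometry$positions[[target]]
  if (is.null(p0) || is.null(p1)) stop("unknown position label")
  if (identical(start, target)) stop("start and target must differ")
  mid <- (p0 + p1) / 2
  h <- geometry$obstacle_halfwidth
  c(xmin = mid[1] - h, xmax = mid[1] + h, ymin = mid[2] - h, ymax = mid[2] + h)
}

#' Catalogue of movement regimes (conditions)
#'
#' Enumerates the task conditions: for each start position there are three
#' possible targets (the remaining canonical positions) and two obstacle
#' openings, i.e. six movement regimes per start and 24 conditions in all.
#' Within a start, \code{regime_id} is assigned deterministically: targets
#' are ordered bottom < left < top < right (the start itself excluded) and
#' \code{regime_id = 2 * (target_index - 1) + opening_index} with opening
#' clockwise = 1, counterclockwise = 2. The map (target, opening) ->
#' regime_id is therefore a bijection onto 1..6 for a fixed start.
#'
#' @param geometry an \code{oa_geometry}.
#' @param start optional position label; if given, only that start's six
#'   conditions are returned.
#' @param target optional target label filter.
#' @return A data frame with columns \code{start}, \code{target},
#'   \code{opening} (\code{"cw"}/\code{"ccw"}) and \code{regime_id}.
#' @examples
#' nrow(regime_catalogue(task_geometry()))            # 24
#' nrow(regime_catalogue(task_geometry(), "bottom"))  # 6
#' @export
regime_catalogue <- function(geometry, start = NULL, target = NULL) {
  stopifnot(inherits(geometry, "oa_geometry"))
  starts <- if (is.null(start)) position_labels else match.arg(start, position_labels)
  rows <- list()
  for (s in starts) {
    targets <- setdiff(position_labels, s)
    for (ti in seq_along(targets)) {
      for (oi in 1:2) {
        opening <- c("cw", "ccw")[oi]
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, target = targets[ti], opening = opening,
          regime_id = 2L * (ti - 1L) + oi,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(target)) out <- out[out$target == target, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up the regime id of a (start, target, opening) triple
#' @param catalogue a data frame from [regime_catalogue()].
#' @param start,target,opening condition labels.
#' @return Integer regime id in 1..6.
#' @export
regime_id_for <- function(catalogue, start, target, opening) {
  hit <- catalogue$start == start & catalogue$target == target &
    catalogue$opening == opening
  if (sum(hit) != 1L) stop(sprintf("condition (%s, %s, %s) not in catalogue",
                                   start, target, opening))
  catalogue$regime_id[hit]
}

# Unit vector from start to target and its ccw-rotated normal.
#' @keywords internal
#' @noRd
segment_frame <- function(geometry, start, target) {
  p0 <- geometry$positions[[start]]
  p1 <- geometry$positions[[target]]
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  u <- d / len
  list(p0 = p0, p1 = p1, mid = (p0 + p1) / 2, u = u,
       normal_ccw = c(-u[2], u[1]), length = len)
}

#' Avoidance via-point for a condition
#'
#' The via-point sits \code{geometry$via_distance} cm from the obstacle
#' centre, perpendicular to the start--target segment: on the left of the
#' direction of travel for a counterclockwise opening, on the right for a
#' clockwise one.
#' @param geometry an \code{oa_geometry}.
#' @param start,target,opening condition labels.
#' @return 2-vector, cm.
#' @export
via_point <- function(geometry, start, target, opening) {
  fr <- segment_frame(geometry, start, target)
  n <- if (opening == "ccw") fr$normal_ccw else -fr$normal_ccw
  fr$mid + geometry$via_distance * n
}
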