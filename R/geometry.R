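#' Arena geometry: feeders, quadrants and reward zones
#'
#' The arena floor is normalised to the unit square with the origin at the
#' lower-left corner and y increasing upward. Quadrants are numbered
#' 1 = (low x, low y), 2 = (high x, low y), 3 = (low x, high y),
#' 4 = (high x, high y). One feeder sits in each quadrant and delivers one of
#' four sucrose concentrations; the quadrant-to-reward-level map records which.
#'
#' A "reward zone" is either the full quadrant containing a feeder
#' (`zone_mode = "quadrant"`) or a disc of radius `zone_radius` centred on the
#' feeder (`zone_mode = "disc"`, the default).
#'
#' @param feeders A 4-row data frame with columns `quadrant`, `x`, `y`
#'   (normalised coordinates), one feeder per quadrant. Default: feeders at
#'   (0.2, 0.2), (0.8, 0.2), (0.2, 0.8), (0.8, 0.8).
#' @param zone_mode `"disc"` or `"quadrant"`.
#' @param zone_radius Disc radius in normalised units (disc mode only).
#' @param reward_map Integer vector of length 4: reward level (1-4) offered at
#'   quadrants 1-4.
#' @return An object of class `arena_geometry`.
#' @export
#' @examples
#' geom <- arena_geometry()
#' in_reward_zone(0.21, 0.19, quadrant = 1, geometry = geom)
arena_geometry <- function(feeders = NULL,
                           zone_mode = c("disc", "quadrant"),
                           zone_radius = 0.18,
                           reward_map = 1:4) {
  zone_mode <- match.arg(zone_mode)
  if (is.null(feeders)) {
    feeders <- tibble::tibble(
      quadrant = 1:4,
      x = c(0.2, 0.8, 0.2, 0.8),
      y = c(0.2, 0.2, 0.8, 0.8)
    )
  }
  feeders <- tibble::as_tibble(feeders)
  if (!all(c("quadrant", "x", "y") %in% names(feeders))) {
    stopf("`feeders` must have columns quadrant, x, y")
  }
  if (nrow(feeders) != 4L || !setequal(feeders$quadrant, 1:4)) {
    stopf("exactly 4 feeders are required, one per quadrant 1-4")
  }
  if (any(feeders$x < 0 | feeders$x > 1 | feeders$y < 0 | feeders$y > 1)) {
    stopf("feeder coordinates must lie in [0, 1]")
  }
  if (zone_mode == "disc" && (!is.numeric(zone_radius) || zone_radius <= 0)) {
    stopf("`zone_radius` must be > 0 in disc mode")
  }
  if (length(reward_map) != 4L || !setequal(reward_map, 1:4)) {
    stopf("`reward_map` must be a permutation of 1:4")
  }
  ok <- quadrant_of(feeders$x, feeders$y) == feeders$quadrant
  if (!all(ok)) {
    stopf("feeder(s) %s do not lie in their declared quadrant",
          paste(feeders$quadrant[!ok], collapse = ", "))
  }
  structure(
    list(
      feeders = dplyr::arrange(feeders, .data$quadrant),
      zone_mode = zone_mode,
      zone_radius = if (zone_mode == "disc") zone_radius else NA_real_,
      reward_map = as.integer(reward_map)
    ),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("<arena_geometry>", x$zone_mode, "reward zones")
  if (x$zone_mode == "disc") cat(sprintf(" (r = %.3g)", x$zone_radius))
  cat("\n")
  print(x$feeders)
  invisible(x)
}

#' Quadrant index of normalised positions
#'
#' @param x,y Numeric vectors of normalised coordinates.
#' @return Integer vector in 1-4 (1 = low x/low y, 2 = high x/low y,
#'   3 = low x/high y, 4 = high x/high y).
#' @export
quadrant_of <- function(x, y) {
  1L + (x >= 0.5) + 2L * (y >= 0.5)
}

#' Reward-zone membership
#'
#' @param x,y Normalised positions.
#' @param quadrant Quadrant (1-4) whose zone is tested, or `NULL` to test
#'   membership in any of the four zones.
#' @param geometry An [arena_geometry()].
#' @return Logical vector.
#' @export
in_reward_zone <- function(x, y, quadrant = NULL, geometry = arena_geometry()) {
  stopifnot(inherits(geometry, "arena_geometry"))
  if (is.null(quadrant)) {
    res <- rep(FALSE, length(x))
    for (q in 1:4) res <- res | in_reward_zone(x, y, q, geometry)
    return(res)
  }
  if (geometry$zone_mode == "quadrant") {
    quadrant_of(x, y) == quadrant
  } else {
    f <- geometry$feeders[geometry$feeders$quadrant == quadrant, ]
    sqrt((x - f$x)^2 + (y - f$y)^2) <= geometry$zone_radius
  }
}

geometry_to_list <- function(g) {
  list(
    feeders = as.data.frame(g$feeders),
    zone_mode = g$zone_mode,
    zone_radius = g$zone_radius,
    reward_map = g$reward_map
  )
}

geometry_from_list <- function(l) {
  arena_geometry(
    feeders = as.data.frame(l$feeders),
    zone_mode = l$zone_mode,
    zone_radius = if (identical(l$zone_mode, "disc")) l$zone_radius else 0.18,
    reward_map = unlist(l$reward_map)
  )
}
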