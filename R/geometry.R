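#' Wrap angles to (-pi, pi]
#'
#' All headings and relative angles in the package live on (-pi, pi],
#' counterclockwise-positive. This is the single wrapping convention used
#' by the geometry, the model and the inference code.
#'
#' @param a numeric vector of angles (rad).
#' @return numeric vector of the same length, wrapped to (-pi, pi].
#' @export
wrap_angle <- function(a) {
  vapply(a, cpp_wrap_angle, numeric(1))
}

#' Circular tank geometry
#'
#' @param radius tank radius in metres (> 0).
#' @param bounded logical; `FALSE` switches to open-space mode in which
#'   wall terms vanish and positions are unconstrained.
#' @return an object of class `tank_geometry` with fields `center`
#'   (always the origin of the tank-centred frame), `radius`, `bounded`.
#' @export
tank_geometry <- function(radius = 2, bounded = TRUE) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(center = c(0, 0), radius = radius, bounded = isTRUE(bounded)),
            class = "tank_geometry")
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf("Circular tank: radius %.3g m (%s)\n", x$radius,
              if (x$bounded) "bounded" else "open space"))
  invisible(x)
}

#' State of one fish
#'
#' @param position numeric length-2, tank-centred Cartesian metres.
#' @param heading heading angle (rad), wrapped to (-pi, pi].
#' @param omega angular velocity (rad/s).
#' @param speed tangential speed (m/s, > 0).
#' @return an object of class `fish_state`.
#' @export
fish_state <- function(position, heading, omega = 0, speed = 0.5) {
  stopifnot(length(position) == 2, is.finite(position),
            is.finite(heading), is.finite(omega), speed > 0)
  structure(list(position = as.numeric(position),
                 heading = wrap_angle(heading),
                 omega = as.numeric(omega), speed = as.numeric(speed)),
            class = "fish_state")
}

#' Wall-impact stimulus
#'
#' Distance along the current heading ray to the tank wall, the signed
#' angle between the heading and the outward normal at that impact point
#' (0 = head-on approach; positive = heading rotated counterclockwise
#' from the normal), and the time to impact at the current speed.
#'
#' @param state a [fish_state()].
#' @param tank a [tank_geometry()]; must be bounded.
#' @return list with `dist_to_impact` (m), `angle_to_normal` (rad, always
#'   strictly inside (-pi/2, pi/2)), `time_to_impact` (s), and
#'   `dist_to_wall` (m), the closest distance to the wall, `R - |x|`.
#' @export
wall_impact <- function(state, tank) {
  stopifnot(inherits(state, "fish_state"), inherits(tank, "tank_geometry"))
  if (!tank$bounded)
    stop("wall_impact is undefined for an unbounded (open-space) tank")
  r <- sqrt(sum(state$position^2))
  if (r >= tank$radius)
    stop("wall_impact: position must be strictly inside the tank")
  m <- cpp_wall_impact(state$position[1], state$position[2], state$heading,
                       tank$radius)
  list(dist_to_impact = m[1, 1], angle_to_normal = m[1, 2],
       time_to_impact = m[1, 1] / state$speed,
       dist_to_wall = tank$radius - r)
}

#' Pairwise geometric stimuli
#'
#' Distance, bearing and relative heading of fish `other` as seen by
#' fish `focal`: the three variables the pair interaction depends on.
#' The bearing `psi` is the angle from the focal heading to the direction
#' of the neighbour's position; `phi` is the wrapped heading difference.
#'
#' @param focal,other [fish_state()] objects.
#' @return list with `distance` (m), `bearing` (rad), `heading_diff`
#'   (rad), and `coincident` (logical; `TRUE` when the two positions
#'   coincide, in which case `bearing` is defined as 0).
#' @export
pair_stimuli <- function(focal, other) {
  stopifnot(inherits(focal, "fish_state"), inherits(other, "fish_state"))
  dvec <- other$position - focal$position
  d <- sqrt(sum(dvec^2))
  coincident <- d == 0
  if (coincident) {
    warning("coincident positions: bearing defined as 0")
    psi <- 0
  } else {
    psi <- wrap_angle(atan2(dvec[2], dvec[1]) - focal$heading)
  }
  phi <- wrap_angle(other$heading - focal$heading)
  list(distance = d, bearing = psi, heading_diff = phi,
       coincident = coincident)
}

#' Topological interaction network
#'
#' Neighbour sets for a configuration of positions. `"all"` gives the
#' complete graph; `"voronoi_shell1"` the first shell of Voronoi
#' neighbours (pairs whose Voronoi cells share an edge of positive
#' length, computed by the exact bisector half-plane test, which reduces
#' to chain adjacency for collinear configurations); `"knn"` each fish's
#' `K` nearest neighbours by Euclidean distance (a directed graph).
#'
#' @param positions an N x 2 numeric matrix of positions (N >= 2).
#' @param method one of `"all"`, `"voronoi_shell1"`, `"knn"`.
#' @param K neighbour count for `method = "knn"`; capped at N - 1.
#' @return object of class `neighbor_graph`: list with `neighbors` (list
#'   of integer index vectors), `counts`, `method`, and the logical
#'   `adjacency` matrix (rows = focal fish).
#' @export
neighbor_graph <- function(positions,
                           method = c("all", "voronoi_shell1", "knn"),
                           K = NULL) {
  method <- match.arg(method)
  positions <- as.matrix(positions)
  if (nrow(positions) < 2)
    stop("neighbor_graph needs at least 2 positions")
  if (ncol(positions) != 2)
    stop("positions must be an N x 2 matrix")
  adj <- switch(method,
    all = {
      n <- nrow(positions)
      matrix(TRUE, n, n) & !diag(TRUE, n)
    },
    voronoi_shell1 = cpp_voronoi_adjacency(positions[, 1], positions[, 2]),
    knn = {
      if (is.null(K) || K < 1) stop("method 'knn' requires K >= 1")
      cpp_knn_adjacency(positions[, 1], positions[, 2], as.integer(K))
    })
  nb <- apply(adj, 1, which, simplify = FALSE)
  structure(list(neighbors = nb, counts = lengths(nb),
                 method = if (method == "knn") paste0("knn:", K) else method,
                 adjacency = adj),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph (%s): %d fish, mean degree %.2f\n",
              x$method, length(x$counts), mean(x$counts)))
  invisible(x)
}

# internal: map a user-facing method string to the C++ code + K
graph_method_code <- function(method) {
  if (startsWith(method, "knn")) {
    K <- as.integer(sub("^knn:?", "", method))
    if (is.na(K) || K < 1) stop("knn method must be written 'knn:K' with K >= 1")
    return(list(code = 2L, K = K))
  }
  switch(method,
         all = list(code = 0L, K = 0L),
         voronoi_shell1 = list(code = 1L, K = 0L),
         stop("unknown neighborhood method: ", method))
}
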