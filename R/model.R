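#' Behavioural model parameters
#'
#' The five behavioural constants of the stimulus/response model, their
#' speed-scaling exponents, and numerical options. The target turning
#' speed of fish i is
#'
#'   omega* = f_wall + (1/N_i) sum_j (k_p v^a_p d_ij sin psi_ij
#'                                    + k_v v^a_v sin phi_ij)
#'
#' with `f_wall = k_w cos(theta_w) sign(theta_w) exp(-d_wall / d_w) / T`,
#' `T` the time to impact (default) or the distance to impact, `d_wall`
#' the distance to the wall, `d_w` the wall screening range, and the
#' angular velocity relaxes toward omega* on the timescale
#' `tau = l / v`.
#'
#' @param wall_strength k_w, wall response scale (rad with the
#'   time-to-impact parameterisation).
#' @param persistence_length l (m); the relaxation time of the angular
#'   velocity is `tau = l / v`.
#' @param noise_scale sigma (rad s^-3/2), scale of the Wiener increments.
#' @param attract_coeff k_p, weight of the positional (attraction) term.
#' @param align_coeff k_v, weight of the orientational (alignment) term.
#' @param speed_exponents integer vector `(a_w, a_p, a_v)` in \{0, 1\}:
#'   exponent of the focal speed multiplying each coefficient. With the
#'   default time-to-impact wall mode the wall term's speed dependence is
#'   carried by `1/T = v/D` itself and `a_w` only applies when
#'   `wall_mode = "distance"`.
#' @param wall_mode `"time_to_impact"` (default) or `"distance"`:
#'   whether the wall response magnitude is divided by the time or the
#'   distance to impact.
#' @param wall_range screening length (m) of the wall response in the
#'   distance to the wall: the response carries a factor
#'   `exp(-d_wall / wall_range)`, so wall avoidance is a near-wall
#'   behaviour rather than a tank-wide forcing, while the `1/T` factor
#'   still diverges at contact and guarantees containment.
#' @param attract_sat optional saturation distance (m) for the attraction
#'   term, `d_eff = attract_sat * tanh(d / attract_sat)`; `Inf` (default)
#'   keeps the linear dependence on distance. Intended for open-space
#'   runs where the linear form would diverge.
#' @return object of class `model_params`.
#' @export
model_params <- function(wall_strength = 40,
                         persistence_length = 0.5,
                         noise_scale = 1.2,
                         attract_coeff = 4,
                         align_coeff = 3,
                         speed_exponents = c(1L, 1L, 1L),
                         wall_mode = c("time_to_impact", "distance"),
                         wall_range = 0.3,
                         attract_sat = Inf) {
  wall_mode <- match.arg(wall_mode)
  speed_exponents <- as.integer(speed_exponents)
  stopifnot(persistence_length > 0, noise_scale >= 0,
            length(speed_exponents) == 3,
            all(speed_exponents %in% c(0L, 1L)),
            is.finite(c(wall_strength, attract_coeff, align_coeff)),
            attract_sat > 0, wall_range > 0)
  structure(list(wall_strength = wall_strength,
                 persistence_length = persistence_length,
                 noise_scale = noise_scale,
                 attract_coeff = attract_coeff,
                 align_coeff = align_coeff,
                 speed_exponents = speed_exponents,
                 wall_mode = wall_mode,
                 wall_range = wall_range,
                 attract_sat = attract_sat),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Persistent-turning-walker model parameters\n")
  cat(sprintf("  k_w = %.4g  l = %.4g m  sigma = %.4g  k_p = %.4g  k_v = %.4g\n",
              x$wall_strength, x$persistence_length, x$noise_scale,
              x$attract_coeff, x$align_coeff))
  cat(sprintf("  speed exponents (w,p,v) = (%d,%d,%d), wall mode = %s\n",
              x$speed_exponents[1], x$speed_exponents[2],
              x$speed_exponents[3], x$wall_mode))
  if (is.finite(x$attract_sat))
    cat(sprintf("  attraction saturation distance = %.4g m\n", x$attract_sat))
  invisible(x)
}

#' Wall-avoidance component of the target turning speed
#'
#' `k_w cos(theta_w) * s * exp(-d_wall / d_w) / T` with turning sign
#' `s = sign(theta_w)`, which turns so that `|theta_w|` grows, steering
#' the fish away from a head-on approach. The `1/T` factor diverges as
#' the time to impact vanishes, so the model itself keeps fish inside
#' the tank, while the exponential screening in the distance to the
#' wall (`d_w = wall_range`) confines wall avoidance to the near-wall
#' region. At exactly
#' `theta_w = 0` (a measure-zero configuration, e.g. a fish at the
#' centre) the sign is drawn uniformly from \{-1, +1\}.
#'
#' @param wall a wall stimulus as returned by [wall_impact()].
#' @param speed focal fish speed (m/s).
#' @param params a [model_params()].
#' @return wall component (rad/s).
#' @export
wall_response <- function(wall, speed, params) {
  stopifnot(inherits(params, "model_params"))
  if (wall$time_to_impact <= 0)
    stop("fish on the wall: time to impact is not positive")
  thw <- wall$angle_to_normal
  s <- sign(thw)
  if (s == 0) s <- sample(c(-1, 1), 1)
  g <- cos(thw) * s
  screen <- exp(-wall$dist_to_wall / params$wall_range)
  if (params$wall_mode == "time_to_impact") {
    params$wall_strength * g * screen / wall$time_to_impact
  } else {
    vfac <- if (params$speed_exponents[1] == 1L) speed else 1
    params$wall_strength * vfac * g * screen / wall$dist_to_impact
  }
}

#' Attraction and alignment components for one neighbour
#'
#' Attraction `k_p v^a_p d sin(psi)` (zero when the neighbour is dead
#' ahead or coincident) and alignment `k_v v^a_v sin(phi)` (zero when
#' already aligned). Attraction does not depend on the neighbour's
#' heading, alignment does not depend on its position.
#'
#' @param pair a pair stimulus as returned by [pair_stimuli()].
#' @param speed focal fish speed (m/s).
#' @param params a [model_params()].
#' @return list with `attraction` and `alignment` (rad/s).
#' @export
pair_response <- function(pair, speed, params) {
  stopifnot(inherits(params, "model_params"))
  vp <- if (params$speed_exponents[2] == 1L) speed else 1
  vv <- if (params$speed_exponents[3] == 1L) speed else 1
  d <- pair$distance
  if (is.finite(params$attract_sat))
    d <- params$attract_sat * tanh(d / params$attract_sat)
  list(attraction = params$attract_coeff * vp * d * sin(pair$bearing),
       alignment = params$align_coeff * vv * sin(pair$heading_diff))
}

#' Target turning speed of a focal fish
#'
#' Combines the wall response with the neighbour-averaged attraction and
#' alignment over the focal fish's neighbour set: the social sum is
#' normalised by the neighbour count so that wall avoidance and the
#' averaged influence of neighbours keep the same relative weight at any
#' group size. An isolated fish has a zero social term; in an unbounded
#' tank the wall term is zero.
#'
#' @param focal index of the focal fish in `states`.
#' @param states list of [fish_state()] objects for the whole group.
#' @param graph a [neighbor_graph()] over the same fish (or `NULL` for a
#'   single fish).
#' @param tank a [tank_geometry()].
#' @param params a [model_params()].
#' @return list with `total`, `wall`, `attraction`, `alignment` (rad/s);
#'   `total` is exactly the sum of the three components.
#' @export
target_turning_speed <- function(focal, states, graph, tank, params) {
  stopifnot(inherits(tank, "tank_geometry"), inherits(params, "model_params"))
  n <- length(states)
  if (!is.null(graph)) {
    if (length(graph$counts) != n)
      stop("graph and states describe different numbers of fish")
    if (focal < 1 || focal > n) stop("focal index out of range")
  }
  st <- states[[focal]]
  w <- if (tank$bounded) {
    wall_response(wall_impact(st, tank), st$speed, params)
  } else 0
  att <- 0; ali <- 0
  nb <- if (is.null(graph)) integer(0) else graph$neighbors[[focal]]
  if (length(nb) > 0) {
    for (j in nb) {
      pr <- pair_response(pair_stimuli(st, states[[j]]), st$speed, params)
      att <- att + pr$attraction
      ali <- ali + pr$alignment
    }
    att <- att / length(nb)
    ali <- ali / length(nb)
  }
  list(total = w + att + ali, wall = w, attraction = att, alignment = ali)
}
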