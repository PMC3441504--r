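#' Simulation configuration
#'
#' @param tank a [tank_geometry()].
#' @param n_fish group size N.
#' @param params a [model_params()].
#' @param speeds per-fish constant speed (m/s); a scalar is recycled.
#' @param dt requested integration step (s). The step actually used is
#'   the nearest exact submultiple of the output frame interval, so that
#'   saved frames fall exactly on the integration grid (e.g. 0.02 s at
#'   12 fps becomes 1/48 s).
#' @param duration simulated time kept after the transient (s).
#' @param transient initial time discarded before sampling (s).
#' @param method neighbourhood method: `"all"`, `"voronoi_shell1"` or
#'   `"knn:K"`.
#' @param output_fps sampling rate of the returned trajectory table.
#' @param init optional explicit initial condition: list with numeric
#'   vectors `x`, `y`, `heading` and optionally `omega` (default 0).
#'   When omitted, positions are drawn uniformly in the disc of radius
#'   `init_radius_frac * radius`, headings uniformly on (-pi, pi], and
#'   omega starts at 0.
#' @param init_radius_frac fraction of the tank radius used for random
#'   initial positions.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(tank = tank_geometry(), n_fish = 2,
                       params = model_params(), speeds = 0.5, dt = 0.02,
                       duration = 120, transient = 20, method = "all",
                       output_fps = 12, init = NULL,
                       init_radius_frac = 0.8) {
  stopifnot(inherits(tank, "tank_geometry"), inherits(params, "model_params"),
            n_fish >= 1, dt > 0, duration > 0, transient >= 0,
            output_fps > 0, dt <= 1 / output_fps + 1e-12)
  speeds <- rep_len(as.numeric(speeds), n_fish)
  stopifnot(all(speeds > 0))
  graph_method_code(method)  # validate early
  structure(list(tank = tank, n_fish = as.integer(n_fish), params = params,
                 speeds = speeds, dt = dt, duration = duration,
                 transient = transient, method = method,
                 output_fps = output_fps, init = init,
                 init_radius_frac = init_radius_frac),
            class = "sim_config")
}

# integration grid implied by a config: effective dt, save stride,
# number of output frames and transient steps
sim_grid <- function(config) {
  stride <- max(1L, as.integer(round(1 / (config$output_fps * config$dt))))
  dt_eff <- 1 / (config$output_fps * stride)
  n_frames <- as.integer(round(config$duration * config$output_fps))
  n_transient <- as.integer(round(config$transient / dt_eff))
  list(dt = dt_eff, stride = stride, n_frames = n_frames,
       n_transient = n_transient,
       n_steps = n_transient + (n_frames - 1L) * stride)
}

# draw or validate initial states; consumes the R RNG when drawing
init_states <- function(config) {
  n <- config$n_fish
  if (!is.null(config$init)) {
    ini <- config$init
    stopifnot(length(ini$x) == n, length(ini$y) == n,
              length(ini$heading) == n)
    om <- if (is.null(ini$omega)) rep(0, n) else rep_len(ini$omega, n)
    return(list(x = as.numeric(ini$x), y = as.numeric(ini$y),
                theta = wrap_angle(ini$heading), omega = as.numeric(om)))
  }
  r <- config$init_radius_frac * config$tank$radius * sqrt(stats::runif(n))
  a <- stats::runif(n, -pi, pi)
  list(x = r * cos(a), y = r * sin(a),
       theta = stats::runif(n, -pi, pi), omega = rep(0, n))
}

#' Run the school simulation
#'
#' Integrates the coupled angular-velocity Ornstein-Uhlenbeck equations
#' with Euler-Maruyama stepping: each fish's omega relaxes toward its
#' stimulus-dependent target on the timescale `tau = l / v` with Wiener
#' noise of scale sigma, headings and positions follow by Euler
#' integration at constant speed. The neighbour graph is recomputed at
#' every step. A position that lands outside a bounded tank is radially
#' projected back to just inside the wall and the event counted; the
#' fitted wall term is expected to make such projections non-events, and
#' a warning is raised if they exceed 0.1% of fish-steps.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (`set.seed` is called when given);
#'   runs are bit-reproducible for a fixed seed.
#' @param speed_schedule optional numeric vector of a common speed per
#'   integration step (length >= total steps), overriding `speeds`; see
#'   [make_speed_schedule()].
#' @return a track table: `data.frame` with columns `t` (s), `id`
#'   (0-based), `x`, `y` (m), `heading` (rad), `omega` (rad/s), sampled
#'   at `output_fps`, with attributes `fps`, `tank`, `n_proj` (boundary
#'   projection count) and `dt` (effective step).
#' @export
simulate_school <- function(config, seed = NULL, speed_schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  g <- sim_grid(config)
  st <- init_states(config)
  mc <- graph_method_code(config$method)
  sched <- if (is.null(speed_schedule)) numeric(0) else as.numeric(speed_schedule)
  res <- cpp_simulate(st$x, st$y, st$theta, st$omega, config$speeds, sched,
                      unclass(config$params), config$tank$radius,
                      config$tank$bounded, mc$code, mc$K, g$dt,
                      g$n_transient, g$n_frames, g$stride)
  frac <- res$n_proj / (g$n_steps * config$n_fish)
  if (frac > 0.001)
    warning(sprintf(paste0("boundary projections in %.2f%% of fish-steps: ",
                           "wall term too weak or dt too coarse"), 100 * frac))
  n <- config$n_fish
  tt <- data.frame(
    t = rep((seq_len(g$n_frames) - 1) / config$output_fps, times = n),
    id = rep(seq_len(n) - 1L, each = g$n_frames),
    x = as.vector(res$x), y = as.vector(res$y),
    heading = as.vector(res$theta), omega = as.vector(res$omega))
  attr(tt, "fps") <- config$output_fps
  attr(tt, "tank") <- config$tank
  attr(tt, "n_proj") <- res$n_proj
  attr(tt, "dt") <- g$dt
  tt
}

#' Piecewise-linear common speed schedule
#'
#' Builds the per-step speed vector consumed by
#' [simulate_school()]`(speed_schedule = )` from ramp knots: the common
#' speed is interpolated linearly between `(times, values)` and held
#' constant beyond the last knot.
#'
#' @param config the [sim_config()] the schedule is for (fixes the step
#'   grid, including the transient).
#' @param times knot times (s) counted from the start of the run
#'   (transient included), starting at 0.
#' @param values speed at each knot (m/s, > 0).
#' @return numeric vector with one common speed per integration step.
#' @export
make_speed_schedule <- function(config, times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1,
            all(diff(times) > 0), all(values > 0), times[1] >= 0)
  g <- sim_grid(config)
  tgrid <- (seq_len(g$n_steps) - 1) * g$dt
  stats::approx(times, values, xout = tgrid, rule = 2)$y
}

#' Group response to a change of swimming speed
#'
#' Simulates a group under a time-varying common speed (e.g. a slow ramp
#' from shoaling to schooling speeds, or an abrupt step) and returns the
#' track table together with the polarization and nearest-neighbour
#' distance time series, for studying the shoaling-to-schooling
#' transition and flash-expansion-like responses.
#'
#' @param config a [sim_config()] (typically open space with speed-scaled
#'   alignment and a finite `attract_sat`).
#' @param times,values ramp knots passed to [make_speed_schedule()].
#' @param seed optional integer seed.
#' @return list with `tracks`, and a `series` data.frame of `t`, `speed`
#'   (common speed at each output frame), `P` (polarization), `nnd`
#'   (mean nearest-neighbour distance).
#' @export
speed_schedule_scenario <- function(config, times, values, seed = NULL) {
  sched <- make_speed_schedule(config, times, values)
  tr <- simulate_school(config, seed = seed, speed_schedule = sched)
  fr <- track_frames(tr)
  g <- sim_grid(config)
  idx <- g$n_transient + (seq_len(g$n_frames) - 1L) * g$stride + 1L
  idx <- pmin(idx, length(sched))
  series <- data.frame(
    t = fr$t,
    speed = sched[idx],
    P = apply(fr$heading, 1, polarization),
    nnd = vapply(seq_len(nrow(fr$x)), function(f)
      mean_nearest_neighbor(cbind(fr$x[f, ], fr$y[f, ])), numeric(1)))
  list(tracks = tr, series = series)
}

#' Reshape a track table to per-frame matrices
#'
#' @param tracks a track table (`t`, `id`, `x`, `y`, optionally
#'   `heading`, `omega`).
#' @return list with vector `t` and frames x fish matrices `x`, `y` and,
#'   when present, `heading`, `omega`.
#' @export
track_frames <- function(tracks) {
  ids <- sort(unique(tracks$id))
  ts <- sort(unique(tracks$t))
  o <- order(tracks$id, tracks$t)
  tr <- tracks[o, ]
  nf <- length(ts)
  out <- list(t = ts,
              x = matrix(tr$x, nrow = nf),
              y = matrix(tr$y, nrow = nf))
  for (col in c("heading", "omega"))
    if (col %in% names(tr)) out[[col]] <- matrix(tr[[col]], nrow = nf)
  out$ids <- ids
  out
}

#' Advance a group of fish by one Euler-Maruyama step
#'
#' Single exposed integration step (the simulator applies exactly this
#' update in compiled code): omega relaxes toward the target turning
#' speed, then heading and position are updated with the new omega.
#'
#' @param states list of [fish_state()] objects.
#' @param params a [model_params()].
#' @param tank a [tank_geometry()].
#' @param method neighbourhood method string.
#' @param dt time step (s).
#' @return list of updated [fish_state()] objects; attribute `projected`
#'   counts boundary projections in this step.
#' @export
step_school <- function(states, params, tank, method = "all", dt = 0.02) {
  n <- length(states)
  graph <- if (n > 1) {
    pos <- t(vapply(states, function(s) s$position, numeric(2)))
    neighbor_graph(pos, sub(":.*", "", method),
                   K = graph_method_code(method)$K)
  } else NULL
  targets <- vapply(seq_len(n), function(i)
    target_turning_speed(i, states, graph, tank, params)$total, numeric(1))
  proj <- 0L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- states[[i]]
    tau <- params$persistence_length / s$speed
    om <- s$omega + (dt / tau) * (targets[i] - s$omega) +
      params$noise_scale * sqrt(dt) * stats::rnorm(1)
    if (!is.finite(om)) stop("non-finite angular velocity for fish ", i)
    th <- wrap_angle(s$heading + om * dt)
    p <- s$position + s$speed * c(cos(th), sin(th)) * dt
    if (tank$bounded) {
      r <- sqrt(sum(p^2))
      if (r >= tank$radius) {
        p <- p * (1 - 1e-6) * tank$radius / r
        proj <- proj + 1L
      }
    }
    out[[i]] <- fish_state(p, th, om, s$speed)
  }
  attr(out, "projected") <- proj
  out
}
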