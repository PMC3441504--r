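test_that("noise-free angular velocity decays geometrically", {
  # sigma = 0, open space, no neighbours: omega_n = omega_0 (1 - dt/tau)^n
  open <- tank_geometry(2, bounded = FALSE)
  p <- model_params(noise_scale = 0)
  v <- 0.5; om0 <- 1.3
  cfg <- sim_config(open, n_fish = 1, params = p, speeds = v, dt = 1 / 48,
                    duration = 2, transient = 0, output_fps = 48,
                    init = list(x = 0, y = 0, heading = 0, omega = om0))
  tr <- simulate_school(cfg, seed = 1)
  tau <- p$persistence_length / v
  n <- seq_len(nrow(tr)) - 1
  expect_equal(tr$omega, om0 * (1 - (1 / 48) / tau)^n, tolerance = 1e-10)
})

test_that("per-step displacement has norm exactly v dt", {
  cfg <- sim_config(n_fish = 3, speeds = c(0.3, 0.5, 0.9), dt = 1 / 48,
                    duration = 2, transient = 0, output_fps = 48)
  tr <- simulate_school(cfg, seed = 5)
  for (i in 0:2) {
    tri <- tr[tr$id == i, ]
    steps <- sqrt(diff(tri$x)^2 + diff(tri$y)^2)
    expect_equal(steps, rep(cfg$speeds[i + 1] / 48, length(steps)),
                 tolerance = 1e-12)
  }
})

test_that("constant forced turning traces a regular polygon on a circle", {
  # effectively infinite persistence keeps omega at its initial value;
  # the discrete path is then a regular polygon inscribed in a circle of
  # radius v dt / (2 sin(omega dt / 2))
  open <- tank_geometry(2, bounded = FALSE)
  p <- model_params(noise_scale = 0, persistence_length = 1e9)
  v <- 0.5; om <- 1.0; dt <- 1 / 48
  cfg <- sim_config(open, n_fish = 1, params = p, speeds = v, dt = dt,
                    duration = 10, transient = 0, output_fps = 48,
                    init = list(x = 0, y = 0, heading = 0, omega = om))
  tr <- simulate_school(cfg, seed = 1)
  expect_equal(diff(tr$heading[1:20]), rep(om * dt, 19), tolerance = 1e-9)
  # vertices z_n = A (e^{i n om dt} - 1), A = v dt e^{i om dt}/(e^{i om dt}-1),
  # so all points lie on the circle of radius |A| = v dt/(2 sin(om dt/2))
  # centred at -A (start at the origin, initial heading 0)
  r_poly <- v * dt / (2 * sin(om * dt / 2))
  A <- v * dt * exp(1i * om * dt) / (exp(1i * om * dt) - 1)
  rad <- Mod(complex(real = tr$x, imaginary = tr$y) + A)
  expect_lt(max(abs(rad - r_poly)), 1e-7)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_fish = 2, duration = 30, transient = 5,
                    method = "voronoi_shell1")
  t1 <- simulate_school(cfg, seed = 42)
  t2 <- simulate_school(cfg, seed = 42)
  expect_identical(t1, t2)
  t3 <- simulate_school(cfg, seed = 43)
  expect_false(identical(t1$x, t3$x))
})

test_that("a single quiet fish in open space swims straight", {
  open <- tank_geometry(2, bounded = FALSE)
  p <- model_params(noise_scale = 0)
  cfg <- sim_config(open, n_fish = 1, params = p, speeds = 0.4,
                    duration = 100, transient = 0,
                    init = list(x = 0, y = 0, heading = 0, omega = 0))
  tr <- simulate_school(cfg, seed = 1)
  expect_lt(max(abs(tr$y)), 1e-12)
  expect_equal(max(tr$x), 0.4 * max(tr$t), tolerance = 1e-10)
})

test_that("dynamics are rotationally equivariant at fixed seed", {
  tank <- tank_geometry(2)
  beta <- 0.83
  init <- list(x = c(0.5, -0.2), y = c(0.1, 0.6),
               heading = c(0.3, -1.2), omega = c(0, 0))
  rot <- rotate_conf(init$x, init$y, init$heading, beta)
  init_r <- list(x = rot$x, y = rot$y, heading = rot$th, omega = c(0, 0))
  cfg <- sim_config(tank, n_fish = 2, duration = 30, transient = 0,
                    init = init)
  cfg_r <- sim_config(tank, n_fish = 2, duration = 30, transient = 0,
                      init = init_r)
  t1 <- simulate_school(cfg, seed = 9)
  t2 <- simulate_school(cfg_r, seed = 9)
  expect_equal(cos(beta) * t1$x - sin(beta) * t1$y, t2$x, tolerance = 1e-9)
  expect_equal(sin(beta) * t1$x + cos(beta) * t1$y, t2$y, tolerance = 1e-9)
  expect_lt(max(abs(wrap_angle(t1$heading + beta - t2$heading))), 1e-9)
})

test_that("one compiled step equals the exposed R step", {
  tank <- tank_geometry(2)
  p <- model_params()
  states <- list(fish_state(c(0.4, 0.1), 0.5, 0.2, 0.5),
                 fish_state(c(-0.3, 0.5), -1, -0.1, 0.5),
                 fish_state(c(0.1, -0.6), 2, 0, 0.5))
  x <- vapply(states, function(s) s$position[1], numeric(1))
  y <- vapply(states, function(s) s$position[2], numeric(1))
  th <- vapply(states, function(s) s$heading, numeric(1))
  om <- vapply(states, function(s) s$omega, numeric(1))
  dt <- 0.02
  set.seed(77)
  res <- ptwschool:::cpp_simulate(x, y, th, om, rep(0.5, 3), numeric(0),
                                  unclass(p), tank$radius, TRUE, 0L, 0L,
                                  dt, 0L, 2L, 1L)
  set.seed(77)
  out <- step_school(states, p, tank, method = "all", dt = dt)
  for (i in 1:3) {
    expect_equal(out[[i]]$position, c(res$x[2, i], res$y[2, i]),
                 tolerance = 1e-12)
    expect_equal(out[[i]]$heading, res$theta[2, i], tolerance = 1e-12)
    expect_equal(out[[i]]$omega, res$omega[2, i], tolerance = 1e-12)
  }
})

test_that("speed schedules: constant schedule reproduces plain runs", {
  open <- tank_geometry(2, bounded = FALSE)
  p <- model_params(attract_sat = 1)
  cfg <- sim_config(open, n_fish = 3, params = p, speeds = 0.5,
                    duration = 30, transient = 5)
  sched <- make_speed_schedule(cfg, c(0, 100), c(0.5, 0.5))
  t1 <- simulate_school(cfg, seed = 3)
  t2 <- simulate_school(cfg, seed = 3, speed_schedule = sched)
  expect_equal(t1, t2, tolerance = 1e-12)
  # piecewise-linear interpolation hits the knots
  sched2 <- make_speed_schedule(cfg, c(0, 10), c(0.2, 0.8))
  g <- ptwschool:::sim_grid(cfg)
  expect_equal(sched2[1], 0.2)
  expect_equal(sched2[round(10 / g$dt) + 1], 0.8, tolerance = 1e-6)
  expect_equal(sched2[length(sched2)], 0.8)  # held beyond last knot
})

test_that("speed_schedule_scenario returns polarization series", {
  open <- tank_geometry(2, bounded = FALSE)
  p <- model_params(attract_sat = 1)
  cfg <- sim_config(open, n_fish = 4, params = p, speeds = 0.3,
                    duration = 40, transient = 5)
  sc <- speed_schedule_scenario(cfg, c(0, 45), c(0.2, 1), seed = 4)
  expect_named(sc$series, c("t", "speed", "P", "nnd"))
  expect_equal(nrow(sc$series), 40 * 12)
  expect_true(all(sc$series$P >= 0 & sc$series$P <= 1))
  expect_true(all(diff(sc$series$speed) >= 0))
})

test_that("a slow speed ramp raises polarization; a step scatters the group", {
  open <- tank_geometry(2, bounded = FALSE)
  p <- model_params(attract_sat = 1)
  n_runs <- 12
  ramp_up <- 0; flash_out <- 0
  for (s in seq_len(n_runs)) {
    cfg <- sim_config(open, n_fish = 5, params = p, speeds = 0.2,
                      duration = 120, transient = 0)
    # slow ramp: low plateau, 60 s linear rise, high plateau
    sc <- speed_schedule_scenario(cfg, c(0, 30, 90), c(0.2, 0.2, 1),
                                  seed = 900 + s)
    lo <- mean(sc$series$P[sc$series$t < 30])
    hi <- mean(sc$series$P[sc$series$t > 90])
    ramp_up <- ramp_up + (hi > lo)
    # abrupt step: nearest-neighbour distance grows within 5 s
    sc2 <- speed_schedule_scenario(cfg, c(0, 30, 30.2), c(0.2, 0.2, 1),
                                   seed = 900 + s)
    before <- mean(sc2$series$nnd[sc2$series$t > 25 & sc2$series$t < 30])
    after <- max(sc2$series$nnd[sc2$series$t > 30 & sc2$series$t < 35])
    flash_out <- flash_out + (after > before)
  }
  # one-sided sign tests at n = 12: >= 10 successes gives p < 0.02
  expect_gte(ramp_up, 10)
  expect_gte(flash_out, 10)
})

test_that("track tables have the documented shape", {
  cfg <- sim_config(n_fish = 2, duration = 120, transient = 20)
  tr <- simulate_school(cfg, seed = 8)
  expect_equal(nrow(tr), 2 * 1440)          # 120 s x 12 fps per fish
  expect_equal(sort(unique(tr$id)), c(0L, 1L))
  expect_equal(max(tr$t), (1440 - 1) / 12)
  expect_true(all(sqrt(tr$x^2 + tr$y^2) < 2))
  expect_equal(attr(tr, "fps"), 12)
  expect_equal(attr(tr, "dt"), 1 / 48)      # 0.02 s snapped to the frame grid
})

test_that("summary statistics are stable under dt refinement", {
  p <- model_params()
  stats_at <- function(dt, seeds) {
    sapply(seeds, function(s) {
      cfg <- sim_config(n_fish = 2, params = p, speeds = 0.6, dt = dt,
                        duration = 120, transient = 20)
      cs <- collective_series(simulate_school(cfg, seed = s))
      c(mean(cs$P), mean(cs$D))
    })
  }
  a <- stats_at(1 / 48, 1:6)
  b <- stats_at(1 / 96, 1:6)
  for (k in 1:2) {
    se <- sqrt(sd(a[k, ])^2 + sd(b[k, ])^2) / sqrt(6)
    expect_lt(abs(mean(a[k, ]) - mean(b[k, ])), 3 * se + 0.02)
  }
})
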