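test_that("regression records have the documented bookkeeping", {
  tank <- tank_geometry(2)
  cfg <- sim_config(tank, n_fish = 2, duration = 30, transient = 5)
  tr <- simulate_school(cfg, seed = 14)
  recs <- build_regression(track_kinematics(tr), tank, "all")
  nf <- 30 * 12
  # headings at F-1 frames, omega at F-2, one transition lost
  expect_equal(nrow(recs), 2 * (nf - 3))
  expect_setequal(attr(recs, "zero_cols"), character(0))
  expect_equal(attr(recs, "dt"), 1 / 12)
  # single fish: social stimuli are identically zero and flagged
  cfg1 <- sim_config(tank, n_fish = 1, duration = 30, transient = 5)
  tr1 <- simulate_school(cfg1, seed = 15)
  recs1 <- build_regression(track_kinematics(tr1), tank, "all")
  expect_setequal(attr(recs1, "zero_cols"), c("S_p", "S_v"))
})

test_that("noise-free state records give an exact zero-residual fit", {
  # with sigma = 0 and records built from the simulator's own state
  # output on the integration grid, the Euler regression is the exact
  # model class: residuals vanish at the truth and the fit recovers it
  tank <- tank_geometry(2)
  p <- model_params(noise_scale = 0)
  cfg <- sim_config(tank, n_fish = 2, params = p, speeds = 0.5, dt = 1 / 48,
                    duration = 40, transient = 5, output_fps = 48)
  tr <- simulate_school(cfg, seed = 16)
  kin <- track_kinematics(tr, use_recorded = TRUE)
  recs <- build_regression(kin, tank, "all", p)
  f <- fit_params(recs, "pooled", method = "euler")
  expect_true(f$converged)
  true <- c(k_w = 40, l = 0.5, k_p = 4, k_v = 3)
  expect_equal(unname(f$estimates[names(true)]), unname(true),
               tolerance = 1e-6)
  expect_lt(max(abs(f$residuals)), 1e-8)
  expect_lt(f$sigma_hat, 1e-7)
})

test_that("single-fish AR(1) reduction recovers the relaxation", {
  # far from any wall, only the -omega regressor is active; the
  # relaxation coefficient is small at this step, so average a few runs
  open <- tank_geometry(2, bounded = FALSE)
  p <- model_params(attract_coeff = 0, align_coeff = 0)
  ests <- sapply(1:3, function(s) {
    cfg <- sim_config(open, n_fish = 1, params = p, speeds = 0.5,
                      dt = 1 / 48, duration = 400, transient = 10,
                      output_fps = 48)
    tr <- simulate_school(cfg, seed = 170 + s)
    recs <- build_regression(track_kinematics(tr, use_recorded = TRUE),
                             open, "all", p)
    f <- fit_params(recs, "pooled", method = "euler")
    expect_true(is.na(f$estimates["k_p"]) && is.na(f$estimates["k_v"]))
    c(l = unname(f$estimates["l"]), sig = f$sigma_hat)
  })
  expect_equal(unname(mean(ests["l", ])), 0.5, tolerance = 0.08)
  expect_equal(unname(mean(ests["sig", ])), 1.2, tolerance = 0.03)
})

test_that("chord-reconstructed kinematics recover parameters via IV", {
  f <- fit_pair_replicates(seed = 6, n_rep = 3)
  expect_true(f$converged)
  expect_equal(unname(f$estimates["l"]), 0.5, tolerance = 0.10)
  expect_equal(unname(f$estimates["k_v"]), 3, tolerance = 0.12)
  expect_equal(unname(f$estimates["k_p"]), 4, tolerance = 0.20)
  expect_equal(f$sigma_hat, 1.2, tolerance = 0.10)
})

test_that("plain least squares is visibly biased where IV is not", {
  # the documented failure mode of the uninstrumented regression under
  # heading feedback: it must disagree with IV in the known direction
  f_iv <- fit_pair_replicates(seed = 19, n_rep = 2, method = "iv",
                              speed_range = c(0.6, 0.6))
  f_ls <- fit_pair_replicates(seed = 19, n_rep = 2, method = "ls",
                              speed_range = c(0.6, 0.6))
  expect_lt(f_ls$estimates["l"], f_iv$estimates["l"])
  expect_lt(abs(f_iv$estimates["l"] - 0.5), abs(f_ls$estimates["l"] - 0.5))
})

test_that("per-fish mode fits each fish separately", {
  tank <- tank_geometry(2)
  tr <- sim_pair(20, v = 0.6)
  recs <- build_regression(track_kinematics(tr), tank, "all")
  fl <- fit_params(recs, "per_fish")
  expect_length(fl, 2)
  for (f in fl) {
    expect_s3_class(f, "ptw_fit")
    expect_true(f$converged)
    expect_gt(f$estimates["l"], 0)
  }
})

test_that("residual diagnostics report near-normal residuals", {
  f <- fit_pair_replicates(seed = 23, n_rep = 2)
  d <- residual_diagnostics(f)
  expect_gt(d$qq_cor, 0.99)
  expect_lt(abs(d$lag1_autocorr), 0.6)
  expect_equal(d$n, length(f$residuals))
})

test_that("omitting the alignment term leaves structure in residuals", {
  tank <- tank_geometry(2)
  set.seed(24)
  rl <- lapply(1:2, function(r)
    build_regression(track_kinematics(sim_pair(240 + r, v = 0.7)),
                     tank, "all"))
  recs <- pool_records(rl)
  # deliberately misspecified: alignment stimulus hidden from the fit
  recs_mis <- recs
  sv_true <- recs_mis$S_v
  recs_mis$S_v <- 0
  recs_mis$S_v_l2 <- 0
  attr(recs_mis, "zero_cols") <- c("S_v")
  f_mis <- fit_params(recs_mis, "pooled")
  expect_gt(abs(cor(f_mis$residuals, sv_true)), 0.05)
  # well-specified fit on the same data: no such correlation
  f_ok <- fit_params(recs, "pooled")
  expect_lt(abs(cor(f_ok$residuals, sv_true)),
            abs(cor(f_mis$residuals, sv_true)))
})

test_that("binned stimulus-response curves fall on the fitted line", {
  set.seed(25)
  tank <- tank_geometry(2)
  rl <- lapply(1:3, function(r)
    build_regression(track_kinematics(sim_pair(250 + r, v = 0.6)),
                     tank, "all"))
  recs <- pool_records(rl)
  f <- fit_params(recs, "pooled")
  curves <- stimulus_response_curves(recs, f)
  expect_setequal(names(curves), c("wall", "attraction", "alignment"))
  for (nm in c("attraction", "alignment")) {
    cv <- curves[[nm]]
    expect_true(all(cv$bins$n >= 10))
    dev <- abs(cv$bins$mean_y - cv$slope * cv$bins$mean_x)
    expect_true(all(dev < 2 * cv$bins$sd_y))
  }
})

test_that("null-interaction data produce flat response curves", {
  set.seed(26)
  tank <- tank_geometry(2)
  p0 <- model_params(attract_coeff = 0, align_coeff = 0)
  rl <- lapply(1:2, function(r)
    build_regression(track_kinematics(sim_pair(260 + r, v = 0.6,
                                               params = p0)),
                     tank, "all", p0))
  recs <- pool_records(rl)
  f <- fit_params(recs, "pooled")
  curves <- stimulus_response_curves(recs, f, n_bins = 8)
  for (nm in c("attraction", "alignment")) {
    b <- curves[[nm]]$bins
    expect_true(all(abs(b$mean_y) < 2 * b$sd_y))
  }
})

test_that("records requirement guards underdetermined fits", {
  tank <- tank_geometry(2)
  tr <- sim_pair(27, duration = 30)
  recs <- build_regression(track_kinematics(tr), tank, "all")
  tiny <- recs[1:20, ]
  attr(tiny, "dt") <- attr(recs, "dt")
  attr(tiny, "zero_cols") <- character(0)
  class(tiny) <- class(recs)
  expect_error(fit_params(tiny, "pooled"), "at least 10 records")
})
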