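#' Build the Ito-discretised regression records
#'
#' One record per retained frame transition and fish, holding the
#' response `domega = omega(t + dt) - omega(t)` and the regressors of
#' the discrete-time model
#'
#'   domega = (dt * vbar / l) * (k_w S_w + k_p S_p + k_v S_v - omega) + eps
#'
#' where `S_w`, `S_p`, `S_v` are the wall, attraction and alignment
#' stimuli (neighbour-normalised, with the configured speed scalings
#' evaluated at the per-fish mean speed `vbar`) and
#' `eps ~ N(0, sigma^2 dt)`. The stimuli are evaluated from the
#' reconstructed states with the same functional forms as the forward
#' model, so inversion and simulation are consistent by construction.
#' Only frames at which every fish has a defined state enter; a record
#' requires omega at two consecutive frames.
#'
#' @param kin a [track_kinematics()] result (or a raw track table, which
#'   is passed through [track_kinematics()] first).
#' @param tank a [tank_geometry()].
#' @param method neighbourhood method (`"all"`, `"voronoi_shell1"`,
#'   `"knn:K"`).
#' @param params a [model_params()]; only its structural settings (wall
#'   mode, speed exponents, saturation) matter here, not the coefficient
#'   values.
#' @return data.frame of class `ptw_records` with columns `fish`,
#'   `frame`, `omega`, `domega`, `S_w`, `S_p`, `S_v`, their lag-2
#'   instrument columns (`*_l2`, used by the instrumented estimator;
#'   `NA` where two-frames-earlier values are unavailable), `vbar`, and
#'   attributes `dt`, `zero_cols` (names of all-zero regressor columns,
#'   e.g. the social stimuli for a single fish).
#' @export
build_regression <- function(kin, tank, method = "all",
                             params = model_params()) {
  if (!inherits(kin, "kinematics_series")) kin <- track_kinematics(kin)
  stopifnot(inherits(tank, "tank_geometry"), inherits(params, "model_params"))
  st <- kin$states
  fps <- kin$fps
  st$frame <- round(st$t * fps)
  ids <- sort(unique(st$id))
  n <- length(ids)
  # frames at which every fish has a defined heading estimate
  tab <- table(st$frame)
  frames <- sort(as.integer(names(tab)[tab == n]))
  if (length(frames) < 5) stop("too few complete frames for regression")
  st <- st[st$frame %in% frames, ]
  st <- st[order(st$id, st$frame), ]
  nf <- length(frames)
  X <- matrix(st$x, nrow = nf)
  Y <- matrix(st$y, nrow = nf)
  TH <- matrix(st$heading, nrow = nf)
  OM <- matrix(st$omega, nrow = nf)
  vbar <- kin$vbar[as.character(ids)]
  mc <- graph_method_code(method)
  # With chord-reconstructed kinematics the stimulus states are taken at
  # the midpoint of the response increment: the displacement heading at
  # frame k already estimates the heading half a frame late, and
  # averaging consecutive positions puts the positional stimuli at the
  # same instant (a midpoint discretisation, which keeps the regression
  # centred under feedback between heading and stimulus). With directly
  # recorded states, everything already sits on the frame instants.
  Xm <- X; Ym <- Y
  if (!isTRUE(kin$recorded)) {
    Xm[-nf, ] <- (X[-nf, ] + X[-1, ]) / 2
    Ym[-nf, ] <- (Y[-nf, ] + Y[-1, ]) / 2
    cons <- c(diff(frames) == 1, FALSE)
    Xm[!cons, ] <- X[!cons, ]
    Ym[!cons, ] <- Y[!cons, ]
  }
  S <- cpp_stimulus_series(Xm, Ym, TH, vbar, unclass(params), tank$radius,
                           tank$bounded, mc$code, mc$K)
  consecutive <- c(diff(frames) == 1, FALSE)
  recs <- list()
  for (i in seq_len(n)) {
    ok <- consecutive & is.finite(OM[, i]) &
      c(is.finite(OM[-1, i]), FALSE)
    if (!any(ok)) next
    k <- which(ok)
    # lag-2 instruments: same quantities two frames earlier (their
    # measurement windows do not overlap the response increment)
    k2 <- match(frames[k] - 2L, frames)
    l2ok <- !is.na(k2)
    k2[!l2ok] <- 1L
    lag2 <- function(v) ifelse(l2ok, v[k2], NA_real_)
    recs[[i]] <- data.frame(
      fish = ids[i], frame = frames[k], omega = OM[k, i],
      domega = OM[k + 1, i] - OM[k, i],
      S_w = S$S_w[k, i], S_p = S$S_p[k, i], S_v = S$S_v[k, i],
      omega_l2 = lag2(OM[, i]), S_w_l2 = lag2(S$S_w[, i]),
      S_p_l2 = lag2(S$S_p[, i]), S_v_l2 = lag2(S$S_v[, i]),
      vbar = unname(vbar[i]), row.names = NULL)
    recs[[i]]$omega_l2[!l2ok | !is.finite(recs[[i]]$omega_l2)] <- NA_real_
  }
  recs <- do.call(rbind, recs)
  rownames(recs) <- NULL
  zero_cols <- c("S_w", "S_p", "S_v")[c(all(recs$S_w == 0),
                                        all(recs$S_p == 0),
                                        all(recs$S_v == 0))]
  attr(recs, "dt") <- 1 / fps
  attr(recs, "zero_cols") <- zero_cols
  class(recs) <- c("ptw_records", "data.frame")
  recs
}

# Sampling-filter theory for the frame-sampled angular velocity.
# The reconstructed omega at frame k differences the two adjacent
# displacement headings, each a half-frame-shifted mean heading, which
# makes omega-hat a triangular-kernel average of the true omega over
# (t_k - dt, t_k + dt). For a stationary OU process with x = dt/tau the
# filtered covariances at lags 0 and 1 are closed forms:
#   C0(x) = 4/(3x) - 4/x^3 + 6/x^4 - 8 e^-x/x^4 + 2 e^-2x/x^4
#   C1(x) = 1/(3x) + 2/x^3 - 4/x^4 + 7 e^-x/x^4 - 4 e^-2x/x^4 + e^-3x/x^4
# (in units of the stationary variance sigma^2 tau / 2), giving the
# exact one-frame relaxation coefficient h(x) = 1 - C1/C0 of the
# least-squares projection (Euler's x is the x -> 0 limit up to the
# 11/20 filter factor) and the residual variance gain
#   g(x) = [C0 (1 + (1-h)^2) - 2 (1-h) C1] / (2x)  ->  11/20.
# The x^-4 terms cancel catastrophically for small x, so a series
# expansion takes over below x = 0.02.
filter_C01 <- function(x) {
  e1 <- exp(-x)
  C0 <- 4 / (3 * x) - 4 / x^3 + 6 / x^4 - 8 * e1 / x^4 + 2 * e1^2 / x^4
  C1 <- 1 / (3 * x) + 2 / x^3 - 4 / x^4 + 7 * e1 / x^4 - 4 * e1^2 / x^4 +
    e1^3 / x^4
  list(C0 = C0, C1 = C1)
}

filter_relax <- function(x) {
  h <- (11 / 20) * x - (73 / 300) * x^2
  big <- x >= 0.02
  if (any(big)) {
    cc <- filter_C01(x[big])
    h[big] <- 1 - cc$C1 / cc$C0
  }
  h
}

filter_vargain <- function(x) {
  g <- 11 / 20 - (521 / 800) * x + (41071 / 84000) * x^2
  big <- x >= 0.02
  if (any(big)) {
    cc <- filter_C01(x[big])
    h <- 1 - cc$C1 / cc$C0
    g[big] <- (cc$C0 * (1 + (1 - h)^2) - 2 * (1 - h) * cc$C1) / (2 * x[big])
  }
  g
}

#' Pool regression records across replicates
#'
#' Concatenates `ptw_records` tables from several replicates (e.g. the
#' five recordings of a group size) into one table for a pooled fit,
#' relabelling fish ids so that fish from different replicates stay
#' distinct. All tables must share the same frame rate.
#'
#' @param record_list list of `ptw_records` tables.
#' @return one `ptw_records` table.
#' @export
pool_records <- function(record_list) {
  stopifnot(length(record_list) >= 1,
            all(vapply(record_list, inherits, logical(1), "ptw_records")))
  dts <- vapply(record_list, attr, numeric(1), "dt")
  if (max(dts) - min(dts) > 1e-12)
    stop("cannot pool records with different frame intervals")
  for (r in seq_along(record_list))
    record_list[[r]]$fish <- paste0("rep", r, ":", record_list[[r]]$fish)
  out <- do.call(rbind, record_list)
  rownames(out) <- NULL
  attr(out, "dt") <- dts[1]
  attr(out, "zero_cols") <-
    c("S_w", "S_p", "S_v")[c(all(out$S_w == 0), all(out$S_p == 0),
                             all(out$S_v == 0))]
  class(out) <- c("ptw_records", "data.frame")
  out
}

# gain (discrete relaxation coefficient) and residual variance factor
# for each estimation method, as functions of x = dt * vbar / l
method_gain <- function(x, method) {
  switch(method,
         iv = 1 - exp(-x),
         ls = filter_relax(x),
         euler = x)
}

method_vargain <- function(x, method) {
  if (method == "euler") return(rep(1, length(x)))
  cc <- filter_C01(pmax(x, 0.02))
  h <- method_gain(x, method)
  g <- (cc$C0 * (1 + (1 - h)^2) - 2 * (1 - h) * cc$C1) / (2 * x)
  small <- x < 0.02
  if (any(small)) g[small] <- 11 / 20 - (521 / 800) * x[small]
  g
}

fit_one <- function(records, dt, init, lower, upper, zero_cols,
                    method = "iv", max_restarts = 3) {
  nm <- c("k_w", "l", "k_p", "k_v")
  scol <- c("S_w", NA, "S_p", "S_v")
  free <- !(scol %in% zero_cols)
  n_par <- sum(free)
  if (nrow(records) < 10 * n_par)
    stop("need at least 10 records per free parameter (have ",
         nrow(records), " for ", n_par, ")")
  resid_par <- function(par, recs) {
    x <- dt * recs$vbar / par[2]
    gn <- method_gain(x, method)
    recs$domega - gn * (par[1] * recs$S_w + par[3] * recs$S_p +
                        par[4] * recs$S_v - recs$omega)
  }
  if (method == "iv") {
    out <- fit_iv(records, dt, lower, upper, free, resid_par)
  } else {
    run <- function(ini) {
      minpack.lm::nls.lm(par = ini[free], fn = function(p_free) {
        par <- numeric(4); par[free] <- p_free
        resid_par(par, records)
      }, lower = lower[free], upper = upper[free],
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12))
    }
    fit <- run(init)
    tries <- 0
    while (!(fit$info %in% 1:4) && tries < max_restarts) {
      tries <- tries + 1
      jit <- init * stats::runif(4, 0.5, 2)
      fit <- run(pmin(pmax(jit, lower), upper))
    }
    par <- numeric(4); se <- rep(NA_real_, 4)
    par[free] <- fit$par
    par[!free] <- NA_real_
    sm <- try(summary(fit), silent = TRUE)
    if (!inherits(sm, "try-error"))
      se[free] <- sm$coefficients[, "Std. Error"]
    out <- list(par = par, se = se, converged = fit$info %in% 1:4,
                info = fit$info, message = fit$message)
  }
  par <- out$par; se <- out$se
  names(par) <- names(se) <- nm
  res <- resid_par(ifelse(is.na(par), 0, par), records)
  # residual variance -> sigma^2 dt, deconvolved from the sampling
  # filter's variance gain at the method's relaxation coefficient
  x <- dt * records$vbar / par[2]
  gvar <- method_vargain(x, method)
  sigma_hat <- sqrt(stats::var(res / sqrt(gvar)) / dt)
  at_bound <- free & (abs(par - lower) < 1e-8 | abs(par - upper) < 1e-8)
  at_bound[is.na(at_bound)] <- FALSE
  list(estimates = par, se = se, residuals = res,
       sigma_hat = sigma_hat, method = method,
       converged = out$converged, info = out$info,
       message = out$message, at_bound = nm[which(at_bound)],
       n_records = nrow(records))
}

# Instrumented estimator. For fixed persistence length l the moment
# equations E[Z_s r] = 0 of the stimulus instruments are linear in the
# coefficients, so the just-identified system reduces to one scalar
# equation in l (the omega-instrument moment): solve the linear
# subsystem on a grid over l, bracket sign changes of the remaining
# moment, and polish each bracket with uniroot. Among multiple roots
# keep the one with the smallest residual sum of squares. This global
# profiling is immune to the spurious local minima a generic
# Levenberg-Marquardt run can report on weakly informative data.
fit_iv <- function(records, dt, lower, upper, free, resid_par) {
  inst_all <- c("S_w_l2", "omega_l2", "S_p_l2", "S_v_l2")
  stim_cols <- c("S_w", "S_p", "S_v")
  stim_free <- free[c(1, 3, 4)]
  inst_cols <- inst_all[free]
  use <- stats::complete.cases(records[, inst_all, drop = FALSE])
  recs <- records[use, , drop = FALSE]
  Z <- as.matrix(recs[, inst_cols, drop = FALSE])
  S <- as.matrix(recs[, stim_cols, drop = FALSE])[, stim_free, drop = FALSE]
  n <- nrow(recs)
  # moments given l: solve stimulus-instrument equations for k, return
  # the omega-instrument moment and the implied parameter vector
  profile_at <- function(l) {
    x <- dt * recs$vbar / l
    h <- 1 - exp(-x)
    # r = domega - h (S k) + h omega ; moment_i = mean(Z_i r)
    b0 <- colMeans(Z * (recs$domega + h * recs$omega))
    A <- crossprod(Z, h * S) / n
    om_row <- which(inst_cols == "omega_l2")
    st_rows <- setdiff(seq_along(inst_cols), om_row)
    k <- tryCatch(solve(A[st_rows, , drop = FALSE], b0[st_rows]),
                  error = function(e) NULL)
    if (is.null(k) || any(!is.finite(k))) return(NULL)
    par <- numeric(4)
    par[2] <- l
    par[c(1, 3, 4)[stim_free]] <- k
    list(par = par, g = b0[om_row] - sum(A[om_row, ] * k))
  }
  if (!any(stim_free)) {
    # no stimulus regressors at all: the omega moment alone defines l
    profile_at <- function(l) {
      x <- dt * recs$vbar / l
      h <- 1 - exp(-x)
      list(par = c(0, l, 0, 0),
           g = mean(recs$omega_l2 * (recs$domega + h * recs$omega)))
    }
  }
  grid <- exp(seq(log(lower[2]), log(upper[2]), length.out = 80))
  gv <- rep(NA_real_, length(grid))
  profs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    pr <- profile_at(grid[i])
    if (!is.null(pr)) { gv[i] <- pr$g; profs[[i]] <- pr }
  }
  roots <- list()
  for (i in seq_len(length(grid) - 1)) {
    if (is.na(gv[i]) || is.na(gv[i + 1])) next
    if (gv[i] == 0) roots[[length(roots) + 1]] <- profs[[i]]$par
    if (gv[i] * gv[i + 1] < 0) {
      sol <- tryCatch(stats::uniroot(function(l) profile_at(l)$g,
                                     c(grid[i], grid[i + 1]),
                                     tol = 1e-10),
                      error = function(e) NULL)
      if (!is.null(sol)) {
        pr <- profile_at(sol$root)
        if (!is.null(pr)) roots[[length(roots) + 1]] <- pr$par
      }
    }
  }
  converged <- length(roots) > 0
  if (!converged) {
    # no sign change: report the grid point with the smallest |moment|
    if (all(is.na(gv))) stop("instrumented moment system is degenerate")
    i_best <- which.min(abs(gv))
    roots <- list(profs[[i_best]]$par)
  }
  rss <- vapply(roots, function(p) sum(resid_par(p, recs)^2), numeric(1))
  par <- roots[[which.min(rss)]]
  # coefficients outside the box are a failed fit, not an estimate
  kidx <- c(1, 3, 4)
  if (any(par[kidx][stim_free] < lower[kidx][stim_free] - 1e-8) ||
      any(par[kidx][stim_free] > upper[kidx][stim_free] + 1e-8))
    converged <- FALSE
  par[kidx] <- pmin(pmax(par[kidx], lower[kidx]), upper[kidx])
  par[c(1, 3, 4)[!stim_free]] <- NA_real_
  # just-identified GMM sandwich (iid approximation across records)
  se <- rep(NA_real_, 4)
  p_free <- c(par[1], par[2], par[3], par[4])[free]
  G <- tryCatch({
    base_m <- colMeans(Z * resid_par(ifelse(is.na(par), 0, par), recs))
    eps <- pmax(abs(p_free), 0.1) * 1e-6
    vapply(seq_along(p_free), function(j) {
      pj <- par
      pj[which(free)[j]] <- pj[which(free)[j]] + eps[j]
      (colMeans(Z * resid_par(ifelse(is.na(pj), 0, pj), recs)) - base_m) /
        eps[j]
    }, numeric(sum(free)))
  }, error = function(e) NULL)
  if (!is.null(G) && all(is.finite(G)) &&
      abs(det(G)) > 1e-300) {
    r_iv <- resid_par(ifelse(is.na(par), 0, par), recs)
    Sm <- crossprod(Z * r_iv) / n
    Gi <- solve(G)
    V <- Gi %*% Sm %*% t(Gi) / n
    se[free] <- sqrt(pmax(diag(V), 0))
  }
  list(par = par, se = se, converged = converged,
       info = if (converged) 1L else 0L,
       message = if (converged) "moment equations solved"
                 else "no root of the moment equations in bounds")
}

#' Estimate the behavioural parameters by nonlinear least squares
#'
#' Minimises the squared residuals of the discretised model over
#' `(k_w, l, k_p, k_v)` with a bounded Levenberg-Marquardt optimizer
#' (up to 3 jittered restarts on non-convergence). The noise scale is
#' derived from the residual variance, `sigma_hat^2 = Var(resid) / dt`,
#' after removing the variance gain of the sampling filter.
#' In pooled mode the constants are shared across fish while each fish's
#' mean speed enters the speed scalings; in per-fish mode each fish is
#' fit separately. Stimulus columns that are identically zero (e.g.
#' social terms for a single fish) have their coefficient reported as
#' `NA` rather than estimated from no signal.
#'
#' Three estimation methods are available. The reconstructed angular
#' velocity is a triangular-kernel average of the underlying process
#' over two frame intervals, and its second difference mechanically
#' contains the same displacement headings that build the stimulus
#' regressors; when the stimuli feed back on the heading (alignment,
#' wall avoidance), plain least squares on the discretised model is
#' therefore biased at 12 fps. The default `method = "iv"` removes this
#' by instrumenting each regressor with its own value two frames
#' earlier -- whose measurement window does not overlap the response
#' increment -- and solving the resulting just-identified moment
#' equations with the exact discrete relaxation gain `1 - exp(-dt/tau)`
#' (nonlinear instrumental variables / GMM). `method = "ls"` is plain
#' least squares with the filtered-process gain (consistent without
#' feedback), and `method = "euler"` is the textbook Ito/Euler
#' regression with gain `dt/tau`. All methods derive the noise scale
#' from the residual variance after removing the sampling filter's
#' variance gain.
#'
#' @param records a `ptw_records` table from [build_regression()].
#' @param mode `"pooled"` or `"per_fish"`.
#' @param init starting values `(k_w, l, k_p, k_v)`.
#' @param lower,upper box bounds on the parameters.
#' @param method `"iv"` (default), `"ls"` or `"euler"`, see Details.
#' @return for pooled mode an object of class `ptw_fit` (fields
#'   `estimates`, `se`, `sigma_hat`, `residuals`, `records`, `dt`,
#'   `converged`, `info`, `at_bound`, `n_records`); for per-fish mode a
#'   list of `ptw_fit` objects named by fish id.
#' @export
fit_params <- function(records, mode = c("pooled", "per_fish"),
                       init = c(k_w = 1, l = 0.2, k_p = 1, k_v = 1),
                       lower = c(0, 0.01, 0, 0),
                       upper = c(100, 5, 100, 100),
                       method = c("iv", "ls", "euler")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(records, "ptw_records"))
  dt <- attr(records, "dt")
  zero_cols <- attr(records, "zero_cols")
  wrap <- function(recs, zc) {
    f <- fit_one(recs, dt, init, lower, upper, zc, method)
    f$records <- recs
    f$dt <- dt
    f$mode <- mode
    class(f) <- "ptw_fit"
    f
  }
  if (mode == "pooled") return(wrap(records, zero_cols))
  out <- lapply(split(records, records$fish), function(recs) {
    zc <- c("S_w", "S_p", "S_v")[c(all(recs$S_w == 0), all(recs$S_p == 0),
                                   all(recs$S_v == 0))]
    attr(recs, "dt") <- dt
    wrap(recs, zc)
  })
  out
}

#' @export
print.ptw_fit <- function(x, ...) {
  cat(sprintf("ptw_fit (%s, %d records)%s\n", x$mode, x$n_records,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- rbind(estimate = x$estimates, se = x$se)
  print(round(est, 4))
  cat(sprintf("sigma_hat = %.4g\n", x$sigma_hat))
  if (length(x$at_bound))
    cat("at bound:", paste(x$at_bound, collapse = ", "), "\n")
  invisible(x)
}

#' Residual diagnostics for a fitted model
#'
#' Normal quantile-quantile data for the residuals, the correlation of
#' the QQ plot (a normality index close to 1 under a well-specified
#' model, justifying the Wiener noise term), and the lag-1 residual
#' autocorrelation (computed within fish and pooled).
#'
#' @param fit a `ptw_fit` object.
#' @return list with `qq` (data.frame `theoretical`, `sample`),
#'   `qq_cor`, `lag1_autocorr`, `sigma_hat`, `n`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "ptw_fit"))
  if (!fit$converged) stop("fit did not converge; no diagnostics")
  r <- fit$residuals
  n <- length(r)
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                   sample = sort((r - mean(r)) / stats::sd(r)))
  lag1 <- unlist(lapply(split(r, fit$records$fish), function(ri) {
    if (length(ri) < 3) return(NULL)
    stats::cor(ri[-1], ri[-length(ri)])
  }))
  list(qq = qq, qq_cor = stats::cor(qq$theoretical, qq$sample),
       lag1_autocorr = mean(lag1), sigma_hat = fit$sigma_hat, n = n)
}

#' Binned residual stimulus-response curves
#'
#' A-posteriori check of the response ansatz: for each stimulus in turn,
#' the two other fitted contributions (and the relaxation term) are
#' subtracted from the observed response, and what remains is binned
#' against the scaled stimulus `x = (dt vbar / l_hat) S`. Under the
#' model the bin means fall on the line through the origin with slope
#' equal to the corresponding coefficient estimate.
#'
#' @param records a `ptw_records` table.
#' @param fit the `ptw_fit` obtained from those records.
#' @param n_bins number of equal-width bins over the stimulus range.
#' @param min_count bins with fewer records are dropped.
#' @return named list (one entry per available stimulus: `wall`,
#'   `attraction`, `alignment`) of lists with `bins` (data.frame
#'   `mean_x`, `mean_y`, `sd_y`, `sem_y`, `n`) and `slope` (the fitted
#'   coefficient, i.e. the expected line through the origin).
#' @export
stimulus_response_curves <- function(records, fit, n_bins = 12,
                                     min_count = 10) {
  stopifnot(inherits(records, "ptw_records"), inherits(fit, "ptw_fit"))
  dt <- attr(records, "dt")
  est <- fit$estimates
  x <- dt * records$vbar / est["l"]
  gain <- method_gain(x, fit$method)
  relax <- gain * records$omega
  comp <- list(
    wall = list(S = records$S_w, k = est["k_w"]),
    attraction = list(S = records$S_p, k = est["k_p"]),
    alignment = list(S = records$S_v, k = est["k_v"]))
  avail <- !vapply(comp, function(cc) is.na(cc$k), logical(1))
  out <- list()
  for (nmi in names(comp)[avail]) {
    others <- setdiff(names(comp)[avail], nmi)
    y <- records$domega + relax
    for (o in others) y <- y - gain * comp[[o]]$k * comp[[o]]$S
    x <- gain * comp[[nmi]]$S
    br <- seq(min(x), max(x), length.out = n_bins + 1)
    bin <- cut(x, breaks = br, include.lowest = TRUE)
    agg <- lapply(split(data.frame(x, y), bin), function(d) {
      if (nrow(d) < min_count) return(NULL)
      data.frame(mean_x = mean(d$x), mean_y = mean(d$y),
                 sd_y = stats::sd(d$y),
                 sem_y = stats::sd(d$y) / sqrt(nrow(d)), n = nrow(d))
    })
    bins <- do.call(rbind, agg)
    rownames(bins) <- NULL
    out[[nmi]] <- list(bins = bins, slope = unname(comp[[nmi]]$k))
  }
  out
}
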