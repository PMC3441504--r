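#' Group polarization
#'
#' Modulus of the mean heading unit vector: 1 for a perfectly aligned
#' group, 0 for a balanced (disordered) one.
#'
#' @param headings numeric vector of headings (rad), N >= 1.
#' @return polarization P in \[0, 1\].
#' @export
polarization <- function(headings) {
  stopifnot(length(headings) >= 1)
  sqrt(mean(cos(headings))^2 + mean(sin(headings))^2)
}

#' Mean inter-individual distance
#'
#' Mean Euclidean distance over all unordered pairs.
#'
#' @param positions N x 2 matrix of positions, N >= 2.
#' @return mean pairwise distance (m).
#' @export
mean_interdistance <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("mean_interdistance needs N >= 2")
  mean(stats::dist(positions))
}

#' Mean nearest-neighbour distance
#'
#' @param positions N x 2 matrix of positions, N >= 2.
#' @return mean over fish of the distance to the nearest other fish (m).
#' @export
mean_nearest_neighbor <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("mean_nearest_neighbor needs N >= 2")
  dm <- as.matrix(stats::dist(positions))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

#' Time series of collective observables for a track table
#'
#' @param tracks a track table (`t`, `id`, `x`, `y`, and `heading`; if
#'   headings are absent they are reconstructed from displacements via
#'   [track_kinematics()]).
#' @return data.frame with `t`, `P`, `D` (mean inter-distance), `nnd`
#'   (single fish: `P = 1`, `D` and `nnd` are `NA`).
#' @export
collective_series <- function(tracks) {
  if (!"heading" %in% names(tracks)) {
    kin <- track_kinematics(tracks)
    tracks <- kin$states
  }
  fr <- track_frames(tracks)
  n <- ncol(fr$x)
  nf <- nrow(fr$x)
  if (n == 1)
    return(data.frame(t = fr$t, P = 1, D = NA_real_, nnd = NA_real_))
  data.frame(
    t = fr$t,
    P = apply(fr$heading, 1, polarization),
    D = vapply(seq_len(nf), function(f)
      mean_interdistance(cbind(fr$x[f, ], fr$y[f, ])), numeric(1)),
    nnd = vapply(seq_len(nf), function(f)
      mean_nearest_neighbor(cbind(fr$x[f, ], fr$y[f, ])), numeric(1)))
}

#' Replicate-simulation predictions with confidence bands
#'
#' Runs `n_sims` seeded simulations, computes each run's time-averaged
#' polarization and mean inter-distance after the transient, and returns
#' their across-run mean with an empirical 95% band (2.5% and 97.5%
#' quantiles; the distributions are skewed near P = 1, so no normal
#' approximation is used). Optionally evaluates the null model -- the
#' same run with attraction and alignment switched off but wall
#' avoidance kept -- as a no-interaction reference.
#'
#' @param config a [sim_config()].
#' @param n_sims number of replicate simulations (>= 2).
#' @param seed integer; run r uses seed `seed + r - 1`.
#' @param null_model also compute the k_p = k_v = 0 reference?
#' @return list with `per_run` (data.frame of run, seed, mean_P, mean_D,
#'   mean_nnd), `mean_P`, `band_P`, `mean_D`, `band_D`, and `null`
#'   (same summaries under the null model, or `NULL`).
#' @export
predict_with_band <- function(config, n_sims = 100, seed = 1,
                              null_model = TRUE) {
  stopifnot(n_sims >= 2)
  run_set <- function(cfg) {
    per <- lapply(seq_len(n_sims), function(r) {
      tr <- simulate_school(cfg, seed = seed + r - 1)
      cs <- collective_series(tr)
      data.frame(run = r, seed = seed + r - 1, mean_P = mean(cs$P),
                 mean_D = mean(cs$D), mean_nnd = mean(cs$nnd))
    })
    do.call(rbind, per)
  }
  per <- run_set(config)
  out <- list(per_run = per,
              mean_P = mean(per$mean_P),
              band_P = stats::quantile(per$mean_P, c(0.025, 0.975),
                                       names = FALSE),
              mean_D = mean(per$mean_D),
              band_D = stats::quantile(per$mean_D, c(0.025, 0.975),
                                       names = FALSE))
  if (null_model && config$n_fish > 1) {
    p0 <- config$params
    p0$attract_coeff <- 0
    p0$align_coeff <- 0
    cfg0 <- config
    cfg0$params <- p0
    per0 <- run_set(cfg0)
    out$null <- list(per_run = per0, mean_P = mean(per0$mean_P),
                     mean_D = mean(per0$mean_D))
  } else out$null <- NULL
  out
}

#' Prediction error of K-nearest-neighbour coupling against a reference
#'
#' For each K, simulates the model with `knn:K` neighbourhoods and
#' accumulates, over the reference replicates, the squared differences
#' between predicted and reference mean polarization and mean
#' inter-distance. Reports the error table, the minimizing K for each
#' observable and combined, and the mean first-shell Voronoi degree of
#' the reference configurations for comparison: the best K is expected
#' near that degree.
#'
#' @param make_config function(replicate_row) -> [sim_config()] used for
#'   the predictions; called once per reference replicate so per-
#'   replicate speeds/initial conditions can be honoured.
#' @param reference data.frame with one row per reference replicate and
#'   columns `mean_P`, `mean_D` (e.g. from synthetic "experimental"
#'   tracks), plus anything `make_config` needs.
#' @param K_values integer vector of K values to sweep.
#' @param n_sims simulations per (K, replicate).
#' @param seed base seed.
#' @param voronoi_degree mean first-shell Voronoi degree of the reference
#'   configurations (e.g. from [mean_voronoi_degree()]).
#' @return list with `errors` (data.frame K, err_P, err_D, err_total),
#'   `best_K`, `best_K_P`, `voronoi_degree`.
#' @export
knn_sweep <- function(make_config, reference, K_values, n_sims = 20,
                      seed = 1, voronoi_degree = NA_real_) {
  errors <- lapply(K_values, function(K) {
    errP <- 0; errD <- 0
    for (r in seq_len(nrow(reference))) {
      cfg <- make_config(reference[r, ])
      cfg$method <- paste0("knn:", K)
      pred <- predict_with_band(cfg, n_sims = n_sims,
                                seed = seed + 1000 * K + r,
                                null_model = FALSE)
      errP <- errP + (pred$mean_P - reference$mean_P[r])^2
      errD <- errD + (pred$mean_D - reference$mean_D[r])^2
    }
    data.frame(K = K, err_P = errP, err_D = errD, err_total = errP + errD)
  })
  errors <- do.call(rbind, errors)
  list(errors = errors,
       best_K = errors$K[which.min(errors$err_total)],
       best_K_P = errors$K[which.min(errors$err_P)],
       voronoi_degree = voronoi_degree)
}

#' Mean first-shell Voronoi degree along a track
#'
#' @param tracks a track table.
#' @param frame_stride compute the degree every `frame_stride`-th frame.
#' @return mean over sampled frames and fish of the first-shell Voronoi
#'   neighbour count.
#' @export
mean_voronoi_degree <- function(tracks, frame_stride = 12) {
  fr <- track_frames(tracks)
  idx <- seq(1, nrow(fr$x), by = frame_stride)
  degs <- vapply(idx, function(f) {
    g <- neighbor_graph(cbind(fr$x[f, ], fr$y[f, ]), "voronoi_shell1")
    mean(g$counts)
  }, numeric(1))
  mean(degs)
}
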