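# Independent oracles used across the suite. These deliberately use
# different constructions from the package code paths they check.

# ray-circle intersection by the explicit quadratic formula, plus the
# signed angle to the outward normal via cross/dot products
oracle_wall_impact <- function(px, py, th, R) {
  ux <- cos(th); uy <- sin(th)
  a <- 1
  b <- 2 * (px * ux + py * uy)
  cc <- px^2 + py^2 - R^2
  disc <- b^2 - 4 * a * cc
  t <- (-b + sqrt(disc)) / (2 * a)
  qx <- px + t * ux; qy <- py + t * uy
  nx <- qx / R; ny <- qy / R
  ang <- atan2(nx * uy - ny * ux, nx * ux + ny * uy)
  list(t = t, impact = c(qx, qy), angle = ang)
}

# Delaunay adjacency by exhaustive empty-circumcircle search over all
# triangles; valid for point sets in general position
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  adj <- matrix(FALSE, n, n)
  circum <- function(p1, p2, p3) {
    ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circum(pts[i, ], pts[j, ], pts[k, ])
    if (is.null(cc)) next
    d2 <- sqrt((pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all(d2[others] > cc[3] + 1e-12)) {
      adj[i, j] <- adj[j, i] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
    }
  }
  adj
}

# rotate a configuration (positions + headings) about the origin
rotate_conf <- function(x, y, th, beta) {
  list(x = cos(beta) * x - sin(beta) * y,
       y = sin(beta) * x + cos(beta) * y,
       th = wrap_angle(th + beta))
}

# small default-parameter pair simulation used by several tests
sim_pair <- function(seed, v = 0.5, duration = 120, params = model_params(),
                     tank = tank_geometry(2), method = "all") {
  cfg <- sim_config(tank, n_fish = 2, params = params, speeds = v,
                    duration = duration, transient = 20, method = method)
  suppressWarnings(simulate_school(cfg, seed = seed))
}

# pooled pair-replicate fit mimicking the five-replicate design
fit_pair_replicates <- function(seed, n_rep = 5, params = model_params(),
                                speed_range = c(0.1, 1), method = "iv") {
  tank <- tank_geometry(2)
  set.seed(seed)
  speeds <- stats::runif(n_rep, speed_range[1], speed_range[2])
  recs <- lapply(seq_len(n_rep), function(r) {
    tr <- sim_pair(seed * 100 + r, v = speeds[r], params = params)
    build_regression(track_kinematics(tr), tank, "all", params)
  })
  fit_params(pool_records(recs), "pooled", method = method)
}
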