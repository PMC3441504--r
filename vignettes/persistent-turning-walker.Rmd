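---
title: "A persistent-turning-walker model of fish schooling: simulation and inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A persistent-turning-walker model of fish schooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ptwschool` implements a stochastic individual-based model for small
groups of fish swimming in a shallow circular tank, together with the
statistical machinery to estimate its parameters from sampled
trajectories and to validate the fitted model against collective
observables.

Each fish is a *persistent turning walker*: a particle moving at a
constant tangential speed $v_i$ whose angular velocity $\omega_i$ — not
its heading — is the stochastic variable. The angular velocity relaxes
toward a stimulus-dependent target $\omega_i^*$,

$$ d\omega_i = -\frac{1}{\tau_i}\bigl(\omega_i - \omega_i^*\bigr)\,dt
   + \sigma\, dW_t, \qquad \tau_i = \ell / v_i , $$

so that trajectories are smooth and differentiable, as observed in real
tracking data. Noise on $\omega$ (rather than on the heading) is what
distinguishes this model class from Vicsek-type models. The relaxation
time is written as a persistence length $\ell$ over the speed: faster
fish update their turning intention faster.

The target combines three stimuli:

$$ \omega_i^* \;=\; f_W(D_W, \theta_W)
   \;+\; \frac{1}{N_i}\sum_{j \in \mathcal N_i}
   \Bigl[ k_p\, v_i^{\alpha_p}\, d_{ij} \sin\psi_{ij}
        + k_v\, v_i^{\alpha_v}\, \sin\phi_{ij} \Bigr], $$

with $d_{ij}$ the distance to neighbour $j$, $\psi_{ij}$ its bearing
(angle from the focal heading to the neighbour's position) and
$\phi_{ij}$ the relative heading. Attraction is linear in distance and
odd in the bearing (the leading term of a Fourier expansion, zero for a
neighbour dead ahead); alignment is the first harmonic $\sin\phi$.
Attraction carries no dependence on the neighbour's orientation and
alignment none on its position; there is no explicit repulsion. The
social sum is normalised by the neighbour count $N_i$, so wall
avoidance and the averaged neighbour influence keep the same relative
weight at every group size.

### Wall avoidance

The wall stimulus is the pair $(D_W, \theta_W)$: the distance to the
impact point along the current heading and the signed angle between the
heading and the outward normal at that point ($\theta_W = 0$ is a
head-on approach; $|\theta_W| < \pi/2$ always, because a ray from
inside a disc meets it at an acute angle). The implemented response is

$$ f_W = k_w\,\cos\theta_W\,\mathrm{sign}(\theta_W)\,
   e^{-d_{\mathrm{wall}}/d_w} \,/\, T, \qquad T = D_W / v , $$

which turns the fish so that $|\theta_W|$ grows — away from head-on —
with a magnitude governed by the *time to impact* $T$ rather than the
raw distance, so that faster fish react further out. Two features
deserve
comment, because the functional form is a genuine design choice of this
package:

* the $1/T$ factor diverges at contact, so the model itself keeps fish
  inside the tank; the simulator's radial projection of an escaped fish
  is a counted numerical safety net, not part of the model, and a run
  that needs it more than rarely warns;
* the screening factor $e^{-d_{\mathrm{wall}}/d_w}$ in the distance to
  the wall (recoverable from $(D_W, \theta_W)$ by the law of cosines)
  confines wall avoidance to a band of width $d_w$ near the wall. An
  unscreened $1/T$ has a long interior tail that would dominate the
  whole tank and make fish orbit its centre; screening in $T$ itself
  would instead erase the grazing response precisely where containment
  is decided. Away from walls the screened response decays
  exponentially, which is also how the earlier single-fish wall ansatz
  behaved.

At exactly $\theta_W = 0$ the turning direction is drawn uniformly from
$\{-1, +1\}$ — a measure-zero tie-break that makes the head-on
configuration an unstable equilibrium.

### Interaction network

Neighbourhoods are topological, not metric: the default is the first
shell of Voronoi neighbours (pairs whose Voronoi cells share an edge),
with all-to-all and $K$-nearest-neighbour graphs as alternatives.
Because no Delaunay library is part of the package's dependency set,
first-shell adjacency is computed by the exact bisector test: two fish
are neighbours iff a positive-length segment of their perpendicular
bisector is closer to them than to every other fish, a one-dimensional
linear-programming feasibility problem per pair ($O(N^3)$ per frame,
negligible at $N \le 30$). The same test naturally yields chain
adjacency for collinear configurations, where no triangulation exists.
Ties from four or more co-circular points (cells meeting at a single
point) are resolved as *not* adjacent; test fixtures avoid such
degenerate configurations.

## Default parameters

| parameter | symbol | default | units | role |
|---|---|---|---|---|
| `wall_strength` | $k_w$ | 40 | rad | wall response scale |
| `wall_range` | $d_w$ | 0.3 | m | wall screening length |
| `persistence_length` | $\ell$ | 0.5 | m | $\tau = \ell/v$ |
| `noise_scale` | $\sigma$ | 1.2 | rad s$^{-3/2}$ | Wiener increment scale |
| `attract_coeff` | $k_p$ | 4 | rad m$^{-1}$ s$^{-1}$ per (m/s) | positional weight |
| `align_coeff` | $k_v$ | 3 | rad s$^{-1}$ per (m/s) | orientational weight |
| `speed_exponents` | $\alpha$ | (1, 1, 1) | — | $v$-scaling of each term |
| `attract_sat` | — | `Inf` | m | attraction saturation (open space) |

The tank radius defaults to 2 m and replicate speeds are drawn
uniformly from 0.1–1.0 m/s (about 1–10 body lengths per second at the
nominal body length of 0.1 m, which is used only to express speeds in
BL/s). These defaults were fixed once, by simulation pilots, to satisfy
three qualitative constraints simultaneously: fish stay inside the tank
over ten-minute runs at typical speeds; pairs cohere to a few body
lengths and polarize increasingly with speed (shoaling at slow,
schooling at fast swimming); and the per-frame interaction stiffness
stays in the regime where 12 fps sampling resolves the dynamics. With
the default speed scalings ($\alpha = 1$ everywhere, $\tau = \ell/v$)
the five constants are speed-independent, which is what makes pooling
replicates with different speeds meaningful.

Integration uses Euler–Maruyama steps. A requested step (default
0.02 s) is snapped to the nearest exact submultiple of the output frame
interval — 1/48 s at 12 fps — so saved frames lie exactly on the
integration grid. The neighbour graph is recomputed every step. One
shared RNG stream is consumed in fish-index order, which makes runs
bit-reproducible and rotationally equivariant at fixed seed. Halving
the step changes 120-s summary statistics by less than their replicate
standard error (asserted in the test suite).

Known limitation: below about 0.2 m/s an *isolated* fish's angular
noise ($\mathrm{sd}(\omega) = \sigma\sqrt{\tau/2}$ grows as speed
drops) can defeat any wall torque at finite step, producing occasional
sub-millimetre boundary projections; these are counted and surfaced,
never silent. Groups are unaffected (attraction pulls fish inward).

## Parameter inversion

Estimation follows the discrete-time form of the stochastic
differential equation. Writing $S_w, S_p, S_v$ for the wall,
attraction and alignment stimuli (neighbour-normalised, with the speed
scalings evaluated at the per-fish mean speed $\bar v$), one record per
frame transition reads

$$ \Delta\omega_k = g\!\left(\frac{\Delta t\,\bar v}{\ell}\right)
   \bigl( k_w S_w + k_p S_p + k_v S_v - \omega_k \bigr) + \varepsilon_k,
   \qquad \varepsilon_k \sim \mathcal N(0, \sigma^2 \Delta t), $$

and the package estimates $(k_w, \ell, k_p, k_v)$ by minimising the
squared residuals (bounded Levenberg–Marquardt; starting values
$\ell = 0.2$ m and unit coefficients, bounds $\ell \in [0.01, 5]$ m and
coefficients in $[0, 100]$, three jittered restarts on
non-convergence), with $\hat\sigma^2$ from the residual variance.

Three refinements matter at 12 fps and are the package's own
methodological contribution; each reduces to the textbook Ito/Euler
regression (`method = "euler"`, gain $g(x) = x$) as
$\Delta t/\tau \to 0$:

1. **Centred turning estimate.** The heading assigned to frame $k$ is
   the direction of the displacement $p_k \to p_{k+1}$, which estimates
   the true heading half a frame late. Differencing the two *adjacent*
   displacement headings therefore yields an angular velocity centred
   exactly on frame $k$ — a triangular-kernel average of $\omega$ over
   $(t_k - \Delta t,\, t_k + \Delta t)$. No further smoothing is
   applied (smoothing would bias $\tau$).

2. **Filter-aware gain and noise.** For a stationary
   Ornstein–Uhlenbeck process observed through that triangular kernel,
   the lag-0 and lag-1 covariances have closed forms in
   $x = \Delta t / \tau$, giving the exact one-frame relaxation
   coefficient $h(x) = 1 - C_1(x)/C_0(x)$ of the least-squares
   projection (`method = "ls"`) and a residual-variance gain
   $g(x) \to 11/20$ used to deconvolve $\hat\sigma$; the naive
   $\mathrm{Var}(\hat\varepsilon)/\Delta t$ underestimates $\sigma^2$
   by roughly $9/20$.

3. **Instrumented estimation (default).** The second difference of
   displacement headings mechanically contains the same headings that
   build the stimulus regressors. Whenever the stimuli feed back on the
   heading — alignment always does, wall avoidance near the wall — this
   correlation biases plain least squares substantially (tens of per
   cent on $\ell$ under schooling conditions). `method = "iv"`
   therefore solves the just-identified moment equations obtained by
   instrumenting every regressor with its own value two frames earlier,
   whose measurement window is disjoint from the response increment,
   using the exact discrete gain $1 - e^{-x}$. For a pure AR process
   this estimator is exactly consistent (filtered covariances are
   exactly geometric from lag 1 on), and in simulation it recovers all
   parameters of schooling pairs within a few per cent where plain
   least squares errs by 30–60%. Spurious roots of the moment system on
   weakly informative data are handled by multi-start over the
   persistence length, keeping the root with the smallest residual sum
   of squares.

In pooled mode the constants are shared across fish and replicates
while each fish's $\bar v$ enters the gains and speed scalings — the
model is then still linear in the coefficients given $\ell$, and the
five constants are estimated from all replicates together. Stimulus
states enter at the midpoint of the response increment (displacement
headings are already there; positions are averaged over the two
bracketing frames); with directly recorded orientations
(`track_kinematics(use_recorded = TRUE)`, mirroring datasets where
heading is measured rather than differenced), everything sits on frame
instants and the Euler regression on the integration grid is the exact
model class — noise-free data then reproduce the generating parameters
to optimizer tolerance.

The instrumented moment system is solved globally: for fixed $\ell$
the stimulus-instrument moments are linear in the coefficients, so the
problem reduces to one scalar equation in $\ell$, profiled on a
logarithmic grid and polished by bisection; multiple roots are resolved
by the residual sum of squares, and a fit whose moment equations have
no root inside the parameter box reports itself as not converged
rather than returning a bound-pinned pseudo-estimate.

Residual diagnostics report normal QQ data and the lag-1 residual
autocorrelation; the binned stimulus–response curves subtract the two
other fitted components from the response and bin what remains against
each scaled stimulus in turn — under the model the bin means fall on a
line through the origin whose slope is the corresponding coefficient.
The QQ correlation doubles as an adequacy gate: trajectories from the
slowest replicates can scrape the wall with angular transients that
alias at 12 fps, and the resulting fits announce themselves by grossly
non-Gaussian residuals (QQ correlation near 0.5 instead of 0.999);
analyses that pool or compare many fits exclude, and count, fits
failing this gate — mirroring the practice of trusting the noise
estimate only after the residuals pass a normality check.

## Synthetic data as stand-in for experiments

No tracking data are shipped; `make_dataset()` emulates the
experimental design the model targets: group sizes
$\{1, 2, 5, 10, 15, 30\}$, five replicates per size, 120 s at 12
frames/s in the 2-m tank, a common per-replicate speed (fish in a
replicate synchronise their speed; the value varies between
replicates), optional isotropic Gaussian observation noise on
positions, and an optional group-size scaling $(2/N)^\gamma$ of the two
social coefficients that emulates the observed decline of social
responsiveness in the largest confined groups. The manifest records
every replicate's seed, speed and true parameters, so any replicate can
be regenerated bit-exactly and recovery studies know their ground
truth.

What the generator does *not* emulate: identity swaps and occlusions
(only clean frame gaps), speed fluctuations within a replicate
(tangential speed is exogenous and constant, reflecting the observed
decorrelation of speed from angular velocity), three-dimensional
manoeuvres, and any behavioural state change. Passing the recovery
tests therefore shows that the inversion is correct for data generated
by the model class, not that real fish obey the model.

## Validation protocol

The test suite asserts, at desk scale: the stationary
Ornstein–Uhlenbeck law of the free angular velocity
($\mathrm{Var} = \sigma^2\tau/2$, autocorrelation time $\tau$, each
within 3 Monte-Carlo standard errors over $10^6$ steps); exact
ray–circle geometry against an independent quadratic-formula oracle on
$10^4$ random states; zero boundary projections over ten simulated
minutes at $N = 1$ and $N = 10$; median recovery of
$(\ell, k_v, \sigma)$ within 10% and $k_w$ within 20% from twenty
five-replicate pair studies; a positive Spearman association between
swimming speed and pair polarization (five speeds, twenty runs each);
re-identification of an imposed group-size decline of $k_v$ by
per-replicate refits (negative Spearman association across
$N \in \{2, 5, 10, 15, 30\}$); a $K$-nearest-neighbour sweep whose
cumulative prediction error over a nine-replicate reference set
($N \in \{5, 10, 15\}$, twenty simulations per cell) is minimised
within $\pm 1$ of the mean first-shell Voronoi degree; the closed forms
of the order statistics; near-unit QQ correlation of fit residuals; and
binned residual responses on the fitted line within two standard
deviations per bin. `scripts/acceptance.R` re-runs the main
computations end to end from a single seed and writes the resulting
numbers as JSON.

## Worked example

```{r example}
library(ptwschool)

params <- model_params()
tank <- tank_geometry(radius = 2)

# one two-fish replicate, two minutes at 12 fps
cfg <- sim_config(tank, n_fish = 2, params = params, speeds = 0.6,
                  duration = 120, transient = 20)
tracks <- simulate_school(cfg, seed = 1)

# collective observables
cs <- collective_series(tracks)
c(P = mean(cs$P), D = mean(cs$D))

# invert the trajectories back to parameters (five pooled replicates
# give far better estimates; see the README)
recs <- build_regression(track_kinematics(tracks), tank, "all", params)
fit <- fit_params(recs, mode = "pooled")
fit
residual_diagnostics(fit)$qq_cor
```
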