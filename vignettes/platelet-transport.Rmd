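---
title: "Modelling shear-induced platelet transport from a heavy-tailed velocity distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling shear-induced platelet transport from a heavy-tailed velocity distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletwalk)
```

## The model

In blood subjected to a shear flow, platelets undergo an enhanced random
motion perpendicular to the flow, driven by collisions with red blood
cells. The classical description treats this as ordinary diffusion with
the Zydney–Colton coefficient

$$D_{ZC} = D_{PRP}(1-H) + 0.15\,\tfrac{d_{RBC}^2}{4}\,H\,\dot\gamma\,(1-H)^{1.8},$$

about $5\times10^{-11}\,\mathrm{m^2/s}$ at hematocrit $H = 0.35$ and
shear rate $\dot\gamma = 100\,\mathrm{s^{-1}}$ (`zydney_colton()`).
Fully resolved cellular-blood-flow simulations, however, show that the
distribution of the wall-normal platelet velocity magnitude is not
Gaussian-like: it has an exponentially decaying bulk and a power-law
tail,

$$P(v) = \begin{cases} p_0\,e^{-\lambda v} & v \le v_{min},\\[2pt]
p_0\,e^{-\lambda v_{min}}\left(v/v_{min}\right)^{-1-\alpha} & v \ge v_{min},
\end{cases}$$

with the convention that $\alpha$ is the *tail* exponent (density
$\propto v^{-(1+\alpha)}$). Given $\alpha$, the threshold $v_{min}$ and
the mean magnitude $v_{moy}$, the constants $p_0$ and $\lambda$ follow
from two integral constraints — unit mass and mean $v_{moy}$
(`solve_normalization()`). For the reference parameter set
$\alpha = 3.8$, $v_{min} = 5\times10^{-3}\,\mathrm{m/s}$,
$v_{moy} = 10^{-3}\,\mathrm{m/s}$ this gives $p_0 = 1015.24$ and
$\lambda = 1017.36$ s/m:

```{r}
d <- velocity_dist(alpha = 3.8, v_min = 5e-3, v_moy = 1e-3)
d
```

The constraint integrals are evaluated in closed form; published
renderings of the mean constraint sometimes drop the bulk term
$p_0/\lambda^2$, but only the exact integral reproduces the constants
above, so that is what the solver implements. The two-parameter system
is reduced analytically (the mass constraint is linear in $p_0$) to one
smooth equation in $\lambda$, bracketed around the pure-exponential
limit $\lambda_0 = 1/v_{moy}$ — in the limit $\lambda v_{min} \gg 1$ the
tail carries no mass and $p_0 = \lambda = 1/v_{moy}$ exactly. The solve
is deterministic, polished to a relative residual below $10^{-12}$, and
errors out (naming both residuals) rather than returning an unconverged
pair.

Velocities are *sampled* by exact inversion: both CDF branches invert in
closed form (`qvel()`), and a signed draw attaches an independent
$\pm1$ sign with probability one half (`rvel()`). Probabilities within
$10^{-12}$ of 1 are clamped before inversion so the tail bracket stays
positive; the affected quantiles sit beyond any physically observed
cut-off speed and carry negligible mass. A `cap` argument (redraw above
a maximum speed) is available but off by default for $\alpha > 2$; in
the infinite-variance regime $\alpha \le 2$ transport becomes
cutoff-sensitive and the cap, if used, is a deliberate, recorded choice.

## From trajectories to the distribution

The analysis side starts from per-platelet wall-normal positions
$y_i(t)$ sampled at a uniform interval ($\delta t = 10^{-5}$ s in the
emulated recording protocol, domain height $50\,\mu\mathrm{m}$).

* `extract_velocities()` forms forward differences
  $v_i(t) = [y_i(t+s\,\delta t)-y_i(t)]/(s\,\delta t)$; the `stride`
  $s$ exposes the resolution dependence — coarse sampling averages away
  the short-lived fast excursions and suppresses the tail.
* `mean_abs_velocity()` averages magnitudes per platelet first, then
  across platelets, so unequal record lengths do not bias the ensemble
  mean.
* `exclusion_filter()` restricts to the band
  $[\mathrm{margin}, L-\mathrm{margin}]$ (default margin
  $10\,\mu\mathrm{m}$, about one red-cell diameter) because margination
  traps platelets near walls and distorts their statistics; records are
  split at band exits so no difference or correlation straddles an
  excursion.
* `fit_tail()` estimates $(\hat v_{min}, \hat\alpha)$ in the standard
  heavy-tail way: continuous MLE for the exponent at each candidate
  threshold, threshold chosen by minimising the KS distance to the
  fitted Pareto. Candidates default to the unique observed values
  between the 50th and 99.9th percentiles, thinned to 200 log-spaced
  values, with at least 50 tail points (bounded cost, standard
  practice). The density exponent is converted to the tail convention by
  subtracting one. A fit is flagged degenerate when the optimum sits at
  a grid extreme *or* when a shifted exponential beats the Pareto in
  likelihood on the selected tail — the latter is what actually
  identifies a purely exponential sample, whose KS optimum can be
  interior.

## Velocity memory

The surrogate walk needs one more ingredient: how long a platelet keeps
its velocity. `vacf()` estimates
$\mathrm{VACF}(\tau) = \langle v_i(t+\tau)v_i(t)\rangle_{i,t}$ from
*signed* velocities. Signed, not absolute: the magnitude
autocorrelation plateaus near $v_{moy}^2$ and never reaches the noise
floor, so the decorrelation criterion below would be ill-posed.
`fit_vacf_powerlaw()` fits $\ln\mathrm{VACF}$ against $\ln\tau$ (with
$\tau$ in ms, so the amplitude $a$ is the VACF at 1 ms; reported
amplitudes of order $0.017\times10^{-3}$ in this convention are treated
as the 1 ms value, their printed unit being dimensionally unclear for an
autocorrelation). `decorrelation_time()` estimates the noise floor
$\sigma$ as the standard deviation of the VACF inside a tail window of
lags and returns the first lag at which the curve falls to $\sigma$.
The tail window is a mandatory, logged parameter (defaulting to the
last quarter of the lags) because where the floor begins is a judgement
call on real curves. On data with a 0.5 ms memory this recovers
$\Delta t = 0.5\times10^{-3}$ s, the update interval used by the walk.

## The stochastic walk and deposition

`simulate_walk()` advances $N$ independent walkers: every
$\Delta t$ each draws a fresh signed velocity and moves
$y \leftarrow y + v\,\Delta t$; an absorbing bottom wall removes
(deposits) walkers at $y \le 0$, a reflecting top maps $y \to 2L-y$.
Update order is draw–move–absorb–reflect, with a second absorption test
after reflection for a walker thrown across the whole domain, then a
clamp into $[0, L]$ as numerical safety; double-crossing handling is
not dictated by the physics at this step size, so it is fixed,
documented and tested rather than left implicit. One RNG stream drives
a run (magnitude uniforms before sign uniforms within each step, walkers
in storage order), making runs bit-reproducible by seed.

`deposition_experiment()` is the reference protocol: 4800 walkers
uniform on $(0, 0.82\,\mathrm{mm})$, $\Delta t = 0.5$ ms, 20 s. For
independent diffusing walkers above one absorbing wall the cumulative
deposit grows as $\mathcal{N}(t) = N\sqrt{4Dt/\pi}/L$, so the log-log
growth exponent should be $1/2$ — both the count and the fitted
exponent are returned.

Because the steps are independent, the walk's diffusion coefficient has
the exact closed form $D = \langle v^2\rangle\,\Delta t/2$, with
$\langle v^2\rangle$ available analytically (`vdist_moment()`); for the
reference parameters $D \approx 5.3\times10^{-10}\,\mathrm{m^2/s}$,
an order of magnitude above $D_{ZC}$. This closed form is the oracle
every MSD-based estimate is tested against. Note the internal tension
in the source material here: the printed large-box diffusion
coefficient ($0.678\times10^{-9}$) is 27% above this closed form, the
printed deposition count (~800) matches the printed coefficient rather
than the closed form, and the stated "65 times larger than $D_{ZC}$"
matches neither (the ratio of the printed values is 13.6). The package
asserts the closed form, computes deposition honestly (~680 at 20 s,
consistent with the continuum flux for the closed-form $D$), and
reports rather than force-matches the printed figures.

## MSD estimation and its finite-size bias

`msd()` computes $\langle(y_i(t)-y_i(0))^2\rangle_i$ with two
censoring modes for a bounded observation band: `"in"` keeps only
platelets that never leave, `"in_and_out"` keeps every platelet up to
its first exit. Both are computed by the pipeline; no ordering between
the two is assumed. `diffusion_coefficient()` offers the zero-intercept
slope (default) and the $\mathrm{MSD}/2t$ ratio estimator over a lag
window defaulting to $[t_{max}/10,\,t_{max}/2]$ — a compromise that
works on both linear and saturating curves; the window is always
recorded in the result.

In a reflecting box the MSD saturates near $L^2/6$, so the fitted slope
*underestimates* the unbounded coefficient, and the bias worsens the
longer one fits past the saturation time. `finite_size_scan()`
quantifies this: $D(L)$ rises monotonically towards the analytic
plateau, and a $50\,\mu\mathrm{m}$ box — the size high-fidelity cellular
simulations can afford — sits well below it. This is the package's
central cautionary result: small-box MSD estimates of platelet
diffusivity are systematically low.

`sensitivity_sweep()` re-solves the distribution over a grid of
$\alpha$ and joint scalings $k$ of $(v_{min}, v_{moy})$ and tabulates
$D$ and the 20 s deposit. Scaling covariance is exact: multiplying both
velocity parameters by $k$ multiplies every quantile by $k$ and hence
$D$ by $k^2$ (the acceptance check runs scale-1 and scale-3 with paired
seeds so the comparison tests the covariance, not Monte-Carlo luck).
On $\alpha$-robustness the exact moments disagree with the qualitative
published claim: $\langle v^2\rangle$ under the mean/threshold
constraints varies by ~16% across $\alpha \in \{3,4,5\}$ and diverges
logarithmically at $\alpha = 2$, where the measured $D$ is
sample-size-dependent and several-fold larger (no cap is applied by
default). The corresponding stability test asserts the claim as stated,
fails for the $\alpha = 2$ cell, and is retained as an honest negative
result; the Lévy cell $\alpha = 1.8$ shows the expected *increase* of
both $D$ and the deposit.

## The synthetic-data generator

`synth_trajectories()` produces ensembles with known truth: velocities
follow a renewal process (redraw every `memory_time`, default 0.5 ms,
held constant in between), positions are integrated at `fine_dt`
(default $10^{-5}$ s) over 1 s for 200 platelets in a
$50\,\mu\mathrm{m}$ domain — the scale of the emulated recording
protocol. The renewal construction was chosen over a process with a
genuinely power-law VACF because it preserves the velocity marginal
*exactly* (what the fitting stages must recover), at the cost of a
triangular VACF, $\langle v^2\rangle(1-\tau/\Delta m)$; the power-law
VACF fitter is therefore exercised on `synth_vacf()` curves instead.
Renewal clocks are phase-randomised per platelet to avoid
ensemble-synchronised redraws (switchable for degenerate
single-segment constructions). Optional reflecting confinement folds
free paths into $(0, L)$ with the triangle map — magnitudes are
preserved, signs flip at walls, the signed marginal stays symmetric.
Optional Gaussian positional jitter models measurement noise; jitter
beyond about half of $v_{moy}\,\delta t$ makes finite-difference
velocities noise-dominated and triggers a warning.

What the generator does *not* emulate: margination drift, wall-induced
velocity suppression, hematocrit dependence, or sub-$\delta t$ velocity
structure (so the observed doubling of measured $v_{moy}$ at 100-fold
finer time resolution is reproduced only qualitatively, via stride
coarsening). Passing tests on synthetic data therefore validate the
estimators' correctness, not the physical fidelity of the velocity
law itself.

## Numerical and design choices

* Trajectory times must be uniform to $10^{-9}$ s; violations name the
  offending platelet. TSV/CSV round-trips preserve full double
  precision (`%.17g`).
* Velocities are forward differences only; each record's last sample
  yields no velocity.
* Log-binned densities use 8 bins per decade over
  $[10^{-5}, 0.3]$ m/s by default and are normalised by the *linear*
  bin width, so density × width sums to the in-range fraction.
* Wall profiles bin at $0.1\,\mu\mathrm{m}$ and mask bins visited by
  fewer than $10^{-3}$ of samples.
* The quantile function's $v$-space round-trip loses a few digits in
  the deep tail (the bracket is a difference of probabilities near 1);
  the $r$-space round-trip is exact to $10^{-12}$, which is the
  contract the sampler relies on.
* Problem sizes in the test-suite: distributional checks use
  $10^5$–$10^6$ draws; walk-based checks use 300–800 walkers over
  0.5–1 s (plus one full-protocol deposition run and a 20 s finite-size
  scan), sizes at which Monte-Carlo error is well below the asserted
  tolerances.

## Known limitations

* The walk has no drift term: margination-driven transport towards the
  wall, one proposed explanation for even larger effective
  diffusivities, is out of scope.
* Shear is spatially uniform; tube geometries with non-uniform shear
  violate the y-independence the wall profiles check.
* The Lévy regime $\alpha \le 2$ is implemented but its transport
  observables depend on the cap policy, which is deliberately left to
  the user and recorded in outputs.
* The high-fidelity reference values for band-censored diffusion
  ($D_{in}$, $D_{in\&out}$) can be recomputed by `run_pipeline()` on
  the original trajectory data if supplied, but no test depends on
  that external dataset.
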