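---
title: "aptfit: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aptfit: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptfit)
```

aptfit analyses the standard in vitro assays used to characterize
small-molecule binding to structured RNAs: 2-aminopurine fluorescence
titrations, stopped-flow association kinetics, continuous-variation
(Job) plots, isothermal titration calorimetry, and pull-down RT-qPCR
enrichment. This vignette documents the models, the parameters that
matter, the numerical machinery, and the design decisions taken where
the conventional lab workflow leaves the analysis under-specified.

## Equilibrium binding models

Three models are available in `fit_titration()`, all operating on
normalized signal $(F - F_0)/(F_f - F_0)$ against ligand concentration.

**Single site with ligand depletion.** At 0.5 µM RNA and sub-µM
dissociation constants, the common excess-ligand hyperbola is biased;
the exact bound fraction solves the 1:1 mass balance as a quadratic,

$$f_b = \frac{S - \sqrt{S^2 - 4\,c_\mathrm{RNA} c_L}}{2\,c_\mathrm{RNA}},
\qquad S = K_D + c_\mathrm{RNA} + c_L,$$

and the fitted curve is `amplitude * f_b + baseline`. We compute the
root in the algebraically equivalent form
$2 c_L / (S + \sqrt{S^2 - 4 c_\mathrm{RNA} c_L})$, which avoids the
catastrophic cancellation of $S - \sqrt{\cdot}$ far from saturation
(the naive form loses ~8 significant digits at low occupancy). A legacy
normalization that divides the quadratic numerator by
$(2 c_\mathrm{RNA} - d)$ appears in some published workflows; it is
dimensionally awkward (it mixes a concentration with a unitless signal
parameter), so the additive `amplitude`/`baseline` form is the default
and the literal form is available via `literal_form = TRUE` for
comparison — the two coincide as the offset parameter goes to zero.

**Hill model.** $d\, c_L^{\,n} / (K_{D}^{\,n} + c_L^{\,n})$ with the
Hill coefficient free by default (bounds 0.2–8). Whether a given lab
fit held $n$ fixed is rarely reported, so no default constraint is
imposed; fix it by passing explicit `param_spec`s.

**Two-site binding polynomial.** With stepwise *association* constants
$K_i = 1/K_{D,i}$ the partition function is
$Z = 1 + K_1 L + K_1 K_2 L^2$ and the mean occupancy
$\nu = (K_1 L + 2 K_1 K_2 L^2)/Z \in [0, 2]$. The fitted signal is
`amplitude * nu / 2`, so that each binding event contributes equally
and the curve saturates at `amplitude`. The cooperativity factor is
$y = 4 K_{D,1}/K_{D,2}$: independent identical sites give
$K_{D,2} = 4 K_{D,1}$ (statistical factor between the stepwise
macroscopic constants), hence $y = 1$; $y < 1$ is negative, $y > 1$
positive cooperativity. The package reports macroscopic stepwise
constants only; decomposing them into microscopic site constants plus
an interaction factor is deliberately not attempted, since that
decomposition is not identifiable from a single binding curve.

**Total versus free ligand.** The customary lab fits use *total*
ligand as the abscissa even though the RNA is 0.5 µM; that convention
is the default here for comparability. An exact free-ligand mode
(`free_ligand_mode = TRUE`) solves $L + c_\mathrm{RNA}\,\nu(L) = c_{L,\mathrm{tot}}$
by bisection at every model evaluation. At this RNA concentration the
two conventions differ mostly in the first stepwise constant, because
depletion is strongest at the low-concentration points.

## Fit engine

All models go through one bounded nonlinear least-squares path
(`nls_fit()`):

* optimizer: `stats::nlminb` (quasi-Newton with box constraints),
  relative tolerance 1e−10 (tighter than the 1e−8 contract), iteration
  cap 10 000;
* every equilibrium or rate constant is fitted as $\log_{10}$ of its
  value — positivity for free, curvature closer to quadratic — and
  standard errors are mapped back by the delta method;
* after the optimizer stops, up to ten damped Gauss–Newton steps polish
  the optimum; for linear models this lands on the closed-form
  least-squares solution to machine precision (verified against `lm()`
  to ten significant digits in the test suite);
* if the first attempt fails to converge or finishes on a bound, a
  five-point multi-start spread across the (internal-scale) parameter
  boxes is tried and the best optimum kept;
* uncertainties come from the Gauss–Newton covariance
  $\hat\sigma^2 (J^\top W J)^{-1}$ at the optimum, with a numerical
  central-difference Jacobian; a singular normal matrix falls back to a
  pseudo-inverse, and non-convergence is reported as
  `converged = FALSE`, never as an error;
* `bootstrap_ci()` offers residual-resampling percentile intervals as
  an alternative uncertainty, restarted from the point estimate for
  speed. The "fit error" reported by instrument software is treated as
  a 1-SE quantity throughout.

## Stopped-flow kinetics

Traces are fitted on the raw signal scale to
$F = A(1 - e^{-k_\mathrm{obs} t})$ with $A$ free (a net-decreasing
signal simply yields negative $A$ with a warning) and $k_\mathrm{obs}$
log-parameterized. $k_\mathrm{obs}$ versus concentration is fitted by
weighted ($1/\mathrm{SE}^2$) linear regression; the slope is $k_on$
and the intercept estimates $k_\mathrm{off}$ under the
pseudo-first-order scheme. The usual 10× excess rule is relaxed to a
*warning* at below 4× ligand over RNA, because the standard design's
lowest point (1 µM ligand vs 0.5 µM RNA) intentionally violates it.
Mixing dead time is not modeled; time zero is the first sample.
`simulate_decay()` draws the dissociation curve $e^{-k_\mathrm{off}t}$
with a 95 % band built by perturbing the *rate* by ±1.96 SE (clamped at
zero). A pointwise delta-method band is the obvious alternative; both
agree at $t = 0$, and the rate-perturbation band was chosen because it
is itself a pair of valid decay curves. Its width grows only up to
$t^* = \ln(k_\mathrm{hi}/k_\mathrm{lo})/(k_\mathrm{hi}-k_\mathrm{lo})$
and then collapses as both envelopes approach zero.

## Job plots

`tangent_intersection()` drops points within `exclusion_halfwidth`
(default 0.08 in mole fraction — one grid step of the standard
11-point design) of the empirical peak, fits an ordinary least-squares
line to each remaining flank (at least `min_points = 3` per side), and
intersects. The stoichiometry is $m = (1 - x_{max})/x_{max}$. Ties at
the peak break toward smaller mole fraction; a boundary maximum warns.
With finite affinity the flanks are genuinely curved, so "tangent"
means the OLS line through the retained flank points — the
conventional manual procedure.

The two-site simulator (`gen_job()`) computes species concentrations
exactly at every mixing ratio. Its default readout is **total bound
ligand** $c_\mathrm{RNA}\,\nu$, consistent with the titration signal
model (each binding event contributes equally). This matters: if the
signal were proportional to the doubly bound species only, then with
*comparable* stepwise constants the singly bound intermediate
accumulates on the RNA-excess flank, the flank curves, and the tangent
intersection lands measurably below the stoichiometric point even at
vanishing $K_D$ (exact species algebra puts it near $x = 0.27$ on the
default grid). The bound-ligand readout is piecewise linear in the
strong-binding limit with its apex exactly at $1/(1+m)$ regardless of
the ratio of stepwise constants, which is what makes the 2:1 diagnostic
$x \approx 1/3$ robust. The doubly-bound-only readout remains available
as `readout = "saturated_complex"`.

## ITC

Heats are modeled in kcal per mole of injectant (normalized), as
exported by instrument software; raw-power baseline integration is out
of scope. For a fixed-volume perfusion cell (iTC200 geometry, V₀ =
200 µL) the composition after cumulative injected volume $v$ follows
the standard displacement bookkeeping
$M = M_0 \frac{1 - v/2V_0}{1 + v/2V_0}$,
$X = L_\mathrm{syr}\frac{v/V_0}{1 + v/2V_0}$, and the per-injection
heat applies the displaced-volume correction
$q_i = [Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}]/(c_\mathrm{syr} dV_i) + q_\mathrm{dil}$.
This convention is isolated in `cell_concentrations()` so an
alternative (exponential-dilution) rule could be swapped in one place.

Two models: the Wiseman "set of identical sites" closed form
(parameters $n$, $K_D$, $\Delta H$, offset) and the two-interdependent
non-equivalent sites binding-polynomial model (stepwise $K_{D,1}$,
$K_{D,2}$, $\Delta H_1$, $\Delta H_2$, offset), whose free-ligand mass
balance is solved by 60-step vectorized bisection (interval shrinks by
$2^{-60}$, comfortably below the 1e−10 relative contract). The two
models coincide exactly on the statistical-equivalence line
$K_{D,1} = k/2,\ K_{D,2} = 2k,\ \Delta H_1 = \Delta H_2$, which the
suite checks to 1e−8. Temperature is metadata only (no $\Delta C_p$).
The customary option to discard the first injection defaults *off* for
synthetic data and is a flag (`--drop-first`) for real files.

## Synthetic data: the stated world

Generators default to the published experimental designs: titrations
at 0.5 µM RNA over the 14-point 0–45 µM ligand series; 700 s traces at
post-mix ligand 1, 2, 6, 10 µM sampled at 1 Hz; 11-ratio Job series at
20 µM total; iTC200 schedules of 20 × 2 µL (73 µM RNA / 1.84 mM
ligand, 25 °C) and 30 × 1.3 µL (48 µM / 1.15 mM, 37 °C). Noise is
additive Gaussian with SD expressed as a fraction of the dynamic range
(first-injection heat for ITC); published work does not state noise
magnitudes, so the defaults — 2 % for titrations, Job and ITC, 1 % for
traces — were chosen once as typical of well-behaved instruments and
are not tuned. ITC enthalpies are likewise unpublished for these
systems; the synthetic defaults ($\Delta H = -10$; $-8/-12$ kcal/mol)
are explicitly arbitrary. Every generator is a pure function of
(parameters, design, seed): seeding is local and the global RNG stream
is restored afterwards.

What a green recovery test establishes: that the estimator recovers
the generating parameters from data whose model class, design and
noise it assumes. What it does not establish: robustness to real
instrument artifacts — photobleaching, baseline drift, injection
spikes, dead-time distortion — none of which are emulated.

## Degenerate inputs and edge behavior

Constant titrations or flat traces yield `converged = FALSE` or a
near-zero amplitude with an inflated SE rather than an error; an
all-equal Job series is a degenerate-input error; a thermogram of pure
offset fits $\Delta H \approx 0$ with an unidentifiable $K_D$ flagged
through its SE. Normalization `(F - F0)/(Ff - F0)` uses the first and
last points, so it spans 0→1 whether raw fluorescence rises or falls
upon binding, and errors when the endpoints coincide.

## Known limitations

Single-curve fits only (no global multi-curve analysis); no Bayesian
uncertainty; no double-exponential or conformational-selection kinetic
schemes; no curvature-corrected Job analysis; no ITC raw-thermogram
processing or kinITC; qPCR assumes amplification efficiency 2 with no
standard-curve correction, and significance testing is out of scope.
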