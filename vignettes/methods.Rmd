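---
title: "Models and methods: peptide anion binding and aggregation kinetics by NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: peptide anion binding and aggregation kinetics by NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkin)
```

`synkin` analyzes solution-NMR measurements of weak monovalent-anion binding
to short cationic peptides and of the aggregation such binding can induce.
The built-in peptides are the 15-mer N-terminal segment of α-synuclein,
MDVFM**X**GLS**X**A**X**EGV with X = K, R or H at positions 6, 10 and 12
(`builtin_peptide("1")` through `"3"`). This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where the design was genuinely open.

## 1. Finke–Watzky two-step aggregation kinetics

### Model

Aggregation is modeled by the minimal two-step scheme: slow continuous
nucleation A → B (rate constant $k_1$, h⁻¹) and fast autocatalytic growth
A + B → 2B ($k_2$, mM⁻¹h⁻¹). The soluble monomer obeys

$$\frac{d[A]}{dt} = -k_1 [A] - k_2 [A]\,([A]_0 - [A]),$$

whose closed-form solution is a falling logistic,

$$[A](t) = \frac{K}{1 + e^{\,r\,(t - t_{\max})}},\qquad
K = A_0 + \frac{k_1}{k_2},\quad r = k_1 + k_2 A_0,\quad
t_{\max} = \frac{\ln(k_2 A_0 / k_1)}{r}.$$

$t_{\max}$ is the inflection of the product curve $[B] = A_0 - [A]$, i.e. the
time of maximum growth rate, which equals $rK/4$ (`fw_max_rate()`).

### Phase times from the jerk

The induction time $t_1$ and the plateau-onset time $t_2$ are defined as the
zeros of the *jerk*, the third time derivative of $[B](t)$: $t_1$ is the time
of maximum acceleration (lag → exponential growth), $t_2$ the time of
greatest deceleration (growth → plateau). For a logistic these are analytic,

$$t_{1,2} = t_{\max} \mp \frac{\ln(2 + \sqrt{3})}{r},$$

symmetric about the inflection, so $t_{\max} = (t_1 + t_2)/2$ exactly
(`fw_jerk_times()`, inverted by `fw_tmax_from_jerk()`). An independent check,
`fw_jerk_times_numeric()`, locates the same zeros by bracketing and bisecting
the finite-difference third derivative, never using the analytic expression;
the two routes agree to better than $10^{-5}$ h across the tested parameter
grid. The finite-difference stencils are the fourth-order central formulas
with step $h = t_{\mathrm{hi}}/400$: for a third derivative, a much smaller
step lets floating-point roundoff ($\varepsilon/h^3$) overwhelm the signal,
so the step is deliberately coarse and the truncation error, $O(h^4)$, is
driven below the agreement tolerance instead.

### Degenerate regime

When $k_1 \ge k_2 A_0$ the logistic has no lag phase within $t \ge 0$
($t_{\max} \le 0$); nucleation is not slow relative to growth and the
jerk-based phase decomposition is meaningless. `fw_params()` flags the
regime, `fw_tmax()` warns, and `fw_jerk_times()` refuses rather than
returning negative "phase times". Fits that land there are marked `poor`.

### Fitting

`fit_fw()` performs nonlinear least squares of the closed-form monomer curve
against a monomer-loss trace. Choices:

* **Fit target** is the monomer $[A](t)$ — the experimentally monitored
  quantity. The complement is available through `to_aggregate()`.
* **$A_0$ fixed** at the known experimental concentration (default 2 mM);
  `fit_amplitude = TRUE` co-fits a scale factor for traces that plateau above
  zero monomer (incomplete conversion).
* **Positivity** is enforced by optimizing $\log k_1, \log k_2$; no bound
  constraints are needed and parameter excursions cannot go negative.
* **Initialization** is feature-based: the apparent rate $r_0$ from the
  25–75% crossing interval of the drop ($\Delta t = 2\ln 3 / r$ for a
  logistic), $t_{\max,0}$ from the 50% crossing, then inversion
  $k_1 = r/(1 + e^{r t_{\max}})$, $k_2 = (r - k_1)/A_0$. Eight additional
  deterministic starts from a low-discrepancy (van der Corput) lattice of
  ±1.5 log-unit offsets guard against bad features; the global RNG is never
  touched, so identical inputs give bit-identical fits.
* **Optimizer**: `stats::optim` BFGS, with a Nelder–Mead polish and a final
  BFGS pass (no Levenberg–Marquardt implementation is available in the
  dependency set; on this 2-parameter problem BFGS from the feature-based
  start recovers noise-free generating parameters to ~1e-15 relative).
* **Quality**: the published analysis reports a qualitative good/poor
  dichotomy without a criterion; the package uses $r^2 \ge 0.98$ by default,
  configurable via `r2_threshold`.
* **Standard errors** come from the numeric Jacobian at the optimum
  (Gauss–Newton covariance), delta-method transformed off the log scale.

The published three-condition perchlorate table is shipped as
`clo4_kinetics_table()`. Its `kmax` column is carried verbatim as an
annotation only: the defining formula was not stated and no candidate
($k_1 + k_2$, max-rate$/A_0$, …) reproduces all rows after rounding, so the
package exposes the unambiguous maximum growth rate $rK/4$ instead. Note also
that recomputing $t_{\max}$ from the *printed* $k_1, k_2$ misses the printed
$t_{\max}$ by ~10% — consistent with the rate constants being rounded to 1–2
significant digits — so the package asserts only the rounding-free midpoint
identity $t_{\max} = (t_1+t_2)/2$ against that table.

## 2. Trace normalization

Aggregation is monitored by the integrals of the 3V, 8L and 15V methyl
signals against an external reference (sodium ethyl sulfate).
`normalize_trace()` forms each probe's ratio to the reference,
self-normalizes to $t = 0$, and averages the probes (unweighted mean by
default; `combine = "median"` for outlier robustness — the combination rule
was not stated in the source study). Self-normalization makes the result
exactly invariant to per-probe calibration constants and to rescaling of the
reference. The maximum pairwise relative spread among probes is attached as a
per-time quality metric. Values up to 5% above $A_0$ are tolerated as
integration noise and clipped (with a count); larger excursions are rejected.
pH vs pD is metadata recorded verbatim; no isotope correction is applied.

## 3. Fast-exchange binding isotherms

Weak 1:1 anion association in fast exchange gives an observed amide shift
that is the population-weighted average of free and bound states:

$$\delta_{\mathrm{obs}}(c) = \delta_{\mathrm{free}} +
\delta_{\max}\,\frac{K_a c}{1 + K_a c},$$

with $c$ the **total** salt concentration (excess-ligand approximation — the
titrations run to ~93 equivalents over 5 mM peptide, a ≥90-fold excess, so
free ≈ total; `equivalents_to_molar()` converts, and the exact quadratic
1:1 solution is available via `fit_ka(..., exact = TRUE, P0 = )` for cases
where the approximation is in doubt). $\delta_{\max}$ is signed: upfield
(negative) limiting shifts indicate association. Each amide is fit
independently — the per-residue $K_a$ is the reported quantity; no global
shared-$K_a$ fit is imposed.

`fit_ka()` optimizes $(\log K_a, \delta_{\mathrm{free}}, \delta_{\max})$ by
least squares with a deterministic multi-start over log-spaced $K_a$ guesses
(0.1–100 M⁻¹). With $K_a \sim$ 1–10 M⁻¹ and titrations to 0.5 M, saturation
($K_a c_{\max}$ = 0.5–5) is only partly approached; when
$K_a c_{\max} < 0.5$ the fit is flagged "weak binding: Ka and delta_max
poorly separable" rather than silently returned. A flat series yields
$K_a = 0$ with a warning.

## 4. Chemical shift perturbation maps

`csp()` computes per-residue $\Delta\delta$ = (bound − free) amide shifts,
signed, on unreferenced shifts as measured (no referencing correction, which
cancels in the difference only if both spectra share a reference — the source
data are stated to be unreferenced, and the package stores them verbatim).
Entries with $|\Delta\delta| \le$ 0.005 ppm (the experimental error bubble,
configurable) are flagged insignificant. Upfield entries are classed
"association", downfield "non-specific" (ionic strength/susceptibility).
`bubble_map_export()` emits plot data with bubble **area** proportional to
$|\Delta\delta|$ (radius $\propto \sqrt{|\Delta\delta|}$).

`neighbor_asymmetry()` evaluates the empirical rule that the amide on the
N-terminal side of a cationic side chain at position $i$ shifts more than the
one on its C-terminal side: $|\Delta\delta_i| > |\Delta\delta_{i+1}|$. The
rule is a strict inequality, so exact ties count as exceptions; positions
without both observable neighbors are skipped and noted.

## 5. Karplus analysis and temperature coefficients

`karplus_j()` implements $J(\varphi) = A\cos^2\theta + B\cos\theta + C$,
$\theta = \varphi - 60°$. The coefficient set is configuration with a
documented default ($A = 6.51$, $B = -1.76$, $C = 1.60$ Hz — the widely used
Vuister–Bax ³J(HN–Hα) parameterization); the source study reports only
qualitative Ramachandran-region assignments, so no coefficient set of its own
exists to adopt. `karplus_invert()` solves the quadratic in $\cos\theta$ and
returns all 0/2/4 dihedral solutions in [−180°, 180°] with a coarse region
tag; a forward–inverse round trip is tested on a 1° grid.

`classify_residue()` buckets couplings using thresholds that default to the
**dataset-derived** cluster boundaries (coil ≤ 6.30 Hz, extended/helical
sampling ≥ 6.65 Hz); they are not universal secondary-structure cutoffs and
are fully configurable. `j_rmsd()` is the root-mean-square difference over
shared residues — a metric (symmetry, zero iff equal, triangle inequality are
tested).

`temp_coeff()` is an ordinary least-squares slope of shift vs temperature
converted to ppb/K, reported as a positive magnitude per the field's
convention (the raw ppm/K slope is negative — upfield drift with warming —
and is retained signed in `slope_signed_ppb_per_K`). Temperatures may be
given in °C or K with explicit declaration; the degree size is identical so
slopes are always per Kelvin. A linearity flag is set at $r^2 \ge 0.99$.

## 6. Synthetic data: what it emulates and what it does not

Every input the pipeline consumes can be generated (`gen_fw_trace`,
`gen_raw_integrals`, `gen_titration`, `gen_vt`, `gen_jset`). The generators
are the forward models above plus i.i.d. Gaussian noise from an explicitly
seeded private stream (the global RNG state is saved and restored), making
every dataset bit-reproducible from its `noise_spec`. Default noise levels
mimic the quality of the experimental data the package was built around:
0.02–0.05 mM on concentration points, 0.002 ppm on chemical shifts, 0.1 Hz on
couplings. Out-of-range noisy values are clipped (to $[0, A_0]$ or
$[0, 12]$ Hz) with a recorded count, not rejected. `gen_raw_integrals` keeps
the $t = 0$ integrals noise-free so that $t = 0$ self-normalization remains
well defined.

What a green round-trip test establishes: the analyzers invert their own
forward models at the stated noise levels. What it does not establish: the
models themselves describe real spectra. Real aggregation traces carry
baseline drift, correlated integration errors and occasional missing points;
real titrations can show slow-exchange broadening and overlapping peaks; real
couplings are ensemble averages over a $\varphi$ distribution, not a single
angle. None of these is simulated.

## 7. Numerical choices and degenerate inputs

* Jerk symmetry is asserted at $10^{-14}$ h (1 ulp separates the two
  half-widths in floating point).
* The ODE oracle in the test suite is an adaptive Cash–Karp RK45 with
  tolerances $10^{-10}$, independent of the closed form.
* `fit_fw` on a flat (no-loss) trace returns a `poor`-quality result with a
  diagnostic, never an error; a constant cannot be represented with positive
  rate constants and a finite inflection inside the window.
* Ties in `neighbor_asymmetry` are exceptions (strict rule).
* `karplus_invert` deduplicates roots to $10^{-10}$ degrees; tangency
  therefore returns fewer than four solutions.
* Labels parse in both dialects ("S9" and "9S"); emission is always
  letter-then-number.

## 8. Known limitations

* No secondary-nucleation or fragmentation kinetics (moment-equation
  models); the two-step scheme cannot describe fibril-size distributions.
* No global multi-residue binding model; per-residue $K_a$'s are treated as
  independent observations.
* The Karplus inversion reports point solutions, not ensemble
  $\varphi$-distributions; for disordered peptides the measured $J$ is a
  population average and the "classification" is a coarse proxy.
* Temperature coefficients assume strict linearity over the fitted window;
  curvature is only surfaced through the $r^2$ flag.
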