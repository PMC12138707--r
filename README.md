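# synkin

Quantitative analysis of weak anion binding to short cationic peptides and of
the aggregation it induces, from solution-NMR observables. The package was
built around studies of the 15-mer N-terminal peptide of α-synuclein
(MDVFM**X**GLS**X**A**X**EGV, X = K/R/H at positions 6, 10, 12) titrated and
aggregated with Hofmeister-series sodium salts, but every stage takes plain
CSV inputs and is reusable for similar peptide/salt systems.

It is for NMR spectroscopists and biophysicists who have already reduced
their spectra to numbers — integral time-courses, per-residue shift tables,
titration series, ³J couplings — and need the downstream model fitting,
phase-time extraction and mapping done reproducibly.

## What it computes

**Aggregation kinetics.** The Finke–Watzky two-step model — slow nucleation
A → B (k₁) plus autocatalytic growth A + B → 2B (k₂) — has the closed-form
monomer solution

    [A](t) = K / (1 + exp(r (t − t_max))),   K = A₀ + k₁/k₂,  r = k₁ + k₂A₀,
    t_max = ln(k₂A₀/k₁) / r

The induction time t₁ and plateau-onset time t₂ are the zeros of the jerk
(third derivative) of the product curve, analytically
t₁,₂ = t_max ∓ ln(2+√3)/r, hence t_max = (t₁+t₂)/2 exactly. `fit_fw()`
recovers (k₁, k₂) from a monomer-loss trace; `fw_jerk_times()` /
`fw_jerk_times_numeric()` give the phase times by two independent routes.

**Binding.** Per-residue association constants from fast-exchange titrations
via the 1:1 excess-ligand isotherm
δ_obs = δ_free + δ_max·K_a c/(1+K_a c) (`fit_ka()`); chemical-shift
perturbation maps Δδ = δ(bound) − δ(free) with bubble-map export and the
N–H_i vs N–H_{i+1} neighbor-asymmetry rule (`csp()`, `neighbor_asymmetry()`).

**Structure metrics.** Karplus ³J(HN–Hα) ↔ φ analysis
(`karplus_j()`, `karplus_invert()`), coil/extended classification, RMSD
between J-sets, and variable-temperature amide coefficients in ppb/K
(`temp_coeff()`).

**Synthetic data.** `gen_fw_trace()`, `gen_titration()`, `gen_vt()`,
`gen_jset()`, `gen_raw_integrals()` generate every input from the forward
models with seeded Gaussian noise, so the full pipeline is testable without
spectrometer time.

## Worked example

Simulate one aggregation condition (the 120 mM perchlorate parameters,
k₁ = 0.03 h⁻¹, k₂ = 0.13 mM⁻¹h⁻¹, A₀ = 2 mM) with realistic noise and refit:

```r
library(synkin)

p <- fw_params(k1 = 0.03, k2 = 0.13, A0 = 2)
trace <- gen_fw_trace(p, seq(0, 24, by = 0.5),
                      noise_spec(sigma = 0.04, seed = 42),
                      metadata = list(peptide = "2", salt = "NaClO4",
                                      salt_mM = 120, pH = 5.2))
fit <- fit_fw(trace, A0 = 2)
print(fit)
#> F-W fit (good): k1 = 0.028047 h^-1, k2 = 0.13706 mM^-1 h^-1, A0 = 2 mM
#>   t1 = 3.186 h, tmax = 7.545 h, t2 = 11.903 h; max rate 0.1665 mM/h
#>   r^2 = 0.99621, RMS residual = 0.04277 mM
```

The fitted rate constants land within the noise of the generating values; the
jerk-based phase times bracket the exponential-growth window, and
tmax = (t1+t2)/2 holds by construction. A titration and a VT series:

```r
titr <- gen_titration(Ka = 6, delta_free = 8.30, delta_max = -0.15,
                      concs = seq(0, 0.5, length.out = 12),
                      noise = noise_spec(0.002, seed = 7), residue = "K12")
print(fit_ka(titr))
#> binding fit [K12]: Ka = 8.022 M^-1 (se 0.49), delta_free = 8.3044 ppm, delta_max = -0.1417 ppm, r^2 = 0.99816

vt <- gen_vt(4.69, 8.3, seq(5, 35, by = 5),
             noise_spec(0.001, seed = 3), residue = "G7")
print(temp_coeff(vt))
#> temperature coefficient [G7]: 4.663 ppb/K (signed -4.663), r^2 = 0.99990
```

Note the K_a estimate: with K_a ≈ 6 M⁻¹ the titration only reaches
K_a·c ≈ 3, so 0.002 ppm of shift noise moves the estimate by ~30% — weak
binding constants are intrinsically noise-sensitive, which is why `fit_ka()`
flags series that do not approach saturation. Noise-free series are recovered
to < 0.01% (see the acceptance tests).

A full study (kinetics + binding + CSP + couplings + VT) can be driven from a
JSON config with `run_study()`, or from the command line:

```sh
inst/exec/synkin fw-eval --k1 0.03 --k2 0.13 --a0 2
inst/exec/synkin simulate fw --k1 0.03 --k2 0.13 --a0 2 --sigma 0.04 --seed 1 --out trace.csv
inst/exec/synkin fw-fit trace.csv --a0 2
```

## Further reading

`vignettes/methods.Rmd` documents the models and assumptions, all tunable
parameters with units and defaults, what the synthetic-data generators do and
do not emulate, numerical choices, and known limitations.
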