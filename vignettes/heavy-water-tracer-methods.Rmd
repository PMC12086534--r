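---
title: "Measuring lipid and bile acid synthesis with heavy water: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lipid and bile acid synthesis with heavy water: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(d2otrace)
```

## The measurement

When an animal drinks deuterated water, its body water equilibrates at a
²H mol-fraction excess *p* (here targeted at ~4%). Every molecule the liver
synthesizes during the labeling window picks up deuterium at its
*exchangeable* hydrogen positions — the *n* positions that equilibrate with
cellular water during biosynthesis. A molecule made before labeling carries
none. Mass spectrometry of the analyte ion therefore sees a mixture:

* an *old* fraction `1 - f` at the natural isotopologue distribution, and
* a *new* fraction `f` whose exchange positions carry extra deuterium,
  binomially distributed: the number of label atoms is `Binom(n, p)`.

The acquisition monitors the first four isotopologues m0–m3. After
correcting the observed distribution for naturally abundant heavy isotopes
(¹³C, ²H, ¹⁸O, ³⁴S, ...), the analyte deuterium enrichment is the
label-weighted sum

```
enrichment = m1 + 2·m2 + 3·m3          (label atoms per molecule)
```

and fractional synthesis is

```
f (%) = enrichment / (p × n) × 100.
```

The default panel covers the five taurine-conjugated bile acids monitored by
LC-MS/MS (common product ion m/z 80 from the taurine sulfonate; precursors
m/z 514.2 for the trihydroxy species and 498.2 for the dihydroxy species,
ion formulas C26H44NO7S⁻ and C26H44NO6S⁻), the palmitate carboxylate ion
C16H31O2⁻ (de novo lipogenesis) and the m/z 247 cholesterol fragment C18H31⁺
(cholesterol synthesis), with exchangeable-hydrogen assignments
n = 14 (T-CA, T-αMCA), 10 (T-βMCA, T-DCA), 18 (T-CDCA), 22 (palmitate) and
20 (cholesterol fragment).

## Natural-abundance mathematics

`natural_mid()` builds the natural isotopologue distribution of an ion by
repeated truncated convolution of per-atom isotope patterns, from a single
shipped abundance table (IUPAC representative values for C, H, N, O, S).
Truncation is exact bookkeeping: mass beyond mK is accumulated in
`truncated_mass`, never dropped, and convolution preserves the invariant
`sum(values) + truncated_mass = 1` because truncated mass can only stay
beyond the cutoff when further shifts are added.

`build_correction_matrix()` turns a natural MID into the lower-triangular
operator whose column *j* is the natural distribution shifted down *j* rows;
applying it convolves a label-only distribution with the natural one, and
solving against it removes the natural contribution. Two provenances are
supported:

* **empirical** (pipeline default when unlabeled baseline samples exist):
  the natural MID is the average of the normalized baseline spectra,
  averaging before matrix construction to damp baseline noise;
* **theoretical**: computed from the ion's elemental formula.

On clean data the two agree (tested); on noisy data they differ in failure
mode — the empirical matrix absorbs instrument-specific effects but injects
the baseline's own noise as a *shared systematic* error into every corrected
spectrum, which matters for the small m2/m3 channels (see the
n-estimation section).

`correct_mid()` solves the triangular system by non-negative least squares
(default), because measurement noise otherwise produces negative
isotopologue fractions; plain triangular back-substitution is available as
`method = "solve"`. Solver residuals are recorded on every result row, and a
residual above `tol` (default 1e-8) flags the row rather than silently
passing.

## The forward model and the truncation decision

`forward_observed_mid()` generates the observed (pre-noise) distribution.
Its default convention treats label as an *excess* convolved onto the full
natural distribution:

```
observed = (1 - f) · N  +  f · (N ⊛ Binom(n, p))
```

This is the exact generative counterpart of baseline-matrix correction:
correcting such a spectrum with N returns `(1 - f)δ₀ + f·Binom(n, p)`
to machine precision, which the test suite verifies. The alternative
`exchange = "replace"` convention removes the n exchangeable hydrogens from
the natural backbone and re-draws them as Bernoulli(p + natural ²H
abundance); it is exact at the atom level but is *not* exactly inverted by
baseline correction. The two differ by ~0.03% relative at p = 4%, far below
instrument noise; the excess convention is the default because it keeps the
correction algebra closed.

Monitoring stops at m3, but a `Binom(22, 0.04)` molecule has ~1.4% of its
mass beyond m3, and at p = 5% the plain estimator's truncation loss reaches
~8% relative for n = 22. Since n and p are already required inputs of the
fractional-synthesis equation, the truncation is exactly invertible at no
cost: a corrected, renormalized K = 3 MID has measured enrichment
`E = f·E_b / (1 - f·t)` with `E_b` the truncated binomial partial mean and
`t` its tail mass, so

```
f = E / (E_b + E·t).
```

The pipeline therefore defaults to `truncation = "correct"`, which is exact
in the noiseless case and converges to the plain ratio as K grows;
`truncation = "none"` reproduces the plain enrichment/(p·n) estimator
verbatim, and `truncation_bias()` reports the tail mass and small-f relative
bias per analyte so the K = 3 assumption can be judged. The acceptance suite
checks both: the default estimator recovers f across the grid
f ∈ {2,...,60}%, p ∈ {2,4,5}%, n ∈ {10,...,22}, and the plain estimator's
bias is verified to be pure truncation loss that vanishes by K = 8.

## Estimating n

`estimate_n()` fits, for every candidate n on an integer grid (default
1..40), the renormalized mixture `((1-f)δ₀ + f·b_n) / (1 - f·t_n)` to each
corrected MID by least squares over f, and returns the candidate with the
smallest pooled residual, with ties broken toward the smaller n and
reported. The closed-form diagnostic `n̂ = 1 + 2·(m2/m1)·(1-p)/p` (exact for
a binomial, and invariant to f in the mixture) is reported alongside. On
noiseless data the recovery is exact, with zero residual only at the true
candidate.

Two practical lessons from the simulations shaped the pooled protocol in
`run_estimate_n()`:

* **Pool raw spectra before correcting.** Fitting each noisy MID separately
  and summing residuals has an incidental-parameter/censoring bias (each
  sample brings its own nuisance f, and the non-negative solve clips noise
  asymmetrically) that does not shrink with more samples. Averaging the
  normalized raw spectra first lets noise cancel before the constraint can
  censor it; the pooled estimator is then unbiased (measured |mean bias|
  < 0.1 across n ∈ {10, 14, 18, 22} at 5% CV).
* **Integer-exact n needs strong labeling and low noise.** The spacing
  between neighboring candidates in the m2/m1 ratio is `2/(n-1)` relative,
  while the pooled noise on the corrected m2 channel at 5% area CV with 8
  samples is several percent: the estimate is unbiased but has sd ≈ 1–2.
  The property tests therefore assert unbiasedness and ±2 coverage at those
  conditions, and exactness on noiseless data; n assignments should come
  from dedicated strong-labeling determinations, not survey spectra. For
  n-determination the theoretical correction matrix is preferable: a small
  empirical baseline set contributes a shared systematic error to the small
  channels that the binomial fit amplifies.

## Calibrations

Body-water enrichment is measured by deuterium exchange into acetone against
gravimetric standards of known ²H mol-fraction excess. `water_enrichment()`
fits the standards' signal-ratio line by OLS and inverts it at each sample's
ratio; samples outside the standards' range are flagged. The acceptance
suite verifies bias < 0.05 percentage points across p ∈ [1, 6]% at 0.5%
relative ratio noise (500 replicates per level). The raw observable is
modeled as a signal ratio linear in p; because standards and samples share
the same reduction, the calibration inversion is insensitive to the exact
reduction formula.

Analyte concentrations use internal-standard calibration: response =
analyte area / IS area, and `fit_calibration()` reports slope, intercept and
r as assay practice requires, rejecting flat or inverted responses.
Blank-level responses below the intercept floor at 0 with a flag rather than
erroring, because blank-level biology is real. `total_content()` implements
the compartment normalization (concentration × compartment mass / body
mass) used for intestinal and fecal totals. `new_pool_amount()` converts
fractional synthesis and pool concentration into the absolute newly
synthesized amount, the quantity that distinguishes a shrunken-pool knockout
(similar f, much less new material) from a synthesis change.

## The synthetic cohort generator

`simulate_study()` is first-class, tested code that emulates the study's
statistical structure so every pipeline stage is testable without any
download: per-animal p ~ Normal(0.04, 0.002) truncated to (0,1); per-animal
true f logit-normal around the group mean (sd 0.10 on the logit scale,
≈10% CV); pool concentrations lognormal (25% CV around panel means chosen to
match realistic liver bile acid concentrations); observed MIDs from the
forward model; areas scaled through per-analyte internal-standard
calibration lines; and multiplicative lognormal noise (default 5% CV) on
every peak area, the mean-one parameterization so noise adds no bias by
construction. Unlabeled baseline animals (default 3), acetone standards at
{0, 1, 2, 4, 6}% with 0.5% relative noise, and a ground-truth table complete
the study. Determinism is a contract: same config and seed give identical
output (default seed 20250407).

Three presets mirror the supported designs: `"hcr_lcr_1wk"` (strain × diet ×
feeding status, 8 groups of 8, full 7-analyte panel), `"vwr_mice"`
(sedentary vs wheel-running, 8 per group) and `"lcyp7a1ko"` (4 groups in
both sexes, 6–8 per group, bile acid pools shrunk ×0.3 in the knockout arms
so the fraction-new stays similar while absolute new amounts collapse).
Preset effect sizes are synthetic defaults chosen to be qualitatively
plausible (high-capacity and exercised arms synthesize more); they are not
measured values.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: chromatographic interference and integration error
(noise is independent per channel; real isotopologue areas share peak-shape
error), drift and batch effects, isobaric contamination of the bile acid
channels, p declining over the labeling window (a single equilibrium p is
assumed), and multi-pool turnover kinetics (the single-timepoint,
single-ratio estimator is the scope; rise-to-plateau kinetics are a
non-goal).

## Numerical choices and problem sizes

* K defaults to 3 (the acquisition); truncated mass is tracked, never
  dropped; a forward truncated mass above 0.05 flags "severe_truncation".
* NNLS via `pracma::lsqnonneg`; residual tolerance 1e-8, reported per row.
* `estimate_n` inner fits use `optimize` on f ∈ [0, 1] at tolerance 1e-12;
  residual ties within 1e-9 relative are reported, smallest n returned.
* Natural ²H at exchange positions stays in the natural distribution at its
  natural abundance (~1.15e-4); the label binomial uses excess p.
* f values above 100% are flagged, never clipped in stored results.
* p is taken per animal when its own water measurement exists, else the
  cohort mean; the choice is recorded per row.
* Test and acceptance problem sizes: property loops use 20–60 replicates;
  the noisy-recovery check runs 100 replicate two-group studies of 16
  animals; the water-calibration check runs 500 replicates per enrichment
  level. The full suite runs in well under a minute of compute per file.

## Known limitations

The estimator assumes a single, known, constant p per animal and a binomial
label distribution with a fixed integer n — adequate for overnight labeling
at tracer levels, but n itself is an effective parameter (positional
exchange probabilities are not all equal in reality). The m0–m3 window
limits identifiability of large n from noisy data, as quantified above.
Concentration accuracy inherits whatever the internal-standard curve's
linear range covers; the pipeline flags but does not model nonlinearity.
Group statistics are deliberately out of scope: the tidy per-sample output
is designed to feed external statistical tools.
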