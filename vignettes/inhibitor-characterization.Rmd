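---
title: "Characterizing a reversible enzyme inhibitor: models, fits and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a reversible enzyme inhibitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchkin)
```

## Scope

`quenchkin` implements the standard biophysical workflow for characterizing
a small-molecule inhibitor of an enzyme — the motivating system is a
flavonoid acting on acetylcholinesterase (AChE), assayed by the Ellman
thiocholine/DTNB method — from five kinds of bench data:

1. absorbance progress curves (initial rates),
2. dose–response tables (IC50),
3. initial-rate grids over substrate × inhibitor (mechanism, Km, Ki),
4. activity time courses (first-order inactivation, transition free
   energies),
5. fluorescence titrations, emission and synchronous (quenching mechanism,
   binding constant and stoichiometry, Van't Hoff thermodynamics, residue
   microenvironment probes).

Because raw instrument traces for such studies are rarely deposited, the
package ships a seeded generator (`gen_*` functions) that produces data
with exactly the statistical structure each fit assumes. Every fitting
routine is therefore testable by parameter recovery, and the test suite and
acceptance script rely on that rather than on any external dataset.

## Models

### Initial rates and IC50

`initial_rate()` is an ordinary least-squares slope of A412 against time
over a user-chosen window (the Ellman product, thionitrobenzoate, is read
at 412 nm; the default extinction coefficient 13,600 M⁻¹ cm⁻¹ with a 1 cm
path converts to molar rates and both are configurable). Points recorded
after the window are compared against the fitted line: a strong monotone
residual trend flags substrate-depletion curvature, signalling that the
window matters.

`fit_ic50()` fits the two-parameter log-logistic
$$a(I) = \frac{100}{1 + (I/\mathrm{IC}_{50})^h}$$
with asymptotes fixed at 100 % and 0 %. Fixing the asymptotes is a
deliberate choice: relative activity is normalized to the uninhibited
control by construction, and freeing the top/bottom on 10–12 point curves
mostly trades bias for variance. The fit refuses inputs that never cross
50 % activity or in which activity *rises* with dose. A related helper,
`hill_from_endpoints()`, solves for the Hill exponent implied by an
(IC50, single high-dose inhibition) pair — useful because published
summaries often quote exactly those two numbers, and they are frequently
inconsistent with $h = 1$ (an IC50 of 6.42 µM with 90 % inhibition at
26.7 µM implies $h \approx 1.54$, and the generator exposes $h$ rather
than guessing).

### Inhibition mechanism, Km and Ki

`fit_inhibition()` runs the classical double-reciprocal (Lineweaver–Burk)
analysis: per inhibitor level $1/v$ is regressed on $1/S$,
$$\frac{1}{v} = \frac{K_m}{v_{max}}\Big(1 + \frac{I}{K_i}\Big)\frac{1}{S}
  + \frac{1}{v_{max}},$$
giving apparent constants $K_m^{app} = \mathrm{slope}/\mathrm{intercept}$
and $v_{max}^{app} = 1/\mathrm{intercept}$. The mechanism is read off the
pattern of the lines (`classify_inhibition_type()`): a common 1/v-axis
intercept with growing slope is competitive; parallel lines are
uncompetitive; a fixed $K_m^{app}$ with a falling $v_{max}^{app}$ is
noncompetitive; anything else is mixed. "Constant" is judged against twice
the pooled standard error of the line parameters, floored at a $10^{-8}$
relative epsilon so that noise-free inputs, whose standard errors are at
machine precision, still classify.

For a competitive pattern the secondary plot
$K_m^{app} = (K_m/K_i)\,I + K_m$ (`ki_secondary_plot()`) returns $K_m$ as
its intercept and $K_i = \mathrm{intercept}/\mathrm{slope}$.

The reciprocal transform distorts the noise distribution, so a global
nonlinear fit of the competitive law
$v = v_{max} S / (K_m(1 + I/K_i) + S)$ is computed alongside and reported
in the same object. The reciprocal-space estimates are kept as the
primary, "plot-compatible" values — they are what the field's secondary
plots produce — while the nonlinear estimates serve as a cross-check whose
divergence grows with noise (this is asserted in the test suite at two
noise levels). Reciprocal fits are unweighted, matching classical
practice; no $1/v^4$ weighting is applied.

Units are never converted implicitly: Km is reported in whatever units the
substrate column carries and Ki in the inhibitor's units. This matters
because published kinetic tables sometimes mix millimolar substrate grids
with micromolar inhibitor constants and print Km without a unit; the
report surfaces the units it was given and nothing else.

`reversibility_test()` regresses rate on total enzyme concentration per
inhibitor level: lines through the origin whose slope falls with inhibitor
indicate reversible (non-covalent, dilutable) inhibition, while a shared
positive abscissa intercept is the signature of irreversible titration of
active sites. The origin test uses the 95 % confidence interval of each
intercept; the literature states no numeric criterion, so a standard one
was chosen.

### Inactivation kinetics

`fit_first_order()` fits
$$A(t) = A_\infty + (100 - A_\infty)\,e^{-kt},$$
with the plateau $A_\infty$ *fitted*, not assumed zero, because partial
inactivation routinely levels off above zero. Numerically the plateau is
profiled out (for fixed $k$ the model is linear in $A_\infty$), reducing
the problem to a bracketed one-dimensional search in $k$ followed by a
root find on the profiled gradient; this converges to ~1e-12 relative
even when $A_\infty$ sits on its boundary, where a joint two-parameter
descent can stall. The traditional semilogarithmic slope of
$\ln(A - A_\infty)$ is reported as a cross-check.

`phase_test()` decides monophasic versus biphasic decay by fitting a
double exponential (multi-start bounded Levenberg–Marquardt) and applying
an extra-sum-of-squares F-test at $\alpha = 0.05$; two phases are only
accepted when the recovered constants also differ by at least 3-fold,
since a "significant" second exponential with nearly equal constants is a
reparameterization, not a second phase.

`transition_free_energy()` computes $\Delta\Delta G^\circ = -RT\ln k$ in
kJ mol⁻¹ ($R = 8.314$ J mol⁻¹ K⁻¹). The reporting temperature defaults to
298 K: the conventional published values for this quantity back-calculate
with 298 K rather than 298.15 K, and both conventions are available
through the `T_K` argument. (The occasional literature unit
"kJ mol⁻¹ s⁻¹" for this quantity is a typographical artifact; the formula
yields kJ mol⁻¹ and that is what the package reports.)

### Fluorescence quenching and binding

`inner_filter_correct()` applies the standard re-absorption correction
$F_{corr} = F_{obs} \cdot 10^{(A_{ex}+A_{em})/2}$ per titration point and
zeroes the stored absorbances afterwards so the correction cannot be
applied twice. `peak_metrics()` finds each spectrum's maximum with
parabolic interpolation through the three bracketing grid points, which
resolves sub-nanometre peak positions on the 1 nm grids typical of
scanning fluorometers.

`stern_volmer_fit()` fits $F_0/F = 1 + K_{SV}[Q]$ with the intercept fixed
at 1 — that is the functional form of the Stern–Volmer law — and reports a
free-intercept diagnostic line alongside. The bimolecular constant is
$K_q = K_{SV}/\tau_0$ with $\tau_0 = 10^{-8}$ s by default, the standard
fluorescence lifetime scale of biopolymers; $\tau_0$ is a configuration
knob, and the downstream mechanism classification deliberately depends
only on the $2.0\times10^{10}$ L mol⁻¹ s⁻¹ collisional ceiling, not on
the exact lifetime. `classify_quenching()` calls the mechanism static
only when $K_{SV}$ strictly decreases with temperature *and* $K_q$
exceeds the ceiling at every temperature, dynamic only on the opposite
pattern, and otherwise reports indeterminate with both criteria spelled
out.

`double_log_fit()` estimates the association constant $K_a$ and site
number $n$ from
$$\log\frac{F_0-F}{F} = n\log K_a + n\log\Big([Q_t] -
  \frac{(F_0-F)[P_t]}{F_0}\Big),$$
where the bracketed term is the free-quencher concentration implied by the
measured quench fraction (each quenched fluorophore has bound one ligand
in a 1:1 static model). The fit requires $0 < F < F_0$ at every non-zero
point and rejects titrations whose implied free-quencher concentration
goes non-positive, which indicates an inconsistent $P_t$. $n$ is fitted
freely at each temperature. All logarithms here and in the Van't Hoff
step are base-10, matching the 2.303 factors of the classical equations.

`vant_hoff()` regresses $\log K_a$ on $1/T$:
$$\log K_a = -\frac{\Delta H^\circ}{2.303\,R\,T} +
  \frac{\Delta S^\circ}{2.303\,R},$$
then $\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ$. Two entropy
estimates are reported deliberately: the regression intercept, and the
Gibbs-route value $(\Delta H^\circ - \Delta G^\circ_{direct})/T$ with
$\Delta G^\circ_{direct} = -RT\ln K_a$. The intercept is an extrapolation
to $1/T = 0$ and is extremely sensitive to rounding in the input $K_a$
values, so the two estimates can disagree substantially on published
three-significant-figure tables; the package emits both rather than
silently choosing. `classify_forces()` maps the signs of
$(\Delta H^\circ, \Delta S^\circ)$ to the dominant noncovalent
interactions by the classical rules (negative/positive → hydrogen bonds +
hydrophobic; negative/negative → van der Waals + hydrogen bonds;
positive/positive → hydrophobic; positive/negative → electrostatic), with
a configurable dead band around zero.

### Synchronous fluorescence

Scans at a fixed excitation–emission offset $\Delta\lambda$ of 15 nm
report tyrosine and of 60 nm tryptophan microenvironments.
`sync_metrics()` tracks the peak trajectory (sub-grid positions via the
same parabolic interpolation — published shifts of 1–2 nm are at or below
typical grid spacing, so interpolation is not optional), reports the total
signed shift (positive = bathochromic, read as increased
microenvironment hydrophobicity), and the quenching ratio
$\mathrm{RSFQ} = 1 - F/F_0$ per point. RSFQ uses peak heights, matching
how $F/F_0$ is read off spectra in practice; an area-based variant is
available behind `use_area = TRUE`. `analyze_sync()` compares the two
channels and names the residue class with the larger final RSFQ as the
dominant contributor.

## The synthetic generator: what it emulates, what it does not

Each generator produces data from the exact model its analysis stage
assumes, plus configurable noise (`synth_config`): none, additive
Gaussian (σ as a fraction of the mean signal), or multiplicative Gaussian
(point-wise $1 + N(0,\sigma)$). One master seed expands into fixed-offset
child seeds per stage, so a full fixture family is reproducible
byte-for-byte from a single integer.

Defaults mirror the motivating study's conditions: substrate grids
spanning 0.3–10× Km with four inhibitor levels including zero (0, 4, 8,
10 µM); inactivation sampled every 3 min to 30 min, every 6 min to
60 min, then at 70 and 80 min, with rate constants of order 10⁻⁴ s⁻¹;
protein at 0.17 µM titrated with quencher 0–16 µM; emission spectra on a
1 nm grid over 290–450 nm peaking at 343 nm; synchronous windows sized to
the peak ± 4 band widths. The quench generator solves the 1:1 mass-action
quadratic for the bound complex (the numerically stable root), and can
alternatively produce ideal linear Stern–Volmer data — the $P_t \to 0$
limit of the same model. Noise at 1 % multiplicative is used for the
stochastic recovery checks, with 100 seeded replicates per check; these
sizes keep the whole suite under half a minute on one CPU while leaving
the medians' Monte-Carlo error an order of magnitude below the acceptance
tolerances.

What the generator does **not** emulate: photobleaching and drift,
wavelength-dependent instrument response, correlated (non-Gaussian)
noise, substrate depletion inside the initial-rate window (a two-phase
curve helper exists in the tests, but the generator's progress curves are
linear by design), cooperative or multi-site binding, and any structural
observables (circular dichroism, docking poses, molecular-dynamics
trajectories are out of scope entirely). Passing parameter-recovery tests
therefore demonstrates correctness of the estimators under the stated
statistical model, not robustness to every instrumental pathology of real
spectra.

## Numerical choices and degenerate inputs

- Linear fits are `stats::lm`; nonlinear fits use `minpack.lm`
  (Levenberg–Marquardt with bounds). The single-exponential inactivation
  fit uses variable projection + Brent + a gradient root-polish instead,
  as described above, because the acceptance bar there is machine-level
  recovery with a boundary-constrained plateau.
- The binding quadratic is solved as $2c/(b + \sqrt{b^2-4ac})$ to avoid
  cancellation, and clamped to the stoichiometric bound
  $\min(P_t, Q_t)$ against round-off.
- Zero rates in a rate table make $1/v$ undefined; such rows are dropped
  with a warning and the fit errors if fewer than four substrate levels
  remain at any inhibitor level.
- Flat spectra and peaks at the grid edge are hard errors in
  `peak_metrics()` (no peak, or an uncomputable interpolation) rather
  than silent extrapolations.
- Classification tolerances (2× pooled SE with a relative floor) are the
  only tie-break heuristics in the package; everything else is a direct
  least-squares estimate. The rule is deliberately conservative: with
  noisy replicates the per-line intercepts scatter beyond twice their
  pooled standard error quite easily, and the classifier then prefers
  "mixed" over forcing a pure mechanism. When that happens, inspect the
  per-line table in `fit$lines` (and the secondary-plot $R^2$) before
  accepting the label; the Km/Ki point estimates do not depend on the
  label.
- `vant_hoff()` accepts two temperatures but warns: the line then has no
  residual degrees of freedom and $R^2$ is reported as 1 by convention.

## Pipeline and interchange formats

All stages read and write headered CSV (`#`-prefixed `key=value`
provenance lines above the column header; synthetic files embed their
generating truths there). Spectra use a wide layout — `wavelength_nm`
first, one column per titration point named by the quencher concentration
in µM — with scalar metadata ($P_t$, temperature, $\Delta\lambda$,
per-point absorbances) in a JSON sidecar. `run_pipeline()` executes the
configured stages in dependency order and returns a report bundle;
`write_report()` emits lossless JSON plus a human-readable summary whose
layout mirrors the rate-constant and thermodynamics tables of a typical
inhibition study. `make_fixtures()` writes the complete synthetic dataset
family from one master seed. This package is a library first: the
pipeline functions and the `scripts/acceptance.R` entry point are the
supported ways to run it end to end.

## Worked example

```{r example}
set.seed(NULL)
dir <- tempfile("fixtures")
paths <- make_fixtures(dir, master_seed = 42)
cfg <- pipeline_config(rate_table = paths$rate_table,
                       dose_response = paths$dose_response,
                       timecourse = paths$timecourse,
                       spectra = paths$spectra,
                       sync15 = paths$sync15, sync60 = paths$sync60)
report <- run_pipeline(cfg)
report
```

## Known limitations

- Tight-binding (Morrison) and slow-binding inhibition, multi-site and
  cooperative binding, FRET distances and site-marker displacement are
  not modelled.
- The Stern–Volmer fit assumes a single quenching population; strongly
  curved plots are flagged, not decomposed.
- The Van't Hoff analysis assumes temperature-independent
  $\Delta H^\circ$ over the (narrow) measured range.
- The dose–response model fixes the asymptotes at 100 %/0 %; compounds
  with partial maximal inhibition need a different model.
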