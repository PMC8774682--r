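# quenchkin

Enzyme-inhibition kinetics and fluorescence-quenching binding analysis in R.

`quenchkin` is for bench scientists characterizing a reversible
small-molecule inhibitor of an enzyme — the motivating system is a
flavonoid inhibitor of acetylcholinesterase assayed by the Ellman
(thiocholine/DTNB, A412) method — who want the full classical analysis
chain as tested, scriptable functions instead of spreadsheet fits:

- **Activity & potency** — initial rates from absorbance progress curves
  (`initial_rate`), relative activity, and IC50 by log-logistic regression
  (`fit_ic50`).
- **Mechanism** — reversibility from rate-vs-enzyme lines
  (`reversibility_test`); Lineweaver–Burk analysis with mechanism
  classification and a global nonlinear cross-fit (`fit_inhibition`,
  `classify_inhibition_type`); Km and Ki from the secondary plot
  `Km_app = (Km/Ki)·I + Km` (`ki_secondary_plot`).
- **Inactivation** — monophasic first-order fits
  `A(t) = A∞ + (100−A∞)·e^(−kt)` with a fitted plateau
  (`fit_first_order`), mono/biphasic decision by extra-sum-of-squares
  F-test (`phase_test`), and transition free energies ΔΔG° = −RT ln k
  (`transition_free_energy`).
- **Binding** — inner-filter correction `F·10^((Aex+Aem)/2)`,
  Stern–Volmer fits `F0/F = 1 + KSV[Q]` with static/dynamic
  classification against the 2×10¹⁰ L mol⁻¹ s⁻¹ collisional ceiling,
  the double-logarithmic fit
  `log((F0−F)/F) = n·log Ka + n·log [Q]free` for Ka and n, Van't Hoff
  thermodynamics (ΔH°, ΔS°, ΔG° = ΔH° − TΔS°) and sign-rule force typing
  (`classify_forces`).
- **Conformation probes** — synchronous-fluorescence peak shifts
  (Δλ = 15 nm → Tyr, 60 nm → Trp) and quenching ratios RSFQ = 1 − F/F0
  (`sync_metrics`, `analyze_sync`).
- **Synthetic data** — seeded generators (`gen_rate_table`,
  `gen_dose_response`, `gen_inactivation_timecourse`,
  `gen_quench_titration`, `gen_synchronous`, …) that produce data with
  exactly the statistical structure each fit assumes, so every estimator
  is validated by parameter recovery; `make_fixtures` writes a complete
  CSV dataset family from one master seed.

See the vignette (`vignettes/inhibitor-characterization.Rmd`) for the
models, assumptions and design decisions.

## Worked example

Generate a noise-free synthetic dataset family and run every stage:

```r
library(quenchkin)

dir <- tempfile("fixtures")
paths <- make_fixtures(dir, master_seed = 42)   # headered CSVs + sidecars

cfg <- pipeline_config(rate_table    = paths$rate_table,
                       dose_response = paths$dose_response,
                       timecourse    = paths$timecourse,
                       spectra       = paths$spectra,
                       sync15 = paths$sync15, sync60 = paths$sync60)
report <- run_pipeline(cfg)
report
```

```
== Inhibitor characterization report ==

IC50: 6.42 (Hill 1.54)
Inhibition type: competitive
Km = 1.674, Vmax = 1, Ki = 4.32
(Km/Ki in the units of the input concentration columns)

Inactivation kinetics:
  [I]    k (s^-1)      ddG (kJ/mol)  phase
  2      0.000148      21.85         monophasic
  4      0.000242      20.63         monophasic
  8      0.000401      19.38         monophasic
  16     0.000518      18.74         monophasic

Fluorescence quenching:
  T (K)    KSV (L/mol)   Kq (L/mol/s)  R^2
  298.15   6.619e+04     6.62e+12      1.0000
  304.15   5.783e+04     5.78e+12      1.0000
  310.15   5.08e+04      5.08e+12      1.0000
  quenching mode: static

Binding (double-log fit):
  T (K)    Ka (L/mol)    n       R^2
  298.15   6.66e+04      1       1.0000
  304.15   5.817e+04     1       1.0000
  310.15   5.107e+04     1       1.0000

Thermodynamics (van't Hoff):
  dH = -17.01 kJ/mol, dS = 35.3 J/mol/K (intercept)
  dG(T): -27.54, -27.75, -27.96 kJ/mol
  dominant forces: hydrogen bonds + hydrophobic interactions

Synchronous fluorescence:
  Tyr (d15): shift +1.00 nm, final RSFQ 58.48%
  Trp (d60): shift +2.00 nm, final RSFQ 63.83%
  dominant residue: Trp
```

Reading the output: the inhibitor is competitive (double-reciprocal lines
meet on the 1/v axis), with Michaelis constant 1.674 (substrate units) and
inhibition constant 4.32 µM recovered exactly from the noise-free table;
inactivation is monophasic with rate constants of a few 10⁻⁴ s⁻¹, i.e.
free-energy barriers of ~19–22 kJ mol⁻¹; the quenching constant falls with
temperature while Kq sits far above the collisional ceiling, so the
quenching is static (ground-state complex); the double-log fit returns a
binding constant of 6.66×10⁴ L mol⁻¹ with one site; negative ΔH° with
positive ΔS° points to hydrogen bonding plus hydrophobic contacts; and the
tryptophan channel shows the larger red shift and quenching ratio, placing
Trp residues closer to the binding site. `write_report(report, dir)` saves
the same content as lossless JSON plus this text table.

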