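# aptfit

Model fitting and simulation for the in vitro characterization of
ligand-binding RNAs — riboswitch aptamers in particular. The package
covers the full quantitative workflow used to characterize preQ₁
riboswitches that bind one or two ligand molecules:

* **Equilibrium fluorescence titrations** (2-aminopurine assays):
  - exact single-site isotherm with ligand depletion — the bound
    fraction is the quadratic root
    `(S − √(S² − 4·cRNA·cL)) / (2·cRNA)` with `S = KD + cRNA + cL`;
  - cooperative **Hill** model `d·cL^n / (KD^n + cL^n)`;
  - **two-site binding-polynomial** model with partition function
    `Z = 1 + K₁L + K₁K₂L²` (`Kᵢ = 1/KD,i`), average occupancy
    `ν = (K₁L + 2K₁K₂L²)/Z`, and cooperativity factor
    `y = 4·KD,1/KD,2` (`y = 1` for independent identical sites).
* **Stopped-flow association kinetics**: per-trace fits to
  `F = A(1 − e^(−kobs·t))`, linear regression `kobs = kon·cL + d`,
  derived `koff = kon·KD` and complex half-life `ln2/koff`.
* **Job plots** (continuous variation): tangent intersection on the
  peak-shaped ΔF-vs-mole-fraction curve; a maximum at `x ≈ 1/3`
  indicates 2:1 ligand:RNA binding.
* **ITC**: "set of identical sites" and "two interdependent
  non-equivalent sites" forward models with injection-by-injection
  perfusion-cell dilution bookkeeping, fit by bounded nonlinear least
  squares.
* **Pull-down RT-qPCR**: `2^−Ct` abundances, input- and
  negative-control-normalized relative enrichment, and `2^−ΔΔCt`
  expression ratios.
* **Synthetic assays**: seeded generators for every assay type with
  known ground truth, so each analysis stage is validated by parameter
  recovery — no instrument data required.

All concentrations are molar inside the package; CSV files and the
command line use µM (mM for ITC syringe stocks).

## Worked example

Simulate a two-site titration at the standard design (0.5 µM RNA,
ligand 0–45 µM) with 2 % noise, then re-fit it:

```r
library(aptfit)
curve <- gen_titration("two_site", list(kd1 = 0.5e-6, kd2 = 2.2e-6),
                       noise = noise_spec(sd = 0.02, seed = 7))
fit <- fit_titration(curve, "two_site")
print(fit)
#> Nonlinear least-squares fit (14 points, 3 parameters)
#>   converged: TRUE   RSS: 0.00511656
#>            estimate        se
#> kd1       5.829e-07 5.846e-08
#> kd2       2.368e-06 3.601e-07
#> amplitude 1.034e+00 1.490e-02
```

The macroscopic stepwise dissociation constants come back as
KD,1 = 0.58 µM and KD,2 = 2.4 µM (truth: 0.5 and 2.2 µM; single-curve
scatter at 2 % noise), and `fit$cooperativity_y` ≈ 0.98 — near the
`y = 1` independent-sites point for this KD pair (`2.2 ≈ 4 × 0.5`).

Stopped-flow kinetics, simulated at post-mix ligand 1, 2, 6, 10 µM and
1 % noise, then pushed through the trace-fit + regression pipeline:

```r
traces <- gen_traces(kon = 1.16e3, koff = 7.2e-4,
                     noise = noise_spec(sd = 0.01, seed = 7))
kin <- analyze_kinetics(traces, kd = 0.62e-6)
print(kin$rate)
#> Association kinetics (kobs = kon * cL + d)
#>   kon       = 1161 +/- 2.6  M^-1 s^-1
#>   intercept = 0.0007168 +/- 1e-05  s^-1
#>   koff      = 0.0007196 s^-1 (from KD = 6.2e-07 M)
half_life(kin$rate$koff)   # ~16.1 min
```

The slope recovers the generating kon (1.16 × 10³ M⁻¹ s⁻¹), the
intercept independently approaches the generating koff, and the
equilibrium-consistent off-rate corresponds to a complex half-life of
about a quarter of an hour.

## Command line

```sh
aptfit simulate --assay itc --model identical_sites \
  --params '{"n_sites": 2, "kd": 1.5e-6, "dh": -10, "heat_offset": 0}' \
  --noise-sd 0.02 --seed 1 --out-prefix cal
aptfit fit-itc --input cal_itc.csv --model identical_sites \
  --cell-uM 73 --syringe-mM 1.84 --out itc.json
```

Subcommands: `fit-titration`, `fit-kinetics`, `fit-itc`, `jobplot`,
`simulate`, `enrich`, `recover` (simulate → fit → score loop reporting
per-parameter bias and RMSE). The launcher script is installed at
`inst/exec/aptfit`; equivalently call `aptfit_cli(c(...))` from R.

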