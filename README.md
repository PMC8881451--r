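# gwirekit

Quantitative analysis of DNA **G-wires** — nanostructures formed when short
guanine-rich oligonucleotides (the d(G2AG4AG2) family and its loop-substituted
variants) self-assemble into continuous stacks of G-quartets. The package is
aimed at groups characterising such assemblies by dynamic light scattering
(DLS), atomic force microscopy (AFM), restrained molecular-dynamics ensembles
and UV melting, and turns each raw measurement into comparable structural
numbers.

## What it computes

**Rigid-rod hydrodynamics.** A G-wire diffuses like a rigid cylinder of
hydrodynamic diameter d ≈ 3.0 nm. The Tirado–de la Torre model

    D_t = k_B T (ln p + ν(p)) / (3 π η L),    ν(p) = 0.312 + 0.565/p − 0.100/p²

(p = L/d, valid for 2 ≤ p ≤ 30) is implemented forward and inverse:
`rod_diffusion()` and `invert_rod_diffusion()` convert between length and
diffusion coefficient, `classify_regime()` separates rod-regime wires from
sphere-regime single quadruplexes at the computed boundary
D_t = D_rod(L = 2d) ≈ 1.04 × 10⁻¹⁰ m² s⁻¹, and Stokes–Einstein handles the
sphere branch. Lengths with p > 30 are flagged as outside the theory's
validity.

**Building-block arithmetic.** With the canonical 0.34 nm quartet rise and
4 quartets per unit, `count_units()` converts an effective length into the
number of stacked quadruplex units (floor division: only complete units
count). `parse_sequence()` handles run notation (`"G2AG4AG2"`) and the
non-nucleotide loop tokens `[li]` (C3 linker) and `[ab]` (abasic site).

**DLS pipeline.** `fit_two_mode()` fits the two-exponential Siegert model
g₂(t) = 1 + β(A_f e^(−q²D_f t) + A_s e^(−q²D_s t))² with deterministic,
data-driven initialisation; `assign_modes()` labels the fast mode (wires)
and slow mode (unspecific clusters); `wire_length_report()` chains fit →
regime → inversion → unit count.

**AFM statistics** (`fit_length_distribution()`, `tip_correct()`,
`summarize_heights()`), **groove geometry** from multi-model PDB ensembles
(`read_ensemble()`, `groove_series()`, `groove_summary()` with a scalar
periodicity score), **melting midpoints** from the derivative of A295(T)
(`melting_midpoint()`), and **seeded synthetic generators** for every input
(`simulate_g2()`, `sample_afm_table()`, `build_ideal_ensemble()`,
`simulate_melting()`).

## Worked example

```r
library(gwirekit)

# A measured fast-mode diffusion coefficient of 0.33e-10 m^2/s:
wire_length_report(0.33e-10)
#> Wire estimate
#>   D_t = 3.300e-11 m^2/s, regime = rod
#>   effective length L = 45.7 nm (p = 15.2), n_units = 33
#> Solvent conditions: T = 298.15 K, eta = 8.900e-04 Pa s
```

The report reads: this species diffuses slowly enough to be a rod
(below the ~1.04e-10 boundary), the rigid-rod inversion puts its effective
length at ~46 nm (axial ratio 15, comfortably inside the model's validity),
and that length accommodates 33 complete stacked four-quartet units of
1.36 nm each. A fast species instead returns a Stokes–Einstein radius:

```r
wire_length_report(1.55e-10)
#>   D_t = 1.550e-10 m^2/s, regime = sphere
#>   hydrodynamic radius R_h = 1.58 nm
#>   flags: above rod-regime boundary: Stokes-Einstein sphere model used
```

Closing the loop on synthetic data:

```r
trace <- simulate_g2(d_f = rod_diffusion(43), noise = 0.01, seed = 7)
fit_two_mode(trace)
#> Two-mode DLS fit
#>   beta  = 0.9060
#>   fast:  D_f = 3.5607e-11 m^2/s, A_f = 0.587
#>   slow:  D_s = 1.1384e-12 m^2/s, A_s = 0.413
#>   residual norm = 1.625e-01, converged = TRUE
```

The generating fast mode was `rod_diffusion(43)` = 3.44e-11 m² s⁻¹; at 1%
multiplicative noise the fit recovers it to ~3%, within its statistical
error.

A thin command-line front end lives at `inst/scripts/gwirekit`
(`gwirekit length --dt 0.33e-10`, `gwirekit dls-fit --trace trace.csv`, …)
and emits the same reports as JSON.

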