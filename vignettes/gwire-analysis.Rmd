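---
title: "Sizing self-assembled DNA G-wires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing self-assembled DNA G-wires: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwirekit)
```

## The problem

Short guanine-rich oligonucleotides such as d(G2AG4AG2) self-assemble in
K+ solution into G-wires: long nanostructures of continuously stacked
G-quartets, built from discrete four-quartet quadruplex units that
multimerise by end-to-end stacking. No single experiment measures a G-wire
population completely. Dynamic light scattering (DLS) sees solution-phase
diffusion; atomic force microscopy (AFM) sees surface-deposited wires through
a finite tip; coordinate ensembles from restrained molecular dynamics expose
groove geometry; UV melting reports thermal stability. `gwirekit` implements
the quantitative chain that turns each of these raw measurements into
comparable numbers — effective lengths, stacked-unit counts, groove widths,
melting midpoints — together with seeded generators that emulate every input
with known ground truth.

## Rigid-rod hydrodynamics

A G-wire is hydrodynamically a rigid cylinder of diameter $d \approx 3.0$ nm
(the quadruplex core plus side loops and hydration shell; the bare geometric
diameter is nearer 2.8 nm). For a cylinder of length $L$ and axial ratio
$p = L/d$, the Tirado–de la Torre model gives the translational diffusion
coefficient

$$D_t = \frac{k_B T\,(\ln p + \nu(p))}{3\pi\eta L}, \qquad
\nu(p) = 0.312 + \frac{0.565}{p} - \frac{0.100}{p^2},$$

valid for $2 \le p \le 30$. Below $p = 2$ the particle is better treated as
a sphere (Stokes–Einstein, $D_t = k_BT/6\pi\eta R_h$); above $p = 30$ the
end-effect interpolation leaves its fitted range, so inverted lengths are
still reported but always carry an out-of-validity flag.

The regime boundary is never hard-coded: it is the forward model evaluated
at $L = 2d$,

```{r}
regime_boundary(diameter_nm = 3.0)
```

about $1.04 \times 10^{-10}$ m$^2$ s$^{-1}$ for 3-nm rods in
room-temperature water. Measured coefficients below it are inverted for $L$
by bracketed root search (the forward model is strictly decreasing in $L$,
so the root is unique; bisection-safeguarded, relative tolerance $10^{-8}$,
no randomness):

```{r}
wire_length_report(0.33e-10)
```

### Solvent conditions

The reference experiments state only "room temperature". We fix the default
profile at 298.15 K and $8.90\times10^{-4}$ Pa s once, as the conventional
room-temperature water values, and echo the conditions in every report.
Because water viscosity changes ~2%/°C, an unstated experimental temperature
anywhere in 21–25 °C moves inverted lengths by several percent; this is the
dominant systematic in any comparison of absolute lengths, and the reason
length agreement is only meaningful to roughly ±7%.

## From length to stacked building blocks

The wire is a stack of four-quartet units spaced at the canonical 0.34 nm
quartet rise, so one unit spans 1.36 nm. The unit count is the *floor* of
$L / 1.36\,\mathrm{nm}$ — floor, not nearest, because only complete stacked
units exist structurally: a 28 nm wire contains 20 full units (28/1.36 =
20.6), a 67 nm wire 49. Nearest-integer rounding would overcount the lower
endpoint. A $+10^{-9}$ additive guard in the floor protects exact unit
multiples from floating-point truncation. Whether capping loops add length
beyond the stacked quartet core is unknown; the model counts the quartet
core only.

```{r}
count_units(c(28, 67))
```

## Two-mode DLS analysis

Wire solutions show two diffusive modes: a fast mode
($D_f \sim 10^{-10}$ m$^2$ s$^{-1}$) from individual quadruplexes and wires,
and a slow mode ($D_s \sim 10^{-12}$) from large unspecific polyelectrolyte
clusters unrelated to quadruplex formation. `fit_two_mode()` fits the
Siegert-relation model

$$g_2(t) = 1 + \beta\left(A_f e^{-q^2 D_f t} + A_s e^{-q^2 D_s t}\right)^2,
\quad A_f + A_s = 1,$$

directly to $g_2$ by Levenberg–Marquardt least squares. Fitting the field
correlation $g_1 = \sqrt{(g_2-1)/\beta}$ instead was considered and
rejected: the square root rectifies noise near the baseline and biases the
slow mode. Initialisation is deterministic and data-driven — $\beta$ from
the zero-lag extrapolation, decay rates from the lags where the normalised
field correlation first falls below 80% and 20%, amplitudes 0.5/0.5 — so
identical traces always give identical fits. If the two starting rates are
closer than a factor of 10 the slow start is pushed to $\Gamma_f/100$,
which keeps the degenerate single-mode case well-posed (it converges with
one amplitude at zero rather than two collinear modes). Fast/slow labels are
assigned by ordering; a warning is raised when $D_f/D_s < 10$, since
well-resolved measurements separate the modes by roughly two decades.

The scattering angle of the reference measurements is unstated; the default
setup uses 532 nm / 90° / $n = 1.33$, and the pipeline equally accepts a
pre-fitted $D_f$, in which case $q$ never enters.

```{r}
trace <- simulate_g2(d_f = rod_diffusion(43), noise = 0.01, seed = 7)
fit_two_mode(trace)
```

## AFM length statistics

Ridge-detected wire lengths follow a log-normal distribution; the package
fits it by maximum likelihood and reports the arithmetic mean with its
standard error ($s/\sqrt{N}$ — the convention consistent with reported
values like 22.1 ± 0.4 nm at $N = 907$). Tip–sample convolution makes wires
appear ~10 nm longer than they are; `tip_correct()` subtracts a constant
offset (flooring at zero with a warning), and the applied offset is carried
in the result's provenance. Whether published AFM means are tip-corrected
is usually unstated, so correction is opt-in, never silent.

The synthetic AFM generator draws true lengths log-normal and *adds* the
tip offset, so correction exactly inverts generation. Its defaults
(`meanlog = log(12.1) - 0.83^2/2`, `sdlog = 0.83`) were derived once from
the published summary statistics — observed mean 22.1 nm and SEM 0.4 nm at
$N = 907$ imply a population sd of ~12 nm before the +10 nm offset. Heights
are Gaussian with sd 0.1 nm: a ±0.1 error on a 2.0 nm mean cannot be an SEM
at $N = 907$ (it would imply a 3 nm sd), so it is treated as the population
spread.

## Groove geometry from coordinate ensembles

For multi-frame models of stacked quadruplexes, the groove dimension is the
P–P distance between the phosphates of the two loop residues flanking the
groove (positions 3 and 8 in the G2XG4XG2 family), measured per frame and
reported in nm. Which P–P pair spans which groove depends on the fold, so
the pairing is explicit configuration (a pair table), not inference;
`default_groove_pairs()` documents the layout for the built-in generator.
Summaries give per-groove mean and standard deviation, grouped by
building-block index and stacking interface (3'-3' / 5'-5'), plus a single
periodicity score — the maximum absolute deviation of a groove mean from the
grand mean — so "smallest deviation with nicest periodicity" becomes a
comparable scalar.

The ensemble generator places four loop-phosphates per ring on a circle
whose four chords equal the requested groove widths (the radius solves
$\sum_k 2\arcsin(w_k/2r) = 2\pi$), stacks rings at the 0.34 nm rise with a
30°-per-quartet twist, and jitters every coordinate with Gaussian noise
(default 0.5 Å). 490 frames corresponds to 9.8 ns sampled every 20 ps. Note
one numerical subtlety used by the tests: the mean of a distance between two
jittered points exceeds the true separation by $\approx 2\sigma^2/w$
(noncentral-chi bias), so recovery checks compare against the convolved
expectation, not the raw width.

```{r}
ens <- build_ideal_ensemble(groove_widths_nm = c(1.6, 1.8, 1.7, 1.9),
                            frames = 100, seed = 1)
ga <- groove_analysis(ens, default_groove_pairs(4))
head(ga$summary$per_groove)
ga$summary$periodicity_score_nm
```

Interface grooves join the top loop ring of one unit to the bottom ring of
the next, so their spans include the axial rise; only intra-unit grooves
carry the imposed chord widths exactly.

## Melting midpoints

Quadruplex unfolding is hypochromic at 295 nm. $T_{1/2}$ is the temperature
of the extremum of the first derivative of $A_{295}(T)$: the curve is
smoothed with a 5-point moving average (configurable; the reference method
does not state a smoothing), differentiated by centred differences, and the
largest-magnitude derivative located. When that extremum falls within one
smoothing window of either end of the range, the transition is not bracketed
by the data — typical of curves that never reach their high-temperature
plateau — and the estimate carries an edge flag rather than silent trust.
The resolution of the estimate is the temperature grid spacing.

```{r}
melting_midpoint(simulate_melting(midpoint_C = 85, noise = 0))
```

## What the synthetic data do and do not show

Every generator is a pure function of its parameters and an explicit seed
(the global RNG state is saved and restored), writes the same formats the
readers consume, and records its seed in file headers. They emulate the
*statistical structure* of the real measurements — two-exponential decays
with multiplicative noise, log-normal length populations with constant tip
broadening, Gaussian groove jitter around ideal geometry, two-state melting
sigmoids with linear baselines. They deliberately do not emulate:
polydispersity of the fast DLS mode (one $D_f$ per trace, where a real wire
population has a length distribution and intensity weighting that favours
long wires as scattering scales with the squared volume), correlated
trajectory dynamics (frames are independent), tip convolution geometry
(a constant offset, not a shape-dependent deconvolution), or baseline drift
in melting curves. Passing tests therefore demonstrate that the inference
chain is correct and well-calibrated for data matching its model
assumptions — not that those assumptions hold for any particular instrument.

## Numerical choices and problem sizes

- Rod inversion: `uniroot` on [2d, 10^4] nm, absolute tolerance 1e-8 nm;
  the round-trip forward-inverse identity holds to 1e-6 relative.
- Two-mode fits: diffusivities parameterised in units of 1e-10 m^2/s for
  conditioning; box constraints keep amplitudes in [0,1] and rates
  positive; convergence tolerances 1e-15 so noise-free traces recover truth
  to ~1e-8 relative.
- Degenerate inputs: flat traces, flat melting curves, constant-length
  samples, single-atom lookups and divergent PDB rosters all raise typed
  errors naming the offending input, never NA propagation.
- Test-suite problem sizes (chosen to exercise the statistics at a few
  seconds total): 25-seed DLS recovery studies, 5000-draw log-normal fits,
  100-fit CI-coverage grids, 200–490-frame ensembles.

## Limitations

Bead-model and wormlike-chain hydrodynamics, rotational diffusion,
concentration corrections, regularised inverse-Laplace (CONTIN-style) DLS
analysis, multi-angle global fits, image-domain ridge detection, and any
prediction of fold topology from sequence are out of scope. Lengths above
$p = 30$ and melting midpoints at the range edge are reported with flags;
treat them as lower/upper bounds, not estimates.
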