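---
title: "Modelling electrostatic charge shielding of PIP2 by cations"
author: "shieldfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electrostatic charge shielding of PIP2 by cations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shieldfit)
```

## The problem

Phosphatidylinositol 4,5-bisphosphate (PIP2) is a polyanionic lipid whose
hydrolysis by phospholipase C (PLC) produces the second messengers IP3 and
DAG. Because the PLC-PIP2 interaction is largely electrostatic, cations that
accumulate around the negatively charged head group — divalent metals,
polyamines, the hexacationic antibiotic neomycin — shield that charge and
reduce the substrate pool effectively visible to the enzyme. `shieldfit`
implements a quantitative equilibrium model of this charge shielding, the
staged least-squares procedure that estimates its parameters from normalized
dose-response curves, a chelator speciation solver for computing the free-ion
composition of the assay solutions, and a synthetic-data generator so that
every stage can be exercised and validated without any external dataset.

## The shielding model

In a solution assay the substrate analog is not embedded in a membrane, so
the model treats it as a point charge at a local potential $\Psi < 0$. A
cation of valence $z$ then accumulates around the substrate by the Boltzmann
factor

$$ C_\mathrm{eff} = C_\mathrm{bulk} \exp\!\left(-\frac{zY q \Psi}{k_B T}\right), $$

where $Y \in (0, 1]$ discounts the effective valence of bulky organic
polycations: their charges are spread over the molecule (charge-separation
effect) and their size limits how many can pack near the substrate (crowding
effect). Small inorganic ions have $Y = 1$.

Free substrate falls with the effective concentration through a Hill-type
electrostatic term with half-maximal constant $L$, and a mass-action binding
term with association constant $K$:

$$ [\mathrm{PIP_2}]_\mathrm{free} =
  \left([\mathrm{PIP_2}]_\mathrm{total} - W\right)
  \frac{L_z}{L_z + C_\mathrm{eff}}
  \cdot \frac{1}{1 + K\,C_\mathrm{eff}} + W. $$

$W$ is a residual pool of unshieldable substrate, nonzero only for neomycin,
whose inhibition plateaus below completeness (plausibly because of steric
hindrance or self-repulsion between the highly charged molecules). Enzyme
activity follows a binding-limited rate law, reported relative to the
cation-free condition:

$$ A(C) = \frac{v(C)}{v(0)}, \qquad
   v(C) = \frac{[\mathrm{PIP_2}]_\mathrm{free}(C)}
               {[\mathrm{PIP_2}]_\mathrm{free}(C) + K_d}. $$

Normalizing by $v(0)$ removes the scale constants of the raw rate law
(enzyme amount and $k_{cat}$), which are not identifiable from normalized
curves.

### Default parameters

The packaged defaults (in `inst/extdata/paper_defaults.yaml`) are
$\Psi = -25$ mV (a molecular-dynamics estimate for this substrate; the model
never fits it, see *Identifiability*), $T = 295.15$ K, total substrate
30 µM, $K_d = 50$ µM, $L_{\mathrm{ref}} = 32$ mM anchored at $z_{ref} = 2$,
and per-cation values

```{r}
str(default_cations(), max.level = 1)
```

with $K$ spanning 1 M$^{-1}$ (Mg$^{2+}$, almost purely electrostatic
accumulation) to 460 M$^{-1}$ (Ba$^{2+}$) and 1000 M$^{-1}$ (neomycin), and
$Y = 0.12$ shared by all organic polycations. $k_B T / q$ is evaluated from
physical constants, not hard-coded as 25 mV.

### Valence scaling of L

$L$ is estimated with the reference divalent; for other valences it is
reduced proportionally, $L_z = L_{\mathrm{ref}}\, z_{ref}/z$, using the
nominal valence $z$ rather than $zY$. This is the literal reading of
"reduced proportionally to valence" with the divalent anchor, and it is
exposed as a pluggable rule (`shielding_params(L_scale = ...)`) for anyone
wanting a different convention.

### Identifiability

The data constrain only the products through which $\Psi$ enters: replacing
$\Psi \to \Psi'$ while rescaling $L \to L f'/f$ and $K \to K f/f'$ (where
$f$ is the Boltzmann factor) leaves every model curve unchanged. The test
suite asserts this numerically. Consequently $\Psi$ is always held fixed and
only $L$, $K$, $Y$, $W$ are ever estimated. $K_d$ is likewise fixed (50 µM
for all enzymes); normalized curves constrain it only weakly and jointly
with $L$.

### Multi-cation background

The assay background contains 16.4 µM free Ca²⁺, whose contribution to
shielding at these levels is of order 2% and is ignored: the canonical model
treats one added cation at a time, as the experiments do. An optional
multiplicative mode (`multi_cation_activity()`) multiplies the per-cation
suppression terms for users who want to explore additive shielding.

## Chelator speciation

Assay solutions buffer free Ca²⁺ with EGTA; adding MgCl₂ or BaCl₂ displaces
Ca²⁺ from the chelator and raises free Ca²⁺. The `chelator` functions solve
the simultaneous mass-action/mass-balance system for any set of metals and
ligands with records in the packaged stability-constant table. Tabulated
constants (reference: 0.1 M ionic strength, 20 °C, NIST-derived values from
the calcium-buffer literature) are adjusted to the requested conditions by

- *proton competition*: the ligand protonation polynomial $\alpha_H$ at the
  solution pH, including metal binding by the monoprotonated ligand
  (M + HL ⇌ MHL) — at pH 7.3 most EGTA is HL³⁻, which matters for Mg²⁺;
- *ionic strength*: a Davies-type activity correction with the
  Debye–Hückel slope evaluated at the solution temperature;
- *temperature*: van 't Hoff adjustment where an enthalpy is tabulated.

pH is treated on the concentration scale ($[H^+] = 10^{-\mathrm{pH}}$), and
HEPES, KCl, DTT and BSA enter only through the stated ionic strength, as in
standard free-ion calculators. The solver eliminates free metals
analytically given free ligand, solves each ligand's scalar balance by
bracketed root finding (monotone, hence unique), and Gauss–Seidel iterates
across ligands to a relative residual of 1e-12 (cap 200 sweeps). This is
positivity-preserving by construction and deterministic.

The base composition (3 mM CaCl₂, 3 mM EGTA, pH 7.3, ionic strength 0.073,
20 °C) is reported by two sections of the source material with pH 7.3 and
7.4 respectively; the package defaults to pH 7.3 and the tests check the
printed free-Ca values at that pH while asserting the qualitative invariants
at both. Published EGTA constant sets differ by ±0.1–0.2 log units across
compilations, which is why agreement with printed calculator outputs is
assessed at ±10%.

## Staged fitting

The estimation mirrors the staged narrative of the original analysis rather
than one global fit (a joint refit of K and W happens only for neomycin,
where no separate K stage exists):

1. **L** from the reference divalent (Mg²⁺, K fixed at 1 M⁻¹) per enzyme,
   then averaged across enzymes;
2. **K** per remaining small cation, L fixed;
3. **Y** (with the organic divalent's K) from putrescine vs the reference
   divalent on the same enzyme; Y is then frozen for all organic
   polycations;
4. **W** (with K) for plateau-capable cations.

The optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
parameter tolerance 1e-10) started from a coarse log-grid scan, with L
optimised on the log scale. Residuals are unweighted by default (the source
analysis states no weighting); `weighted = TRUE` switches to 1/SD²
weighting. Estimates that land on a bound are flagged rather than silently
clipped, flat curves yield a flagged non-estimate, and fewer than two doses
in the activity transition region raises an ill-conditioning note in the
diagnostics. Uncertainty comes from a case-resampling bootstrap over the
replicate measurements within each dose level, with percentile intervals.

```{r}
params <- default_params()
cations <- default_cations()
doses <- 10^seq(log10(1e-4), log10(0.3), length.out = 12)
ds <- generate_dose_response(cations$Mg, params, doses,
                             noise_model(n_rep = 1, sd = 0, seed = 1))
fit_stage_L(ds, params)
```

## Synthetic data

The generator emulates exactly the statistical structure the fitter assumes:
replicate normalized activities with additive i.i.d. Gaussian noise (default
SD 0.05, replicate counts 4–8, matching the reported replication), clipped
at −0.05, around the exact model curve; and fluorogenic progress curves
following the closed-form Michaelis–Menten solution (Lambert-W form),
converted to fluorescence through a linear standard curve. Dose grids
default to log-spaced ranges spanning the published figures (10 µM–100 mM
for divalents, 0.1 µM–10 mM for neomycin). What it does *not* emulate:
systematic errors (pipetting drift, inner-filter effects, enzyme
instability over the incubation), non-Gaussian or dose-dependent noise, and
any direct cation effect on the enzyme itself. Passing round-trip tests
therefore demonstrates correctness of the estimation machinery under the
model's own assumptions, not validity of the model for any particular real
dataset.

All randomness flows through explicit integer seeds; generation is bitwise
reproducible and never perturbs the caller's RNG stream.

The printed specific activities in the source material
(mmol · min⁻¹ · mg⁻¹) are dimensionally inconsistent with the observed
depletion timescales (likely a unit typo); the time-course generator
therefore takes specific activity as a free field and hard-codes no value.

## Rate extraction

`fit_standard_curve()` fits an ordinary least-squares line (intercept
fitted, not forced through zero) to calibration points;
`rate_from_timecourse()` inverts it, fits a linear slope over a configurable
time window, and converts to mol · min⁻¹ · mg⁻¹ using the reaction volume
(default 20 µL). Window defaults follow the source protocol (slope at
10 min for the fast isoform, 30 min otherwise; endpoint incubations 90, 60
and 12 min). Both slope-based and endpoint readouts are supported; slope is
the default since the windowed slope is less biased by substrate depletion
(the bias is bounded by the fraction of substrate consumed, which the tests
check).

## Numerical choices and degenerate inputs

- Speciation: residual tolerance 1e-12 relative, iteration cap 200,
  log-scale bracketing keeps all concentrations positive; a solution with
  no ligand (or all-zero totals) returns free = total exactly.
- IC50: bracketing plus bisection to 1e-6 relative; when the activity
  plateau exceeds 0.5 the half-inhibition point does not exist and `NA` is
  returned (the CLI prints `"none"`).
- Fitting: ties at bounds are reported via boundary flags; the grid start
  makes the 1-2 parameter problems effectively global.
- Problem sizes used in the packaged studies: 12-point dose grids (14 for
  neomycin), 3 enzymes for the L stage, 100 seeded repeats with 150
  bootstrap draws for the coverage study — sizes chosen to make the
  simulation studies decisive yet quick to re-run.

## Known limitations

- The point-charge Boltzmann treatment deliberately ignores spatial
  structure (no Gouy–Chapman/Poisson–Boltzmann electrostatics, no membrane
  geometry); it is the appropriate idealization for a soluble substrate
  analog, not for membrane-embedded lipid.
- The Hill coefficient of the electrostatic term is fixed at 1, as the
  model is written.
- Model-predicted IC50 values under the printed parameter set do not
  necessarily reproduce experimentally quoted IC50s for every
  enzyme-cation pair; the staged estimates, not the IC50s, are the
  package's validated outputs.
- The stability-constant table ships EGTA/Ca/Mg/Ba only; other
  chelators or metals require adding rows with their reference conditions.
- The units of the residual plateau W are interpreted as µM of substrate
  (the same units as total substrate), which yields a ~20% residual
  activity plateau consistent with the published curve shapes; the source
  prints the value without units.
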