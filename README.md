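# shieldfit

Quantitative modelling of **electrostatic charge shielding of PIP2 by
cations** and its effect on phospholipase C (PLC) activity.

PIP2 (phosphatidylinositol 4,5-bisphosphate) is a polyanionic signalling
lipid. Divalent metals (Mg²⁺, Ca²⁺, Ba²⁺), polyamines (putrescine²⁺,
spermidine³⁺, spermine⁴⁺) and neomycin⁶⁺ accumulate around its negatively
charged head group, shield the charge that PLC recognises, and thereby
inhibit hydrolysis. `shieldfit` is for enzymologists and membrane
biophysicists who want to fit or simulate this behaviour quantitatively:
it bundles

- a **chelator speciation solver** (EGTA/Ca/Mg/Ba, with pH, ionic-strength
  and temperature corrections) for computing the free-ion composition of
  buffered assay solutions,
- the **charge-shielding activity model**,
- a **staged nonlinear least-squares fitter** for its parameters with
  bootstrap uncertainty and IC50 extraction,
- a **synthetic-data generator** (noisy dose-response curves; fluorogenic
  Michaelis-Menten progress curves with standard-curve calibration), and
- **standard-curve rate extraction** for fluorogenic PLC assays, plus a
  command-line wrapper.

## The model

A cation of valence $z$ at bulk concentration $C$ is enhanced near the
substrate (treated as a point charge at local potential $\Psi$) by the
Boltzmann factor:

$$C_\mathrm{eff} = C\,e^{-zYq\Psi/k_BT},$$

with $Y \le 1$ discounting the effective valence of bulky organic
polycations. Free substrate combines a Hill-type electrostatic term
(half-maximal constant $L_z = L_{\mathrm{ref}}\,z_{ref}/z$) with chemical
binding (association constant $K$) and an unshieldable residue $W$:

$$[\mathrm{PIP_2}]_\mathrm{free} = ([\mathrm{PIP_2}]_\mathrm{total}-W)\,
\frac{L_z}{L_z+C_\mathrm{eff}}\cdot\frac{1}{1+KC_\mathrm{eff}} + W,$$

and normalized activity is
$A(C) = v(C)/v(0)$ with
$v = [\mathrm{PIP_2}]_\mathrm{free}/([\mathrm{PIP_2}]_\mathrm{free}+K_d)$.
Parameters are estimated in stages — $L$ from the reference divalent
(Mg²⁺), then per-cation $K$, then $Y$ (putrescine vs Mg²⁺), then $W$
(neomycin) — see the vignette `vignettes/charge-shielding.Rmd` for the
full account.

## Worked example

Free Ca²⁺ in the standard assay buffer after adding 15 mM BaCl₂ — Ba²⁺
displaces Ca²⁺ from EGTA:

```r
library(shieldfit)
sol <- assay_solution(c(Ca = "3mM", Ba = "15mM"), c(EGTA = "3mM"))
solve_speciation(sol)
#> Speciation result (converged, residual 1.16e-16)
#>   free Ca    0.000332501 M
#>   free Ba      0.0146683 M
#>   free EGTA  8.00241e-07 M (unbound, all protonation states)
#>   Ca-EGTA       0.0026675 M bound
#>   Ba-EGTA       0.0003317 M bound
```

Free Ca²⁺ rises from 17 µM to 333 µM (Ba²⁺ strips the chelator), while
only ~2% of the added Ba²⁺ is consumed — so a Ba²⁺ dose-response stays
interpretable at its nominal concentrations.

Recover the electrostatic constant L from synthetic Mg²⁺ curves for three
enzymes and extract an IC50:

```r
params <- default_params()
cations <- default_cations()
doses <- 10^seq(log10(1e-4), log10(0.3), length.out = 12)
mg <- lapply(c("PLCb1", "PLCg1", "PLCd1"), function(e)
  generate_dose_response(cations$Mg, params, doses,
                         noise_model(n_rep = 1, sd = 0, seed = 1), enzyme = e))
fit_stage_L(mg, params)
#> Stage L fit: PLCb1:Mg 0.032, PLCg1:Mg 0.032, PLCd1:Mg 0.032
#>   stage value: 0.032
ic50(cations$Ba, params) * 1e3
#> [1] 0.419   # mM
```

The recovered stage value 0.032 M is the generating L of 32 mM: on
noiseless data the staged fitter reproduces the packaged defaults
(L = 32 mM, K(Ba²⁺) = 460 M⁻¹, Y = 0.12, W = 4.1 µM) to better than 0.1%.
The Ba²⁺ IC50 of ~0.42 mM reflects its strong chemical binding on top of
the electrostatic accumulation shared by all divalents.

A one-command reproduction of the default analysis (free-ion table,
simulated curves, staged refit, comparison table):

```sh
Rscript inst/cli/shieldfit.R reproduce --out out/ --seed 7
```

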