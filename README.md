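# polbkin

Pre-steady-state kinetic analysis of single-nucleotide gap filling by
DNA polymerase β, focused on the covalently DNA-crosslinked enzyme that
arises during base excision repair: after the dRP lyase domain forms a
Schiff base with the 5′-dRP group, Pol β fills the gap while still
tethered to its substrate. The crosslink abolishes the fast DNA
dissociation that limits kinetic work on the free enzyme, so quench-flow
experiments on the crosslinked complex can interrogate enzyme-bound
intermediates directly. This package is for enzymologists who run (or
want to model) those experiments.

## What it implements

**Mechanism simulation.** Mass-action reaction networks for the
crosslinked mechanism (ten steps: DNA binding, Schiff-base formation,
binary-substate exchange, dNTP binding with K_d = k₋₄/k₄, the
rate-limiting active-site rearrangement k₅ = k_p — optionally split into
sub-steps 5/5i — reversible chemistry k₆/k₋₆, reopening, PPi release,
β-elimination, product release) and the classical seven-step
uncrosslinked mechanism, integrated with a stiff ODE solver. Product is
observed as every species at or past phosphodiester bond formation, the
mechanistic counterpart of a quantified gel band.

**Protocol emulation.** Single-turnover rapid quench,
pulse-quench/pulse-chase with explicit labeled/unlabeled species
bookkeeping, sulfur (phosphorothioate) elemental substitution as an
f-fold reduction of the chemistry rates, Eyring temperature scaling
k = κ(k_B T/h)·e^(ΔS‡/R)·e^(−ΔH‡/RT), and viscosity scaling of
diffusion-sensitive steps.

**Estimation.** Single-exponential fits
[product] = A(1 − e^(−k_obs·t)), linear fits for slow misincorporation,
the linearized Eyring regression of ln(k/T) on 1/T yielding ΔH‡ and ΔS‡,
and ΔG‡(T) = ΔH‡ − TΔS‡ with propagated uncertainty.

**Diagnostics.** Elemental-effect classification against the revised
10–160 benchmark for a rate-limiting chemical step, slope-derived rate
constants (k = slope/A), pulse amplitude partitioning (intermediate
pool A_chase − A_quench, forward fraction f = A_q/A_c, internal
equilibrium constant K_int = A_q/(A_c − A_q), release rate
k_chase(1 − f)/f), and a rate-limiting-step decision table.

**Synthetic data.** A seeded generator for the full experiment battery
(closed-form or mechanism-based) with additive Gaussian noise, used for
parameter-recovery testing of the whole pipeline.

## Worked example

```r
library(polbkin)

# simulate a single-turnover run (30 nM crosslinked complex + 25 uM dCTP)
# and fit the product time course
r   <- default_rates("crosslinked")
tc  <- simulate_single_turnover(r, protocol_config(dNTP_uM = 25))
fit_single_exponential(tc)
#> <exp_fit> A = 20.74 +/- 0.11 nM, k_obs = 0.6409 +/- 0.0078 s^-1 (n = 13, converged)

# sulfur elemental effect for correct incorporation
elemental_effect(0.77, 0.21)
#> <elemental_effect> ratio = 3.67 -> not_chemistry_limited (benchmark 10-160)

# pulse-chase / pulse-quench amplitude partitioning
partition_analysis(16.3, 24.5, 0.55)
#> <partition_analysis> A_chase/A_quench = 1.5, diff = 8.2 nM, f = 0.665, K_int = 1.99, release = 0.277 s^-1

# Eyring analysis and the activation free energy at 37 C
T_K <- c(293.15, 298.15, 303.15, 310.15)
fit_eyring(T_K, eyring_rate(21.5, 11.5, T_K))
#> <eyring_fit> dH = 21.5 +/- 3.6e-14 kcal/mol, dS = 11.5 +/- 1.2e-13 cal/(mol K)
delta_g(list(dH_kcal = 21.5, dS_cal = 11.5, se_dH = 0.2, se_dS = 0.5), 310.15)
#>    dG_kcal      se_dG
#> 17.9332750  0.2530776
```

The simulated single-turnover rate tracks the configured k_p
(0.72 s⁻¹) to within the fit bias of the sequential mechanism; the
small elemental effect says chemistry is not rate-limiting for correct
incorporation; the excess pulse-chase amplitude exposes an 8.2 nM
pre-chemistry ternary intermediate with an internal equilibrium constant
of ≅2 that partitions 67%/33% between product formation and nucleotide
release; and the activation parameters give a ~17.9 kcal/mol barrier at
37 °C. An end-to-end run over a synthetic suite, including the verdict
on the rate-limiting step, is one call:

```r
run_pipeline(list(synthetic = list(seed = 1, sd_nM = 0)))
```

## Layout

- `R/` — mechanism core, protocols, fitting, diagnostics, synthetic
  data, I/O and pipeline
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/crosslinked-polymerase-kinetics.Rmd` — the methods
  vignette: model, assumptions, default parameters and their rationale,
  numerical choices, limitations
- `scripts/acceptance.R` — reproducibility script
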