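# ankthermo

Structural-bioinformatics pipeline around a simple question: is the
ankyrin (ANK) domain of the Notch-1 receptor built to act as a
**thermodynamic sensor** — a protein module whose binding in the
RBPJ/Notch/MAML-1 transcription complex fails when the cell warms by a few
kelvin? The package is for computational structural biologists who want
the full argument as runnable, tested code: repeat anatomy, disorder
energetics, electrostatics, interface hydrogen bonds, a reduced dynamics
model and the cellular heat-budget arithmetic.

## The model

The ANK domain is a stack of 33-residue repeats (helices α1, α2, then a
β-hairpin). The pipeline implements:

- **Disorder energetics.** A Boltzmann-inverted pairwise potential
  *E*ᵢⱼ = −ln(ρᵢⱼ/ρ\*ᵢⱼ) over amino-acid pairing frequencies, a windowed
  per-residue disorder score in [0, 1], and the destabilization
  coefficient

  *c* = *R* · (*S*<sub>target</sub>/*S*<sub>ref</sub>) · *n* / 1000  [kcal·mol⁻¹·K⁻¹]

  with *R* = 1.987 cal·mol⁻¹·K⁻¹, *S* the domain-mean disorder scores and
  *n* the residue count. Dissociation threshold ΔT = |ΔG⁰|/*c*,
  optionally divided by the rigid-body degrees of freedom; heat spike
  ΔT = *P*·*t* / (*c*<sub>w</sub>·*m*) for a cell of mass *m* heating at
  power *P*.
- **Electrostatics.** Formal side-chain charges, a Shrake–Rupley dot
  surface, single-dielectric Debye–Hückel potential
  φ(r) = Σ *C qᵢ* e^(−r/λ_D)/(ε r), connected-component detection of
  charged surface zones, carboxyl–carboxyl distance tables and charge
  anisotropy.
- **Interface inventory.** Geometric hydrogen-bond detection
  (donor–acceptor ≤ 3.5 Å, angle ≥ 120°) with per-chain-group counts for
  the ternary complex.
- **Reduced dynamics.** A Langevin-integrated chain of coupled
  oscillators, one site per repeat along the domain's long axis, with
  charge-dependent site softening and screened-Coulomb coupling — a
  stand-in for temperature-dependent molecular dynamics that reproduces
  the orderings (warmer ⇒ larger RMSF; discharging the central repeat ⇒
  dampening).
- **Assay arithmetic.** Pfaffl expression ratios, amplification-efficiency
  regression over the window of linearity, and nearest-neighbor melting
  temperatures for stem-loop beacon thermometers.
- **Synthetic generators** for idealized repeat structures, planted
  hydrogen-bond complexes, charge clusters and qPCR curves, so the whole
  pipeline is testable offline.

## Worked example

```r
library(ankthermo)

thermo_report(score_target = 0.37, score_ref = 0.21, n_residues = 230,
              deltaG0 = -8, ndof = 3)
#> $per_residue_cal          3.500333
#> $coefficient_kcal_per_K   0.8050766  (printed as 0.8)
#> $dissociation_delta_t_K   10
#> $dof_threshold_K          3.333  (~3 K)
#> $heat_spike_K             4.780115

chain <- build_chain()              # 7 repeats, acidic charges on 3-6
rmsf_by_temperature(chain, c(310.15, 312.15), seeds = 1:10, steps = 2e5)
#>              [,1]    [,2]   [,3]   [,4]   [,5]    [,6]    [,7]
#> 310.15     0.0978  0.0951 0.1017 0.1155 0.1030  0.0979  0.0971
#> 312.15     0.0982  0.0954 0.1021 0.1159 0.1033  0.0983  0.0974
```

Reading: a 0.8 kcal·mol⁻¹·K⁻¹ destabilization coefficient means a 10 K
rise offsets the −8 kcal·mol⁻¹ binding free energy (≈3 K per degree of
freedom), on the same scale as the ≈4.8 K one-second heat spike of a
20 nW cell — and the charged repeat 4 fluctuates most, more so at 39 °C
than 37 °C.

The numbered scripts under `analysis/` run the full narrative
(segmentation → composition enrichment → disorder → thermodynamics →
surface zones → hydrogen bonds → oscillator sweep → assays) and write
their tables under `results/`.

## Layout

- `R/`, `src/` — package code (Rcpp Langevin core in `src/`)
- `analysis/01_*.R … 06_*.R` — narrative drivers over the package
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/thermosensor-methods.Rmd` — model, parameters, calibration
  and limitations
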