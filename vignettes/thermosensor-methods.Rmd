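---
title: "Methods: the ankyrin domain as a thermodynamic sensor"
author: "ankthermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ankyrin domain as a thermodynamic sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the chain of reasoning

The active Notch transcriptional complex assembles when the Notch
intracellular domain binds RBPJ and MAML-1 on DNA; the contact surface is
carried largely by the ankyrin (ANK) domain, a stack of 33-residue repeats
(two antiparallel helices a1/a2 followed by a beta-hairpin). `ankthermo`
implements, as a tested pipeline, the computational argument that this
domain is built to *fall apart* with a small temperature rise — a
thermodynamic sensor that terminates signalling when a cell heats up:

1. **Repeat anatomy and composition.** The domain is segmented into
   33-residue repeats and the per-element amino-acid composition is
   compared between variants: alanine enrichment in the helices (a helix
   stabiliser) and acidic-residue enrichment on the solvent-exposed
   hairpins are the structural signature of interest.
2. **Disorder energetics.** A Boltzmann-inverted pairwise potential
   `E_ij = -ln(rho_ij / rho*_ij)` converts pairing statistics into
   dimensionless interaction energies; a windowed, composition-weighted
   average mapped through a logistic gives a per-residue disorder score in
   [0, 1]. The ratio of domain-mean scores (sensor domain vs a reference
   set), times the molar gas constant and the residue count, is a
   destabilization coefficient in energy per kelvin.
3. **Thresholds.** With domain means 0.37 (Notch-1 ANK) against 0.21
   (yeast reference; 0.22 for other human ankyrin domains) and 230
   residues, the coefficient is `1.987 × (0.37/0.21) × 230 / 1000 ≈ 0.8`
   kcal·mol⁻¹·K⁻¹. A binding free energy of −8 kcal·mol⁻¹ is then offset
   by a 10 K rise, or ~3 K if the destabilization funnels into one of
   three rigid-body degrees of freedom of the repeat stack.
4. **Heat budget.** A cell of ~1 ng water mass producing 20 nW for one
   second heats itself by `20 / 4.184 ≈ 4.8` K — the same order as the
   dissociation threshold, which is what makes the sensor plausible.
5. **Electrostatics and dynamics.** Clustered acidic side chains create
   zones of negative surface potential; their mutual repulsion is proposed
   to drive temperature-dependent fluctuation of the repeat stack, probed
   here with a coupled-oscillator model rather than all-atom molecular
   dynamics.

The package computes every step; the `analysis/` scripts narrate them in
order and write their tables under `results/`.

## Disorder scorer: scope and calibration

The scorer re-implements the energy-estimation *idea* behind pairwise
disorder predictors, not any published parameter fit. Pairing frequencies
are counted within a sequence window (`contact_window`, default 2
positions), the reference state is the marginal product, and unobserved
pairs are flagged `NA` and imputed only at scoring time with the row
maximum + 1 (unseen pairings are treated as unfavourable; `NaN`s never
propagate). The per-residue energy is the mean pair energy over a centred
window (default 21, truncated at the termini) and the logistic that maps
energy to [0, 1] has slope 0.5 and a midpoint centred so that a packaged
ordered-like / disordered-like synthetic sequence pair straddles 0.5
(`calibrate_midpoint()`); with toy alphabets the midpoint falls back to the
mean imputed energy. Because published score curves depend on the original
tool's fitted parameters, this module is validated on *orderings* only
(hydrophobic-core below charge-rich under a fixed potential), and
externally computed per-residue scores can be supplied as a TSV
(`read_disorder_scores()`) so published domain means can be used verbatim —
which is exactly what the thermodynamic layer does with 0.37/0.22/0.21/0.16.

The printed per-residue coefficient of 3.5 cal·mol⁻¹·K⁻¹ back-computes to
the 0.21 reference (1.987 × 0.37/0.21 = 3.50, vs 3.34 with 0.22), so 0.21
is the default `score_ref`; both references are always computed side by
side and round to the same 0.8 kcal·mol⁻¹·K⁻¹ domain coefficient. Values
are carried at full precision; rounding (one decimal for the coefficient,
integer kelvin for the partitioned threshold) happens only at reporting.

## Electrostatics: a screened-Coulomb stand-in

The published surface maps come from a two-dielectric Poisson–Boltzmann
solver. Here the potential is single-dielectric Debye–Hückel screening,
`phi(r) = Σ C q_i exp(-|r-r_i|/λ_D) / (eps |r-r_i|)`, with `C` the Coulomb
constant (1389.35 kJ·Å·mol⁻¹·e⁻²), `eps = 78` (the solvent value; the
protein dielectric 2 of the original settings has no role in a
single-dielectric model) and `λ_D ≈ 7.8 Å` at 0.15 M monovalent salt and
298.15 K. Zero ionic strength recovers pure Coulomb exactly. Formal
charges sit at the carboxyl-oxygen midpoint (D/E, −1), NZ (K, +1) and CZ
(R, +1); histidine defaults to 0 (pH 7 approximation, configurable).

Surfaces are Shrake–Rupley dot surfaces (probe 1.4 Å, 240 dots per atom by
default — enough that patch membership is stable on the fixtures used
here) and patches are connected components of super-threshold points
(default −5 kJ·mol⁻¹·e⁻¹, the display-scale extreme; adjacency twice the
mean dot spacing). Under this stand-in, **patch areas are comparative
quantities only**: the published ~289/327 Å² zone areas depend on the
solver and iso-potential choice and are deliberately not reproduced. What
is tested is zone *identity* — which residues line which zone — which the
planted-cluster fixtures recover exactly.

## The coupled-oscillator model

The repeat stack is reduced to one displacement per repeat along the
domain's long axis (the published reduction of repeat-stack flexibility to
one major axis). Sites are tethered by an on-site spring (`k_intra = 100`,
the internally rigid helix bundle), coupled by soft nearest-neighbour
links (`k_link = 5`, the hairpin connectors), and charged repeats repel
through a screened Coulomb term (`kc = 50`, spacing 8, screening length 8,
model units). Integration is BAOAB Langevin (friction 1, `dt = 0.005`,
enforced stable against the stiffest site) with Gaussian kicks from a
dedicated generator keyed by the seed, so identical inputs give
bit-identical trajectories. Kelvin enters through a single scale that puts
`k_B T = 1` at 310.15 K.

One modelling choice deserves emphasis. In one dimension the screened
Coulomb pair term is *convex* in the separation, so by itself it stiffens
the chain — the opposite of the destabilization the charges are supposed
to carry. The destabilization is therefore modelled where it physically
lives, inside a repeat: a dense like-charge cluster lowers the effective
on-site stiffness, `k_i = k_intra (1 − softness · q_i²)` with
`softness = 0.04`, clamped at `0.2 k_intra`. The default preset places the
acidic charges on repeats 3–6 (`0, 0, −2, −3, −2, −1, 0`), mirroring the
hairpin clusters of repeats 3–4, the a2 cluster of repeat 4 and the tail
of the acidic surface. With this construction the qualitative orderings
are near-deterministic under matched seeds: fluctuation grows with
temperature, the charged chain out-fluctuates its discharged copy, and
reducing the repeat-4 charge (the D→N-style substitution) dampens its
RMSF. Absolute RMSF values are model units and are never compared with
all-atom magnitudes. Chains start at their relaxed (zero-force)
configuration, so a zero-temperature run stays put, and RMSF is measured
about each site's own trajectory mean.

Parameters were chosen once to realise these orderings comfortably —
thermal displacement ~0.1 length units against a softening scale that a
3-unit charge reaches — and are exposed, not tuned per run.

## Hydrogen-bond criteria

The published interface counts (8 bonds ANK↔MAML-1, 5 of them through
GLU-2008/ASP-1972, 2 between ASP-1994 and GLN-347 of RBPJ) come without
stated criteria. The detector uses standard geometry: donor–acceptor
heavy-atom distance ≤ 3.5 Å and, when the structure has no hydrogens, an
antecedent–donor–acceptor angle ≥ 120°; with explicit hydrogens the
donor–H···acceptor angle takes over. Donor/acceptor atom sets are
table-driven per residue type, with a nearest-heavy-atom antecedent
fallback for minimal synthetic residues; bifurcated bonds count
individually. Both criteria are exposed, and the planted-complex
generator guarantees exact recovery (precision = recall = 1) on synthetic
complexes. The check against the real DNA-bound complex requires the PDB
entry as a local file; without it the corresponding acceptance test fails
by design rather than being skipped or replaced by a synthetic stand-in.

## Assay arithmetic

The Pfaffl ratio is `eff_tar^Δct_tar / eff_ref^Δct_ref` with Δct in the
(control − test) convention. Amplification efficiency is the antilog of
the log₁₀-fluorescence slope over the best window of linearity: all
5-point windows with positive fluorescence are fit, the best coefficient
of determination wins, ties go to the earliest cycles, and exactly flat
windows (baseline/plateau) are excluded as non-exponential. On noiseless
curves recovery is exact; at 1% multiplicative noise the estimate stays
within ±0.02 over 100 seeded replicates.

Beacon hairpin melting uses unified DNA nearest-neighbor parameters
(1 M NaCl reference) over the self-complementary stem, a terminal-AT
penalty, a purely entropic hairpin-loop term (Jacobson–Stockmayer
extrapolated beyond 9 nt) and an entropic salt correction, with the
two-state unimolecular `Tm = ΔH/ΔS`. The packaged 4-bp and 5-bp beacon
designs compute to ~35 °C and ~56 °C against design temperatures of 36 °C
and 50 °C: the 4-bp design lands within a degree, the 5-bp design runs
~6 °C high — buffer and measurement criterion for the design values are
unknown, so only the ordering (5-bp melts above 4-bp) is asserted.

## Synthetic data: what it does and does not show

The generators produce idealized repeat structures (ideal helices with
1.5 Å rise and 100° turn, an out-and-back hairpin, minimal charged side
chains), multi-chain complexes whose hydrogen bonds are planted at exact
distances and angles, charge clusters separated by at least three Debye
lengths, and qPCR curves of known efficiency. Their planted truths double
as oracles: the analysis modules must recover them exactly in the
noiseless case. What passing these tests shows is that the *machinery* is
correct — segmentation, charge assignment, potential, patch connectivity,
bond geometry, window regression. What it cannot show is anything about
real structures: idealized geometry has no packing defects, no missing
side chains, no crystallographic artefacts, and planted complexes have no
near-miss polar contacts. Claims about the real Notch complex (the 8/5/2
bond counts, the >75% human–fly similarity) therefore remain tied to the
real inputs and fail visibly when those inputs are absent.

## Numerical and interface choices

- **PDB parsing** rides on `bio3d::read.pdb`; alternate locations keep the
  highest occupancy (ties to label order), waters/ions are dropped, HETATM
  amino acids (e.g. MSE) are kept and sequence-mapped to `X`, and author
  numbering is the only numbering exposed (insertion codes are identity
  suffixes, ignored for ordering). Alignment is
  `Biostrings::pairwiseAlignment` (global, BLOSUM62, gap open 10 / extend
  1); "similarity" is the fraction of non-terminal-gap columns with a
  positive substitution score, since the original similarity measure is
  undefined. An independent brute-force enumeration oracle checks the
  aligner on short sequences.
- **Segmentation** scores a packaged consensus-derived PWM (log-odds,
  pseudocount 0.5, uniform background) at every offset and selects the
  maximal-scoring non-overlapping placement by dynamic programming,
  leftmost on ties; `n_expected` switches to a cardinality-constrained
  variant. The sequence-only element template is positions 5–12 (a1),
  15–24 (a2), 25–31 (hairpin); a structure overrides it via CA-geometry
  helix detection.
- **Enrichment** uses `log2((f_t + p)/(f_r + p))` with pseudocount 0.01 so
  absent residues stay finite.
- **Problem sizes.** The test suite and the analysis scripts run the
  oscillator at 10 seeds × 1–2×10⁵ steps (plus single 10⁶-step
  equipartition runs), surfaces at 240 dots per atom, and 100 qPCR
  replicates; these sizes hold every ordering with margin while keeping
  the whole suite around half a minute.

## Known limitations

- The disorder scorer shares only the energy-inversion idea with published
  predictors; its absolute scores are not comparable to published curves.
- Debye–Hückel screening has no low-dielectric protein interior, so
  absolute potentials and patch areas differ from Poisson–Boltzmann
  results; only zone membership and sign structure are robust.
- The oscillator chain is a one-dimensional caricature: it encodes the
  charge-destabilization hypothesis rather than testing it, and its
  temperature dependence is essentially `sqrt(T)` plus anharmonic
  corrections.
- Hairpin Tm values inherit the uncertainty of loop parameters for long
  loops and of the unknown measurement buffer.
- The cross-species similarity and ternary-complex bond counts require
  real sequences and structures that must be supplied as local files.
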