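---
title: "Methods: modeling and analyzing Ca2+/phosphate co-transport by a CAX antiporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and analyzing Ca2+/phosphate co-transport by a CAX antiporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capiflux)
```

## Scientific setting

H^+^/Ca^2+^ antiporters of the CAX family export cytosolic Ca^2+^ powered by
the inward H^+^ gradient. The bacterial homolog studied here has two
transport modes: a low-flux H^+^/Ca^2+^ exchange mode and a high-flux mode in
which Ca^2+^ and mono-anionic inorganic phosphate (H~2~PO~4~^−^) are
co-transported 1:1 in exchange for H^+^. capiflux implements the
computational side of such a study as reusable, tested components: a
geometric survey for shared Ca^2+^/P~i~ sites in deposited structures,
restraint-based ensemble modeling of the binding site, free-energy
bookkeeping for side-chain protonation, and the quantitative analysis of the
functional assays (transport kinetics, coupling stoichiometry, calorimetry,
LRET, phosphate speciation). Synthetic-data generators with known ground
truth stand in for the raw measurements, so the whole pipeline runs and is
testable offline.

## What the synthetic generators emulate — and what they do not

Every generator produces data at the conditions the study reports, with an
error model matched to the instrument class:

* **Initial transport rates** follow v = V~max~·S/(K~M~+S) with
  *multiplicative* Gaussian noise (default CV 5%, triplicates), as
  scintillation-counting errors scale with the signal. Generating parameter
  pairs used throughout are the reported ones: K~M~ = 69 µM, V~max~ = 4.2
  µmol/min/g without P~i~; 198.7 µM and 33.3 with 5 mM P~i~; K~M~ = 4.9 mM,
  V~max~ = 0.097 for P~i~ transport.
* **Uptake time courses** are saturating curves A(1−e^−t/t0^) in five modes
  (co-transport, low-flux, empty-vesicle control, protonophore-collapsed,
  Ca^2+^-free/EDTA). The study never states raw uptake amplitudes, so the
  amplitude is a free parameter set once (the Michaelis–Menten rate times the
  saturation time constant, default t0 = 10 min). In co-transport mode the
  P~i~ leg is exactly `coupling_ratio` times the Ca^2+^ leg before noise.
* **ITC isotherms** follow the single-site (Wiseman) model with explicit
  per-injection dilution bookkeeping and *additive* heat noise, default
  0.01 µcal — the baseline noise level of power-compensation instruments of
  the VP-ITC class used for such titrations (25 × 10 µl injections into a
  1.4166 ml cell).
* **Luminescence decays** are single exponentials on a grid spanning five
  lifetimes with 1% multiplicative noise.
* **FEP samples** are per-window Gaussian energy differences in kT. For a
  Gaussian work distribution the exponential average has the closed form
  ΔG~w~ = µ~w~ − σ~w~²/2, so every dataset carries an exact ground truth;
  the reverse-direction dataset negates it. This validates the estimator
  chain, not any force field.

What passing tests on these data demonstrate is therefore *estimator
correctness and pipeline integrity*: unbiased recovery of known parameters at
realistic noise, correct unit bookkeeping, correct thermodynamic-cycle signs.
They do not demonstrate anything about membrane energetics, vesicle leakage,
instrument drift, or baseline artifacts, none of which are simulated.

## The survey engine

A structure passes when (i) its recorded resolution is ≤ 3.0 Å, (ii) it has
a Ca^2+^ and a phosphate entity whose minimum inter-atomic distance
(calcium atom to any phosphate non-hydrogen atom — the closest-approach
reading of "minimum distance between the two ions") is ≤ 3.2 Å, (iii) the
site is flanked by at least two acidic side chains and one histidine, and
(iv) its best chain identity to every previously accepted structure is
< 70%. Choices the criteria leave open, fixed here and configurable:

* flanking is measured from side-chain functional atoms (carboxylate O,
  imidazole N, ...) to either ion, cutoff 4.5 Å;
* phosphate het codes default to {PO4, 2HP, PI, H2P};
* redundancy is greedy in ascending-resolution then lexicographic order, so
  the output is order-invariant and reproducible;
* identity uses global alignment with match +1 / mismatch 0, gap open −5 /
  extend −1, and the identity denominator excludes terminal gap columns. The
  70% criterion is coarse, so the exact scoring scheme is immaterial; it just
  has to be fixed and documented.

Running against the full archive of deposited structures is a documented
external-data mode; the shipped drivers run on planted fixtures whose truth
labels make the engine's accuracy a testable quantity.

## The restraint ledger and sampler

The binding-site model encodes ten geometric restraints on a fixed scaffold:
four flat-bottom upper-distance terms (2.6 Å, σ 0.1 Å) from Ca^2+^ to the
E72/E255 carboxylate oxygens; the same form to the nearest phosphate oxygen,
the G68 backbone carbonyl and the N69 side-chain carbonyl (together implying
a Ca^2+^ coordination number of exactly 7); five target distances holding
the phosphate against H256 (P–Nδ1 3.9 Å), N252 (P–Cγ 4.5 Å) and S278
(P–Oγ 4.5 Å — serine has no Cγ, so the hydroxyl oxygen is the ledger's
reading of that landmark) plus the N69–Q281 (3.2 Å) and N99–N252 (4.2 Å)
polar contacts; and two planarity dihedrals (Ca–Cδ–Oε1–Oε2, 0° ± 20°)
imposing bidentate carboxylate coordination. Only the first four are stated
as flat-bottom; the fixed distances of the others read as targets, so they
are implemented as two-sided harmonics with the same σ (configurable).

The sampler replaces a full modeling engine with the minimal machinery the
problem needs: degrees of freedom are the side-chain χ torsions of the nine
site residues plus the Ca^2+^ position and a rigid-body phosphate move;
backbone atoms never move. Each model is an independently seeded restart:
perturb the scaffold configuration (torsions ±25°, ions σ ≈ 0.05 Å),
anneal against the restraint pseudo-energy (geometric cooling from T = 10 to
0.01 score units over 200 Metropolis steps), then polish with a bounded
quasi-Newton minimization. A restart is accepted when **every** scalar term
deviates by ≤ 3σ — the package's operational definition of a satisfying
model. Ion proposal scales are about half the restraint σ: inside the
flat-bottom region the pseudo-energy is exactly zero, so larger proposals
would let the cation random-walk across the penalty-free basin and the
ensemble would be diffuse for no physical reason; half-σ proposals keep
accepted models concentrated where the restraints place them. Because some
directions (distal χ angles of N99, the H256 ring spin, the phosphate spin
about its anchored oxygen) are unconstrained, the ensemble retains genuine
spread there — which is exactly what the occupancy contours visualize.

The scaffold itself is an idealized construction: standard bond lengths,
the nine residues radiating from seed ion positions placed so every
restraint is satisfiable at zero violation. No fidelity to any deposited
backbone is claimed; the scaffold exists so that modeling, clustering and
contouring are exercised end-to-end without downloads.

## Clustering and occupancy

RMSD uses all non-hydrogen atoms of the eight side-chain residues plus both
ions, with **no superposition** — all models share the frozen backbone
frame, so direct coordinate RMSD is well-defined and cheaper than fitted
RMSD. Clustering is leader-style in model-index order with the founder as
representative (threshold 0.6 Å): deterministic, order-stable, and its
invariants (member-within-threshold of the representative, population
conservation) are assertable post-conditions. The reported cluster fractions
of the original 2000-model study depended on the replaced modeling engine
and are deliberately not targets here.

Occupancy grids count, per 0.5 Å voxel, the fraction of models with at
least one selected atom within a capture radius of the voxel center
(default 1.0 Å, of the order of an ionic/united-atom radius — the
convention of standard volumetric-occupancy tools); "contour at 85%" means
voxels with value ≥ 0.85. A pure atom-center binning (`radius = 0`, also
supported) was rejected as the default after it proved to be a grid
artifact: the cation's accepted positions scatter over a few tenths of an
Ångström inside the flat-bottom feasible region, so with point atoms and
0.5 Å voxels no voxel reaches 85% even for an ensemble any structural judge
would call consistent. Giving atoms their physical footprint makes the
contour report the ensemble, not the grid. The grid is additionally
anchored so the selection centroid falls on a voxel center. Grids serialize
to OpenDX for standard molecular viewers.

## Protonation free-energy bookkeeping

Estimators work internally in kT and convert to kcal/mol only at reporting
(R = 1.98720×10⁻³ kcal mol⁻¹ K⁻¹, default 298 K). The per-window estimator
is exponential averaging, −ln⟨e^−ΔU^⟩, under a hard log-sum-exp contract
(no overflow for |ΔU| ≤ 700 kT); Bennett's acceptance ratio is available
behind a flag as the lower-variance alternative, the default staying with
exponential averaging for fidelity to the original protocol. Each window
discards its leading fraction of samples as equilibration (the 200-of-1000
and 40-of-240 patterns both map to `discard_equilibration`). Path totals are
computed per direction, the reverse leg sign-flipped onto the forward
convention, and the two combined as mean ± half-difference. The
protein-minus-solution cycle gives ΔΔG, whose sign convention is pinned
once: negative means protonation is favored in the protein, an upshifted
apparent pK~a~, with shift = −ΔΔG/(RT ln 10) ≈ 1 pH unit per −1.364
kcal/mol at 298 K. The published per-residue ΔΔG values require all-atom
membrane-protein simulation and ship only as an annotated reference table
(`protonation_reference()`); nothing in the package asserts them.

## Assay fitting choices

* **Michaelis–Menten** fits run on log-parameterized (K~M~, V~max~) so
  positivity is structural, with data-driven starts (V~max~ = max rate,
  K~M~ = concentration nearest half-max). Convergence flags are honest; a
  degenerate all-zero dataset is flagged, never "fitted".
* **Stoichiometry** is the through-origin OLS slope Σxy/Σx² of P~i~ on
  Ca^2+^ rates at matched time points (rates = uptake/time), with a seeded
  1000-resample bootstrap CI. Through-origin is the model the biology
  dictates: zero Ca^2+^ flux implies zero coupled P~i~ flux.
* **ITC** fits the one-site isotherm with dilution bookkeeping; dilution
  heat is absorbed into a fitted constant offset since raw background
  titrations are not simulated. For low-c titrations (the P~i~ isotherm has
  c ≈ 0.01) the stoichiometry parameter is not identifiable and is fixed at
  1, the standard practice; the Wiseman c-value is computed and flagged
  outside [0.01, 10⁴].
* **LRET** lifetimes come from single-exponential fits; distances from
  R = R₀·[τ~DA~/(τ~D~−τ~DA~)]^1/6^. R₀ of the probe pair is a required user
  input — it is a property of the dyes, never stated in the study.
* **Speciation** uses the two-species Henderson–Hasselbalch form with
  pK~a~ 7.2 for H~2~PO~4~^−^/HPO~4~^2−^; the pH-profile peak is a discrete
  argmax with tie and boundary flags, because the measured profile is a
  discrete series and interpolation would manufacture precision.

One recorded inconsistency: the study's discussion quotes an apparent
Ca^2+^ K~M~ of 0.15 mM while the kinetics figures report 69 µM (−P~i~) and
198.7 µM (+P~i~); this package works with the figure-level values.

## Problem sizes and numerical details

The shipped drivers use ensembles of 60 models and FEP datasets of 40
windows × 1000 samples × 2 directions, sizes at which every stage's
statistical behavior is already visible; all are parameters, and the test
suite exercises the same code at smaller sizes with fixed seeds. All
generators are bit-reproducible given a seed, restored afterwards so library
code never perturbs the caller's RNG stream. Degenerate inputs
(zero-tolerance acceptance, flat decays, saturating-impossible titrations,
windows emptied by the equilibration discard) error or flag explicitly.

## Known limitations

The scaffold is idealized, so ensemble statistics (cluster counts, exact
occupancy volumes) characterize the sampler and restraints, not the real
protein. The sampler has no sterics beyond what the restraints imply.
Transport simulation has no membrane voltage, vesicle leakage, or H^+^-pump
kinetics, and the antiport H^+^ stoichiometry (possibly 1 Ca^2+^ : 2 H^+^)
is annotation, not a fitted model. The survey's outcome on the live
structure archive depends on the archive version; only the engine, not any
particular hit list, is the tested artifact.
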