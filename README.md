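# capiflux

Analysis toolkit for **coupled Ca²⁺/inorganic-phosphate (Pᵢ) transport by
CAX-family H⁺/Ca²⁺ antiporters**. These membrane transporters normally export
cytosolic Ca²⁺ in a low-flux H⁺ exchange mode; when cytosolic Pᵢ is abundant
they can switch to a high-flux mode that co-transports Ca²⁺ and mono-anionic
phosphate 1:1. Characterizing that switch requires a heterogeneous set of
computations — structure screening, restraint-based modeling, free-energy
bookkeeping, and quantitative assay fits — and this package implements all of
them as tested, reusable R functions, with synthetic-data generators (known
ground truth) standing in for raw measurements so everything runs offline.

**Who it is for:** membrane-transporter groups analyzing transport kinetics,
ITC, or LRET data; modelers building restraint-based binding-site ensembles;
anyone needing clean reference implementations of the estimators below.

## What's inside

| Stage | Core model / statistic | Entry points |
|---|---|---|
| Structure survey | shared Ca²⁺/Pᵢ site: min ion distance ≤ 3.2 Å, resolution ≤ 3.0 Å, 2 acidic + 1 His flanking, <70% redundancy | `run_survey()`, `find_co_bound_sites()`, `pairwise_identity()` |
| Binding-site modeling | ten-restraint ledger (flat-bottom 2.6 Å Ca²⁺ coordination, phosphate target distances, carboxylate planarity dihedrals); annealing sampler over side-chain χ + rigid ions | `build_scaffold()`, `build_default_restraints()`, `sample_ensemble()`, `coordination_count()` |
| Ensemble analysis | no-superposition RMSD leader clustering (0.6 Å); binary-voxel occupancy maps, 85% contour | `cluster_ensemble()`, `occupancy_map()`, `write_dx()` |
| Protonation energetics | per-window exponential averaging (BAR optional), bidirectional mean ± half-difference, protein−solution cycle, shift = −ΔΔG/(RT ln 10) | `total_free_energy()`, `combine_bidirectional()`, `protonation_ddg()`, `ddg_to_pka_shift()` |
| Assay analysis | Michaelis–Menten v = V·S/(K+S); through-origin stoichiometry slope Σxy/Σx²; one-site Wiseman ITC isotherm; Förster R = R₀[τ_DA/(τ_D−τ_DA)]^{1/6}; Henderson–Hasselbalch speciation | `fit_michaelis_menten()`, `estimate_stoichiometry()`, `fit_itc_one_site()`, `fit_lifetime()`, `forster_distance()`, `phosphate_speciation()` |
| Synthetic data | every input above, with seeded noise and known truth | `gen_initial_rates()`, `gen_transport_timecourse()`, `gen_itc_isotherm()`, `gen_lret_decay()`, `gen_fep_samples()`, `plant_survey_fixtures()` |

## Worked example

Generate a triplicate Ca²⁺ initial-rate dataset at the reported kinetic
parameters (K_M = 69 µM, V_max = 4.2 µmol/min/g, 5% CV noise), refit it, and
fit a synthetic Ca²⁺ ITC titration (K_d = 0.46 µM into 5 µM protein):

```r
library(capiflux)

rates <- gen_initial_rates(km = 69, vmax = 4.2,
                           conc_grid = c(10, 25, 50, 100, 200, 400, 700, 1000),
                           noise_cv = 0.05, n_rep = 3, seed = 1)
fit <- fit_michaelis_menten(rates)
print(fit)
#> kinetic_fit: Km = 64.22 (SE 4.3), Vmax = 4.147 (SE 0.069), n = 24

itc <- gen_itc_isotherm(kd = 0.46, delta_h = -5, n_sites = 1,
                        cell_conc = 5, syringe_conc = 75,
                        conc_scale = 1e-6, seed = 5)
print(fit_itc_one_site(itc))
#> binding_fit: Kd = 0.4707 (SE 0.0084), dH = -5.02 kcal/mol, n = 1, c = 10.6

ddg_to_pka_shift(-11.5)   # a strongly protonation-favoring site
#> +8.4 pH units
```

The fitted Km (64.2 µM, 95% CI 55.9–73.8) recovers the generating 69 µM
within its confidence interval; the ITC fit recovers the dissociation
constant within 3%; the last line converts a protonation free-energy shift
of −11.5 kcal/mol into its apparent-pKₐ upshift of +8.4 pH units
(−1.364 kcal/mol per unit at 298 K).

## Analysis workflow

The `analysis/` scripts run the four stages end to end and write their
tables under `results/`:

```sh
Rscript analysis/01_survey.R              # fixture survey + TSV/JSON report
Rscript analysis/02_binding_site_model.R  # 60-model ensemble, clusters, occupancy maps
Rscript analysis/03_protonation.R         # FEP estimator chain demo + reference table
Rscript analysis/04_assays.R              # kinetics, stoichiometry, ITC, LRET, speciation
```

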