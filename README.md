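# crossbridge

Analysis machinery for studying how myosin handles its nucleotide during the
cross-bridge cycle. The package grew out of the multi-scale workflow used to
characterize hypertrophic-cardiomyopathy myosin variants such as G256E, where
the same question — *is ADP release slowed?* — is asked of molecular-dynamics
trajectories, steered-pulling simulations, stopped-flow biochemistry and
single-myofibril mechanics. `crossbridge` implements the analysis layer of
that workflow in R, together with synthetic-data generators with known ground
truth, so every estimator can be validated end to end without external data.

It is intended for structural biophysicists and muscle physiologists who need
reproducible, oracle-tested implementations of:

* **Trajectory descriptors** — Kabsch-superposed RMSD/RMSF, residue–residue
  contact fractions (5 Å heavy-atom criterion), salt-bridge persistence,
  ligand torsion series, 2-D dihedral maps (5°×5° bins) with conformational
  entropy S = −R Σ pᵢ ln pᵢ and percent coverage, per-residue linear
  interaction energies (Coulomb + Lennard-Jones), centre-of-mass reaction
  coordinates, modal distances, seed-frame selection and occupancy grids.
* **Nonequilibrium work analysis** — an overdamped-Langevin steered-pulling
  generator on analytic 1-D surfaces, work resampling onto a common reaction
  coordinate, mean-work comparisons (Welch t-test), and free-energy profiles
  via the Jarzynski equality ΔF(λ) = −kT ln⟨exp(−W(λ)/kT)⟩ evaluated with a
  log-sum-exp reduction, plus contact-release timelines filtered at 90%
  replicate presence.
* **Stopped-flow kinetics** — single/double-exponential transient fits with
  multi-start initialization, and the apparent ADP affinity from competitive
  inhibition of ATP-induced actomyosin dissociation,
  k_rel = 1/(1 + [ADP]/K_ADP).
* **Myofibril mechanics** — decomposition of force traces into activation
  kinetics (k_ACT), steady-state force, and the biphasic relaxation: a linear
  slow phase (slope k_REL,slow, duration t_REL,slow) followed by exponential
  fast relaxation (k_REL,fast), located by an exhaustive change-point scan;
  group comparisons by type-II two-way ANOVA with pairwise contrasts.

## Worked example

Generate a synthetic ADP titration (seven concentrations, 0–640 µM, 1 %
noise), fit every trace, and recover the affinity:

```r
library(crossbridge)

spec   <- stopped_flow_spec(K_ADP_true = 46.46, noise_sd = 0.007, seed = 42)
traces <- generate_stopped_flow_traces(spec)
curve  <- fit_adp_titration(traces)
round(as.data.frame(curve), 4)
#>   adp   krel
#> 1   0 1.0000
#> 2  20 0.7138
#> 3  40 0.5419
#> 4  80 0.3688
#> 5 160 0.2295
#> 6 320 0.1241
#> 7 640 0.0665
fit_kadp(curve)
#> kadp_fit: K_ADP = 47.58 +/- 0.52 uM
```

The fast-phase rate halves at [ADP] = K_ADP by construction, and the fitted
47.6 µM recovers the 46.46 µM ground truth to ~2 % from a single noisy
titration.

A steered-pulling ensemble on a harmonic surface (κ = 0.5 kcal/mol/Å², pulled
4 Å at 1 Å/ns, 60 replicates) and its Jarzynski profile:

```r
ens  <- generate_pulling_ensemble(pulling_spec(
          pulling_potential("harmonic", k = 0.5),
          end_position = 4, pull_speed = 1, n_replicates = 60, seed = 42))
jarzynski_profile(ens)
#> free_energy_profile (jarzynski, n = 60): dF(end) = 3.876 kcal/mol,
#>   <W>(end) = 4.075 kcal/mol
ens$dF_analytic
#> [1] 4
```

The mean work exceeds the analytic free-energy difference (second law) while
the Jarzynski average lands within 0.2 kcal/mol of it. Finally, a myofibril
force trace built with k_REL,slow = 0.5 /s, t_REL,slow = 0.2 s and
k_REL,fast = 8 /s is inverted by the change-point decomposition:

```r
tr <- generate_force_trace(force_trace_spec(noise_sd = 1, seed = 42))
decompose_relaxation(tr)
#> relaxation_decomposition: k_slow = 0.525 /s over 0.2 s, k_fast = 8.007 /s
steady_state_force(tr)
#> [1] 100
```

`run_pipeline(demo_run_config())` chains all five stages (synthetic data,
trajectory descriptors, pulling analysis, kinetics, mechanics) and writes
per-stage TSV/JSON plus a manifest with seeds and file hashes; reruns with
the same seed are byte-identical.

## Package layout

* `R/` — implementation (trajectory containers and descriptors, dihedral
  maps, energetics, pulling synthesis + analysis, kinetics, mechanics,
  pipeline orchestration); `src/` holds the Rcpp Langevin integrator.
* `tests/testthat/` — unit, property and end-to-end tests, with brute-force
  oracles in `helper-oracles.R`.
* `vignettes/crossbridge-methods.Rmd` — the methods vignette: models,
  parameter choices, numerical decisions and limitations.
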