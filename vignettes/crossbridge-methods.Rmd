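---
title: "Methods behind crossbridge: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind crossbridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbridge)
```

`crossbridge` implements four analysis families that interrogate the same
physiological question — the kinetics of ADP handling by actomyosin — at
four scales: molecular-dynamics trajectory descriptors, steered-pulling
free-energy analysis, stopped-flow transient kinetics, and myofibril force
mechanics. This vignette records the models, the tunable parameters with
their defaults and units, the numerical decisions taken where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate. No empirical numbers are stated here beyond what the package's own
tests and scripts compute.

## Trajectory descriptors

**Containers.** An `md_trajectory` holds an `n_frames x n_atoms x 3` array
of coordinates (Å) plus a per-atom topology (name, element, residue id,
heavy-atom flag, mass, optional partial charge and Lennard-Jones σ/ε).
Topologies can be read from PDB (`read_pdb_topology()`, via bio3d), frames
from DCD or portable long-format TSV. Inputs are assumed imaged; periodic
boundary handling is out of scope.

**Superposition.** RMSD and RMSF use an unweighted Kabsch superposition
(SVD of the cross-covariance, with a determinant correction to exclude
reflections). RMSF is two-pass: frames are aligned to the raw mean
structure, the mean is recomputed, frames re-aligned, and the per-atom RMS
deviation from the final mean reported. `rmsf()` accepts a separate
`align_selection` so fluctuations of a mobile group can be measured in the
frame of a rigid core.

**Contacts.** Two residues are in contact in a frame iff at least one pair
of heavy atoms lies within 5 Å (the standard criterion; the cutoff is a
parameter). Salt-bridge persistence uses a stricter 4.0 Å cutoff between
side-chain N/O atoms carrying nonzero, opposite partial charges; 4.0 Å is
the usual structural-biology convention for charged-group bridges, adopted
here as the package's own decision since none is dictated by the contact
definition itself.

**Dihedral maps, entropy, coverage.** Torsions are the standard signed
dihedral, reported in degrees on (−180, 180]; collinear triplets give `NA`.
Joint maps bin two torsion series on [−180, 180)² with half-open 5° bins
(72 × 72 = 5184 bins by default; any width dividing 360 works). The
conformational entropy is the Gibbs entropy of the joint histogram,
S = −R Σ pᵢ ln pᵢ with R = 1.987 cal mol⁻¹ K⁻¹ and 0·ln 0 ≡ 0, which is
0 for a ligand locked in one bin and R ln N for a uniform map. Coverage is
the percentage of bins visited at least once — the simplest reading of "%
of the map sampled"; no density threshold is applied. Entropies of real
nucleotide ensembles depend on the estimator and binning, so values from
other software are comparable only qualitatively.

**Interaction energies.** The linear interaction energy of a residue with a
ligand group is the frame-averaged sum of pairwise vacuum Coulomb terms
(332.0636·qᵢqⱼ/r kcal/mol) and Lennard-Jones terms (Lorentz–Berthelot
combining). The pair cutoff is exposed (`Inf` by default for toy systems;
10 Å mirrors a production nonbonded cutoff) because published analyses vary
on this point. Pocket residues are selected where |mean combined energy|
≥ 3 kT with either of the ligand groups; kT is evaluated at 310 K, the
physiological simulation temperature (kT ≈ 0.616 kcal/mol, so the default
threshold is ≈ 1.85 kcal/mol).

**Reaction coordinate utilities.** The pulling coordinate is the
mass-weighted centre-of-mass distance between ligand and pocket. The modal
distance uses 0.1 Å histogram bins *centred* on multiples of the bin width,
so a series constant at 3.6 Å reports 3.6 exactly; ties resolve to the
smaller distance. Seed structures for steered runs are frames whose
coordinate lies within 0.1 Å of the target; when more qualify than the
per-replicate quota (20), they are taken evenly spaced across the
qualifying set — a choice made to avoid temporal clustering, since nothing
in the physics prefers one subset. Occupancy grids count atom visits in
0.5 Å voxels and store the conventional rendering iso-level, mean + 2 SD
over nonzero voxels.

## Steered pulling and Jarzynski analysis

**Toy model.** The generator integrates an overdamped Langevin particle on
a 1-D energy surface U(q) (flat, harmonic, double-well or tabulated),
coupled to a harmonic guide of stiffness κ_s whose centre moves at constant
speed v from λ₀ to λ_end:

ζ dq = −[U′(q) + κ_s (q − λ(t))] dt + √(2 ζ kT) dW.

The external work is accumulated as the guide-work integral
W(t) = Σ κ_s (λ − q) v Δt, the definition appropriate to the stiff-spring
regime; engine-internal work definitions of production MD codes are not
reproduced. The recorded ground truth is the stiff-spring limit
ΔF = U(λ_end) − U(λ₀); `stiff_spring_profile()` additionally provides the
exact finite-κ_s profile by quadrature as an independent oracle.

**Parameters and units.** κ_s defaults to 100 kcal/mol/Å², stiff enough
that the guide-work profile approximates the free energy along λ. The drag
coefficient ζ (field `friction`) is in kcal mol⁻¹ ps Å⁻², default 50 —
chosen so that pulls at ~1 Å/ns dissipate a clearly measurable but not
overwhelming few tenths of kcal/mol over a few Å, the regime in which the
estimator comparisons are informative. The Euler–Maruyama timestep defaults
to 0.02 ps; together with the default stiffness this puts the step–rate
product Δt(κ_s + max U″)/ζ ≈ 0.04, two orders below the stability boundary
of 2 at which the scheme is rejected with a diagnostic. (A femtosecond-class
step would integrate the same dynamics ~20× more finely without changing
any reported distribution materially; 0.02 ps keeps a 60-replicate,
multi-speed study of the toy system interactive.) A guide too soft to track
the pull — mean lag above 3 thermal widths √(kT/κ_s) over the final stretch
— triggers a warning rather than an error, since the run is still
well-defined, just not interpretable in stiff-spring terms. Replicates are
equilibrated at λ₀ for 10 ps before pulling.

**Estimators.** Work curves are linearly resampled onto a common λ grid
(default 0.1 Å, matching the seed-selection tolerance scale) and anchored
to W(λ₀) = 0; the grid endpoint is constructed to survive floating-point
jitter so the final-λ work is never silently truncated. The Jarzynski
profile −kT ln⟨e^(−W/kT)⟩ is computed with a log-sum-exp reduction; by
Jensen's inequality it lies at or below the mean work pointwise, which is
asserted in tests. A single replicate degenerates to ΔF = W with a warning.
Mean works are compared with a two-sided Welch t-test on final-λ values —
the unequal-variance form is the conservative default when nothing is known
about variance homogeneity. The "representative trajectory" is
operationalized as the replicate minimizing the L2 distance between its
work curve and the profile: unlike any averaged curve, it corresponds to an
actual structure series that can be displayed. Contact timelines across
replicates retain a contact if it appears at least once in ≥ 90 % of
replicates and report per-time presence probabilities.

**Problem sizes.** The packaged studies use 60 replicates, pulls of a few
Å, and speed ladders such as {10, 1, 0.1} Å/ns — sizes chosen so the full
property suite (validity of the estimator at slow pulling, monotone
dissipation with speed, second-law bounds) completes in seconds while
leaving sampling error well below the effects being asserted.

## Stopped-flow kinetics

**Forward model.** Fluorescence transients follow
A_f e^(−k_f t) + A_s e^(−k_s t) + C + ε with i.i.d. Gaussian ε. Competitive
inhibition slows the fast phase as k_f = k₀ / (1 + [ADP]/K_ADP); at
[ADP] = 0 the slow amplitude is set to zero, matching the single-exponential
zero-ADP control condition. Defaults: the experimental concentration ladder
0, 20, 40, 80, 160, 320, 640 µM ADP against 25 µM ATP; k₀ = 100 /s (typical
of ATP-induced actomyosin dissociation at this ATP concentration);
k_s = 1.5 /s, low enough that the fast phase remains separable even at the
highest ADP where k_f has fallen more than tenfold; amplitudes 0.7/0.2 with
offset 0.1; 400 points over 2 s. "1 % noise" is operationalized as a noise
SD of 1 % of the fast-phase amplitude (0.007 signal units at the default
amplitude). A spec whose fast rate does not exceed the slow rate at maximal
ADP is rejected; a ratio under 3 is flagged in the trace metadata as
marginally separable.

**Fitting.** Exponential fits use Levenberg–Marquardt least squares with
multi-start initialization over log-spaced rates spanning roughly four
decades (plus a log-linear estimate from the early decay), keeping the
lowest-residual converged fit; two-exponential fits are notoriously
initialization-sensitive and this removes the dependence on a lucky start.
Phases are ordered so "fast" is the larger fitted rate. Least squares is
unweighted — no error model beyond additive noise is assumed. The binding
curve k_rel = k_obs/k_obs,0 is fit with the one-parameter model
1/(1 + [ADP]/K_ADP); the curve passes through (0, 1) by construction rather
than via a free offset, so the normalization is a constraint, not a fitted
quantity, and the model predicts k_rel = 0.5 exactly at [ADP] = K_ADP. When
replicate titrations are supplied, the reported SE is the SD of
per-replicate estimates (the convention for n = 4 replicate experiments);
otherwise it comes from the fit curvature. Non-monotone curves beyond noise
raise a warning. `kadp_recovery_experiment()` packages the whole loop —
generate, fit traces, build the curve, fit K_ADP — with per-repeat seeds
derived from one base seed.

## Myofibril mechanics

**Forward model.** Force traces are piecewise: baseline; exponential rise
baseline + F_ss(1 − e^(−k_ACT (t − t_act))); plateau; from the relaxation
switch a linear slow phase of slope −k_REL,slow·F_ss lasting t_REL,slow;
then exponential decay to baseline at k_REL,fast. Defaults (F_ss = 100,
k_ACT = 4 /s, k_REL,slow = 0.5 /s, t_REL,slow = 0.2 s, k_REL,fast = 8 /s,
1 kHz sampling) sit in the range typical of demembranated cardiac
myofibrils at submaximal calcium. Spec invariants enforce
k_REL,slow·t_REL,slow < 1 (force stays positive through the linear phase)
and k_REL,fast > k_REL,slow. The ADP-challenge preset encodes the
qualitative effect of replacing half the nucleotide pool with ADP as
ground-truth parameter changes — both relaxation rates halved, slow-phase
duration doubled, activation slowed 30 %, force unchanged — deliberately as
phenomenology, not mechanistic chemistry. "2 % noise" means a noise SD of
2 % of F_ss.

**Decomposition.** All fit windows exclude 5 ms after each solution switch
(the dead time of fast switching systems). Steady-state force is the mean
over a 0.5 s pre-relaxation window minus the pre-activation baseline, so
uniform offsets cancel. The relaxation is decomposed by an exhaustive
change-point scan: candidate transitions on a grid (default every 5 ms)
from 10 ms to 1 s after the switch; per candidate the slow segment is fit
linearly (closed form) and the fast segment as B + A e^(−k(t−t_c)) by
variable projection (the linear pair solved exactly for each k, k optimized
on a log scale); the candidate minimizing the total squared residual wins.
Because the estimator *is* an exhaustive scan, it can be checked verbatim
against an independent scan, and on noiseless generator traces whose
transition falls on the grid the inversion is exact to machine precision.
If no interior change point beats the best single-segment fit the trace is
flagged monophasic. k_REL,slow is reported as |slope| divided by the force
at relaxation onset (above baseline), giving units of 1/s and invariance to
instrument rescaling; whether published slow-phase rates are
amplitude-normalized is often unstated, which affects absolute values but
not group contrasts.

**Group comparisons.** `compare_mechanics()` fits
response ~ genotype * solution and reports type-II sums-of-squares F tests
(via car) — the appropriate choice for the unbalanced group sizes typical
of myofibril studies (e.g. 15 vs 13 preparations) — plus Tukey-adjusted
pairwise contrasts via emmeans. Cells with fewer than two observations are
rejected. Null simulations at those group sizes keep the genotype type-I
error near the nominal 5 %, which the test suite checks.

## Synthetic data: what it does and does not emulate

The generators reproduce the *structure* of each data class — contact
schedules and torsion-state schedules realized exactly in toy bead
geometries, work ensembles with known free-energy differences,
double-exponential transients obeying competitive inhibition, piecewise
force traces with event markers — under additive i.i.d. Gaussian noise,
seeded and bit-reproducible. They do not emulate: force-field physics,
solvent, or load in the pulling toy (it validates estimators, not myosin);
photobleaching, mixing artefacts or instrument drift in stopped-flow
traces; sarcomere inhomogeneity, series compliance or calcium-solution
chemistry in force traces; correlated noise anywhere. Passing tests
therefore demonstrate correctness of the estimators under the stated
models, not robustness to every artefact of real instruments; conclusions
about real systems still require the usual experimental controls.

## Numerical conventions

Angles are degrees in (−180, 180] with half-open bin edges [−180, 180);
energies kcal/mol; entropies cal mol⁻¹ K⁻¹ (R = 1.987); distances Å; rates
1/s (pull speeds Å/ns); the Coulomb constant is 332.0636 kcal Å mol⁻¹ e⁻².
Ties break low (modal distance) or first (representative replicate).
Degenerate inputs fail loudly: empty selections, zero-mass groups,
non-separable phases, unstable integrator steps and contradictory contact
schedules are rejected with diagnostics rather than silently patched.
Every stochastic entry point takes an explicit integer seed, and
`run_pipeline()` records seeds, package version and output hashes in its
manifest so that reruns are verifiably byte-identical.
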