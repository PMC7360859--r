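---
title: "Methods: CDR3 loop ensembles, Markov-state models and interdomain orientations"
author: "tcrmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDR3 loop ensembles, Markov-state models and interdomain orientations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrmsm)
```

# Scope and model

`tcrmsm` implements the ensemble-and-kinetics protocol for TCR CDR3 loops:
dihedral featurization, a toy well-tempered metadynamics engine, RMSD seed
clustering, tICA, reversible Markov-state models with PCCA+ macrostates and
Chapman–Kolmogorov validation, and macrostate-conditioned Vα–Vβ
interdomain-angle statistics. It deliberately does **not** run all-atom MD:
the sampling engines (force fields, thermostats, solvation, equilibration)
are out of scope, and the package's biased-sampling component operates on
analytic potentials in collective-variable space so that the bias
mathematics can be tested exactly.

Units are fixed throughout: coordinates in Å, times in ns, energies in
kcal/mol, temperatures in K, angles in degrees externally (radians
internally), with all angles reported in (−180°, 180°].

# Structures, trajectories and selections

PDB input is parsed from fixed-column ATOM records; author residue
numbering is authoritative and no renumbering scheme (IMGT/Kabat) is
applied, because CDR definitions are supplied by the user as explicit
chain + residue-range selections. The first alternate location is kept and
insertion codes are treated as part of the residue key, which makes parsing
of real PDBs deterministic without a numbering library.

Trajectories live in a frame-major binary container with a one-line
self-describing ASCII header (atom count, frame count, frame interval,
float precision); multi-model PDB is accepted as a portable alternative
and the test suite asserts both paths decode the same ensemble. The
container was chosen over standard MD formats to keep the artifact
dependency-free.

# Dihedral featurization

ψ(i) is computed from N(i), CA(i), C(i), N(i+1) and φ(i) from C(i−1), N(i),
CA(i), C(i); terminal residues lacking a flanking residue contribute no
angle. The torsion uses the right-handed convention with cis = 0°; the sign
was frozen against an independent projection-formula oracle before the
main implementation (the quadruple (1,0,0), (0,0,0), (0,1,0), (0,1,1)
evaluates to −90°). Each dihedral enters the feature matrix as a
(sin, cos) pair, which removes the periodic discontinuity; the invariant
sin² + cos² = 1 is asserted to 10⁻⁹.

The metadynamics collective variable is s = Σᵢ aᵢ sin ψᵢ + Σᵢ bᵢ cos ψᵢ
over the ψ angles of both CDR3 loops. The coefficients of this linear
combination are not fixed by any published protocol we reimplement, so the
default is uniform weights aᵢ = bᵢ = 1, overridable in configuration; this
is a documented guess, not an inference.

The interdomain orientation is the torsion through four centers of mass,
in order: CDR loops of the α (light) chain, Vα domain, Vβ domain, CDR
loops of the β (heavy) chain. COMs are mass-weighted by default with an
unweighted option, since published descriptions of this metric do not
always state the convention. Whether "CDR loops" means all three loops per
chain or only CDR3 is likewise convention-dependent, so the operation
takes four explicit selections and the caller decides.

# Toy well-tempered metadynamics

Dynamics are overdamped Langevin in 1-D CV space with unit mobility:
ds = −∇(V + V_bias) dt + √(2 k_B T dt) η, k_B = 0.0019872041 kcal/(mol K),
T = 300 K by default. Every `deposition_stride` steps a Gaussian of height
w₀ exp(−V_bias(s)/((γ−1)k_BT)) is deposited; the free energy is recovered
as F(s) = −(γ/(γ−1)) V_bias(s), min-shifted to zero. Default bias
parameters follow the standard CDR-loop protocol — initial height
10 kcal/mol, deposition every 1000 steps, bias factor γ = 10 — and the
hill width, which that protocol does not pin down, defaults to 0.35 CV
units. Periodic CVs are supported through minimum-image distances in the
Gaussian argument.

The validation test bed is a quartic double well a·s⁴ − b·s² calibrated so
the barrier and minima positions are exact by construction. The study
conditions used by the tests and the acceptance script are: barrier
6 kcal/mol (≈ 10 k_BT at 300 K, deep enough that 2×10⁵ unbiased steps of
dt = 0.002 never cross), minima at ±1, hill height 0.5 kcal/mol (the
10 kcal/mol default scaled to this desk-scale system), width 0.25 (about a
quarter of the well separation), stride 500, γ = 10, 2×10⁵ steps. Under
these conditions the biased runs cross dozens of times, deposited hill
heights decay in revisited regions, and the reconstructed barrier lands
within 15% of the analytic value across seeds.

# Seed clustering and microstating

Frames are superposed by the Kabsch least-squares rotation (proper
rotations only); each frame is first superposed to the first frame, then
the pairwise matrix is computed with pairwise-optimal superposition — the
convention of the common trajectory-clustering tools — and average-linkage
agglomeration stops when the minimum average inter-cluster distance
exceeds the cutoff (default 1.2 Å). The agglomeration is delegated to
`stats::hclust(method = "average")` with `cutree(h = cutoff)`; a
brute-force O(n³) re-implementation in the test suite verifies the flat
clusters on 8-frame instances. Equal-height merge ties therefore follow
`hclust`'s internal order rather than a bespoke rule; on continuous RMSD
data exact ties have measure zero. Representatives are medoids (minimal
mean in-cluster distance, ties to the lower frame index). RMSD is computed
on backbone atoms (N, CA, C, O) of the configured selection.

k-means microstating is written in the package because the pipeline needs
kmeans++ initialization under a fixed seed, deterministic re-runs, an
explicit empty-cluster repair (re-seed at the point farthest from its
center) and a per-iteration assertion that the within-cluster sum of
squares never increases; `stats::kmeans` exposes none of these and serves
instead as an independent competitiveness check in the tests.

# tICA

Instantaneous (C₀) and lagged (C_τ) covariances are accumulated over all
trajectories with lagged pairs never spanning a trajectory boundary, and
C_τ is symmetrized — the reversible estimator, chosen to match common MSM
practice; its spectrum is real and lies in [−1, 1], and fitting
time-reversed data reproduces the eigenvalues to 10⁻¹⁰. The generalized
eigenproblem C_τ v = λ C₀ v is solved after adding a variance floor
(default 10⁻⁶) to C₀'s diagonal, because sin/cos pairs of low-variance
angles are nearly collinear. Two components are retained by default (the
landscapes of interest are 2-D); the count is configurable. Free-energy
surfaces use F = −k_B T ln ρ on a per-axis binned histogram, min-shifted,
with empty bins marked unsampled (NA) rather than given a number.

# Markov-state models

Counts are sliding-window at the chosen lag (10 ns by default, converted
to frames and rounded down with a logged message on mismatch). Estimation
restricts to the largest strongly connected component of the count graph
(heaviest by total counts, then larger, then lower indices). The
reversible maximum-likelihood transition matrix comes from the classic
self-consistent fixed-point iteration on the unnormalized flux matrix,
iterated to a relative tolerance of 10⁻¹⁰; row-stochasticity,
stationarity and detailed balance are asserted at 10⁻¹⁰/10⁻⁸/10⁻⁸ on
every estimate.

PCCA+ obtains fuzzy memberships from the simplex structure of the leading
π-orthonormalized right eigenvectors: spanning vertices are located with
the inner-simplex (index) algorithm, and the linear transform is made
feasible by the standard first-row fill, which guarantees memberships in
[0, 1] with unit row sums while preserving the vertex geometry. A further
trace-optimization refinement was considered and omitted: on the
metastable systems this package targets, the filled index solution already
recovers block structure exactly and hidden states at ≥95% purity, and the
fill is deterministic. Crisp assignment is the argmax membership with ties
to the lower macrostate id; macrostate stationary probabilities aggregate
π over the crisp assignment (fuzzy coarse-graining via membership-weighted
aggregation is the obvious alternative; crisp aggregation matches how
frames are counted in the downstream angle distributions). The number of
macrostates is a user input — the spectral-gap ratio at the chosen count
is logged as an advisory rather than enforced, since published macrostate
counts are typically chosen by inspecting the gap.

The Chapman–Kolmogorov test compares, for each crisp macro-set A, the
model-propagated stay probability w_Aᵀ[T(τ)]ᵏ 1_A against the same
quantity under a model re-estimated at lag kτ, for k = 1…5. Uncertainty
bands are the 2.5/97.5 percentiles of 100 bootstrap re-estimates —
resampling whole trajectories when several are available, contiguous
blocks of ~10 lags otherwise (published CK plots show bands but not their
recipe; the bootstrap is this package's choice). Multiples with
insufficient data are flagged, not dropped. Mean first-passage times solve
the standard linear system over non-target states, scaled by the lag, with
stationary weighting over the source set; both MFPTs and implied
timescales t = −τ/ln λ are provided as kinetics summaries, MFPT being the
default label for macrostate transition arrows.

# Angle statistics

Macrostate-conditioned interdomain-angle distributions use circular
mean and variance by default (reported in degrees and degrees², the
variance being the squared circular standard deviation √(−2 ln R)); the
angle distributions of interest are usually far from ±180° where circular
and linear statistics agree, and a linear mode is available for
comparability with conventions that ignore wraparound. Pairwise
macrostate comparisons use the two-sample Kolmogorov–Smirnov test
(`stats::ks.test`, asymptotic p-value with the effective sample size
n₁n₂/(n₁+n₂)); raw p-values are reported with a Bonferroni-adjusted
column alongside. KS treats frames as independent although MD frames are
autocorrelated; an optional thinning stride is provided and logged when
used. RMSF superposes frames to the subset-average structure in two
passes and reports the root-mean-square deviation of each residue's
backbone centroid.

# Synthetic ground truth

The generators define the study conditions for every statistical claim
the tests make.

* **Hidden-Markov dihedral trajectories**: a discrete-time hidden chain
  (geometric dwell times — the MSM assumptions are exactly satisfiable,
  which is the point) emits per-residue φ/ψ angles as state means plus
  iid Gaussian noise, realized as an idealized polyalanine-like backbone
  by NeRF chain extension (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
  standard angles, ω = 180°, side chains omitted — downstream features
  are dihedral-based, so this suffices). The construction is exact: the
  featurizer reads back the prescribed angles to machine precision.
* **Two-domain assemblies**: four 8-atom equal-mass clouds with exactly
  centered offsets place the four COMs so that the interdomain torsion
  equals the macrostate's target by construction (verified to 10⁻⁶ over
  a grid of targets before the rest of the build); per frame the β side
  is rotated about the Vα–Vβ axis and optional isotropic coordinate
  jitter adds angle noise. A coupled variant drives two backbone loops
  and the assembly torsion from the same hidden state — or decouples
  them, for null controls.
* **Double well**: quartic potential with analytic barrier and gradient.

What the generators do **not** emulate: force-field energetics, solvent,
sequence-specific geometry, semi-Markov dwell times, and the
frame-to-frame coordinate autocorrelation of real MD within a hidden
state (emissions are iid given the state). Passing tests therefore
demonstrate correctness of the estimators under their own assumptions and
well-separated metastability; they do not demonstrate robustness to
force-field error, poorly separated states, or featurization mismatch on
real trajectories.

Problem sizes were chosen once as desk-scale study conditions: the
end-to-end recovery experiments use 3 hidden states, 50,000 frames and
five seeds (recovering stationary probabilities within ±0.05 and the
slowest implied timescale within 25%); CK discrimination uses
30,000-frame chains; the KS null calibration uses 200 label permutations
of a 1000-frame series. The full test suite runs in about three minutes.

# Pipeline and reproducibility

`run_pipeline()` executes featurize → tICA → k-means → MSM → PCCA+ → CK →
angle distributions → KS table → RMSF from one validated configuration
(JSON-serializable; defaults: tICA lag 10 ns, 2 components, k = 150
microstates, MSM lag 10 ns, 300 K, cutoff 1.2 Å), writing every artifact
plus a manifest with an MD5 config hash. One master seed fans out
per-stage seeds through a deterministic counter, so re-runs are
byte-identical; any stage error aborts with the stage name and a partial
manifest. The package's exported functions and this configuration object
are the interface — the package is a library, not a shell tool.

# Known limitations

* PCCA+ uses the filled index method without subsequent simplex
  optimization; on systems with very weak spectral gaps the memberships
  may be suboptimal (the crisp assignments in all validation regimes are
  unaffected).
* CK bands from block bootstrap understate uncertainty when a single
  trajectory barely covers the largest lag multiple.
* The KS test's independence assumption is the user's responsibility;
  thinning is available but not automatic.
* The toy metadynamics engine is 1-D-oriented; multi-dimensional CVs are
  out of scope.
* Average-linkage clustering materializes the full pairwise RMSD matrix:
  O(n²) memory, intended for desk-scale frame counts (the seed-clustering
  stage), not for hundreds of thousands of frames.
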