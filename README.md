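# tcrmsm

Kinetic characterization of T-cell receptor (TCR) CDR3 loop conformational
ensembles, and of how those loop states shift the relative Vα–Vβ interdomain
orientation.

## The scientific problem

The two CDR3 loops sit at the center of the TCR paratope and dominate
peptide recognition. A single crystal structure is a poor description of
them: in solution each loop populates several metastable conformations, and
which conformation is occupied co-varies with the relative orientation of
the Vα and Vβ domains — and hence with the geometry of the antigen-binding
site. Characterizing this requires an ensemble-and-kinetics toolchain, not
a single-structure one:

1. **Featurization.** Backbone dihedrals φ/ψ of the CDR3 loops, embedded
   periodically as (sin θ, cos θ) pairs. A metadynamics collective
   variable s(x) = Σᵢ aᵢ sin ψᵢ + Σᵢ bᵢ cos ψᵢ over the loop ψ angles is
   available for biased sampling, and a four-center-of-mass torsion
   θ(COM CDR loops α, COM Vα, COM Vβ, COM CDR loops β) measures the
   interdomain orientation.
2. **Enhanced sampling (toy engine).** Well-tempered metadynamics on
   analytic potentials: Gaussians of height
   w·exp(−V_bias/((γ−1)k_BT)) deposited every n steps along the CV,
   free energy recovered as F(s) = −(γ/(γ−1))·V_bias(s). The engine runs
   overdamped Langevin dynamics in CV space, isolating the bias
   mathematics from any MD engine.
3. **Seed clustering.** Average-linkage hierarchical clustering of frames
   on pairwise backbone RMSD (Kabsch superposition) with a distance
   cutoff (default 1.2 Å), medoid representatives.
4. **Dimensionality reduction.** Time-lagged independent component
   analysis (tICA) with the symmetrized covariance estimator; free-energy
   surfaces F = −k_BT ln ρ over the leading two components.
5. **Markov-state model.** k-means microstates (default 150) on the tICA
   projection; reversible maximum-likelihood transition matrix on the
   largest connected set; implied timescales tᵢ = −τ/ln λᵢ; PCCA+
   macrostates; Chapman–Kolmogorov validation with bootstrap bands; mean
   first-passage times between macrostates.
6. **State analysis.** Macrostate-conditioned interdomain-angle
   distributions (circular statistics), pairwise two-sample
   Kolmogorov–Smirnov comparison, per-residue RMSF.

Every stage is validated against synthetic generators with known ground
truth: hidden-Markov dihedral trajectories built on an idealized
polyalanine-like backbone, and rigid two-domain assemblies whose four-COM
torsion is exact by construction.

## Worked example

Three hidden conformational states drive two synthetic CDR3-like loops,
and each hidden state prescribes an interdomain torsion (40°, 60°, −170°).
The pipeline has to rediscover the three states and their angle shifts from
coordinates alone:

```r
library(tcrmsm)

hmm <- hmm_dihedral_spec(
  transition = matrix(c(0.95, 0.03, 0.02,
                        0.02, 0.95, 0.03,
                        0.02, 0.03, 0.95), 3, 3, byrow = TRUE),
  psi_means = rbind(rep(-60, 4), rep(120, 4), c(-60, 120, -60, 120)),
  emission_sd = 12, n_frames = 5000, seed = 42)
gen <- generate_coupled_trajectory(hmm, angle_targets = c(40, 60, -170),
                                   angle_jitter_sd = 0.3)

fm    <- psi_phi_features(gen$trajectory, gen$feature_selections)
tica  <- fit_tica(fm, lag = 5, n_components = 2)
micro <- kmeans_microstates(predict(tica, fm), k = 40, seed = 1)
msm   <- estimate_msm(count_transitions(micro$assignment, 5), lag = 5)
macro <- pcca_plus(msm, 3)

ang   <- do.call(interdomain_torsion,
                 c(list(gen$trajectory), gen$angle_selections))
dists <- macrostate_angle_distributions(
  ang, frames_to_macrostates(macro, micro$assignment))
dists$summary
```

Printed output (abridged):

```
reversible MSM: 40 states, lag 5 ns
leading eigenvalues: 1 0.6838 0.6581 0.112 0.1096
PCCA+ macrostates: 3 macrostates over 40 microstates
stationary probabilities: 0.295 0.396 0.309

  macrostate    n   mean_deg variance_deg2
1          1 1490   40.01832      2.222867
2          2 1979   60.00055      2.147204
3          3 1531 -169.98160      1.447075
```

Reading it: the MSM spectrum has exactly two slow processes (eigenvalues
0.68, 0.66 far above the rest), so three macrostates; their stationary
probabilities recover the hidden chain's equilibrium; and the
macrostate-conditioned interdomain angles land on the prescribed 40°, 60°
and −170° targets to within a tenth of a degree. `pairwise_ks_table(dists)`
gives D = 1 for every macrostate pair — the angle distributions are fully
KS-distinguishable — and `macro_mfpt_matrix(msm, macro)` prints the
macrostate-to-macrostate mean first-passage times (here tens of ns).

`run_pipeline(pipeline_config(...))` chains all stages from a single
(JSON-serializable) configuration and writes CSV/JSON artifacts plus a
manifest with the config hash, so a re-run with the same config is
byte-identical.

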