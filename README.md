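# ffval — statistical validation of protein force fields

Molecular-dynamics force fields are routinely "validated" by simulating a
handful of proteins and eyeballing RMSDs. Such comparisons confound three
sources of variation: the parameter set under test, the choice of protein,
and run-to-run variability between replicate simulations. `ffval` is a
toolkit for doing this properly. It is aimed at force-field developers and
simulation groups who want to decide, with honest error control, whether two
parameter sets differ and which one lies closer to experiment.

The package provides three layers:

1. **A curated benchmark test set.** A packaged manifest of 52
   high-resolution, monomeric, ligand-free protein structures — 39 solved by
   X-ray diffraction and 13 by NMR, 17–326 residues, with nine proteins
   present as X-ray/NMR pairs — together with design bookkeeping
   (per-parameter-set sample sizes, total simulated time).

2. **A metric battery on conformational ensembles.** Backbone and native
   hydrogen bonds (geometric criterion: H···A < 0.25 nm, D–H–A > 120°),
   polar/nonpolar solvent-accessible surface area (Shrake–Rupley, probe
   0.14 nm), mass-weighted radius of gyration, positional RMSD after
   least-squares backbone superposition with Carugo–Pongor RMSD₁₀₀
   normalisation `RMSD / (1 + ln √(N/100))`, a full Kabsch–Sander
   secondary-structure assignment (electrostatic H-bond energy with the
   −0.5 kcal/mol cutoff), φ/ψ dihedral distributions and Ramachandran
   densities, Karplus back-calculation of ³J(HN–Hα) couplings
   `J(θ) = A cos²θ + B cos θ + C` with `θ = φ − 60°`, and NOE upper-bound
   violations from `⟨r⁻³⟩^(−1/3)`-averaged distances with Wüthrich
   pseudoatom corrections. Metrics are re-expressed as percentage deviations
   Δq% = 100·(q_sim − q_ref)/q_ref from the experimental structure.

3. **A nested mixed-effects decision framework.** Observations
   y(parameter set, protein, replicate, metric) are Box-Cox transformed,
   then modelled with random intercepts for protein and
   replicate-within-protein and the parameter set as fixed effect. A
   maximum-likelihood likelihood-ratio test (χ² reference) decides whether
   the parameter set matters — per metric, or across stacked metrics with
   per-metric residual variances and inter-metric correlation (the
   multivariate mixed-effects LRT). Pairwise contrasts report
   Δμ = |mean error(older)| − |mean error(newer)| (positive favours the
   newer set) with Benjamini–Yekutieli adjusted significance.

## Worked example

```r
library(ffval)

# the packaged test set and its design arithmetic
design_summary(load_manifest(), replicates = 3, run_length_ns = 15)
#> Force-field validation study design
#>   structures:        52 (39 X-ray, 13 NMR; 43 distinct proteins)
#>   residue range:     17-326
#>   sample size per parameter set:
#>     45A4  120
#>     53A6  120
#>     54A7  156
#>     54A8  156
#>   total simulated time: 8.28 us

# compare two parameter sets on a synthetic two-metric study in which the
# newer set is worse by +0.5 on the radius-of-gyration deviation
offs <- matrix(c(0, 0.5, 0, 0), 2, 2,
               dimnames = list(c("54A7", "54A8"), c("rgyr_dq", "beta_dq")))
tab <- gen_metric_table(n_proteins = 12, n_replicates = 3,
                        parameter_sets = c("54A7", "54A8"),
                        metrics = c("rgyr_dq", "beta_dq"), ff_offsets = offs,
                        sd_protein = 1, sd_replicate = 0.3,
                        sd_residual = 0.3, seed = 42)
ffcompare(tab)
#> Force-field comparison (nested mixed-effects models)
#>   parameter sets: 54A7 < 54A8
#>   multivariate LRT: p = 0.134 on 2 df
#>   pairwise differences in |mean error| (positive favours the newer set):
#>
#>   metric delta_mu.54A7 -> 54A8 stars.54A7 -> 54A8
#>  rgyr_dq           -0.54492664                ***
#>  beta_dq            0.05676107                 ns
```

Read it as: the planted +0.5 degradation on `rgyr_dq` is recovered
(Δμ ≈ −0.54, i.e. the newer set is farther from experiment, significant at
the BY-adjusted 0.001 level), the null metric `beta_dq` is correctly not
significant, and the overall two-metric test is inconclusive at this small
study size — exactly the protein-versus-parameter-set variance trade-off
the framework is built to expose.

For real trajectories, `read_structure()` / `read_ensemble()` ingest PDB
(and DCD) input, `ensemble_metrics()` / `delta_q_metrics()` produce the
long-format observations, and `run_pipeline()` writes the full report
bundle (metrics, boxplot summaries with 1.5×IQR outlier flags, a pairwise
Δμ table, and the multivariate LRT). A thin command-line wrapper lives at
`inst/cli/ffval.R` (subcommands `manifest`, `metrics`, `nmr`, `compare`,
`synth`, `run`).

## Scope notes

The package analyses ensembles; it does not run MD, assign protonation
states, or solvate systems. XTC/TRR trajectories are not read directly —
convert to DCD or multi-model PDB first. Deposited PDB entries are not
redistributed with the package.
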