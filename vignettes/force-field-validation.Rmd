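---
title: "Validating protein force fields with nested mixed-effects models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protein force fields with nested mixed-effects models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffval)
```

## The problem

Whether a change to a force-field parameter set improves the simulation of
proteins cannot be decided from a few trajectories. Any structural metric
computed from a simulation varies at three levels: with the parameter set
(the effect of interest), with the protein simulated, and between replicate
runs of the same system that differ only in initial velocities. In practice
the protein-to-protein and replicate-to-replicate variation is large
compared with the differences between parameter sets, so single-system
comparisons are close to meaningless. `ffval` packages the ingredients of a
statistically defensible comparison: a diverse benchmark test set, a battery
of metrics that can all be expressed as deviations from an experimental
reference, and a nested mixed-effects testing framework.

## The test set and its bookkeeping

The packaged manifest (`load_manifest()`) lists 52 structures: 39 X-ray
entries and 13 NMR entries, covering 43 distinct proteins once the nine
proteins present as X-ray/NMR pairs are deduplicated (the `paired_id`
column makes the pairing explicit and reciprocal). Entries record residue
counts, secondary-structure percentages (with β = strand + bridge),
pH, crystallographic resolution and R-factors where applicable, available
NMR data types, and which parameter sets cover the entry: 40 structures are
covered by all four GROMOS sets (45A4, 53A6, 54A7, 54A8), 12 only by
54A7/54A8. `design_summary()` turns this into sample sizes — with three
15 ns replicates: 120 observations per older set, 156 per newer set, and
8.28 μs of total simulated time, which rounds to 8.3 μs at one decimal (a
truncated 8.2 is sometimes quoted for the same arithmetic; the package
always reports the computed value). One entry (2PNE) folds entirely into a
polyproline-II spiral that the secondary-structure dictionary does not
detect; its table row carries that fact as a free-text note rather than a
number.

## Structural metrics

All internal geometry uses nanometres, atomic mass units and degrees; PDB
ingestion converts Å to nm. Reading a structure keeps only the first
`MODEL`, resolves alternate locations to the highest-occupancy conformer
(ties broken by the lexicographically first altloc identifier — a
deterministic stand-in for manual inspection), restricts analysis to the
first protein chain (all test-set proteins are monomeric), and retains
waters and heteroatoms in a separate table.

**Hydrogen bonds.** A bond exists when the hydrogen–acceptor distance is
below 0.25 nm and the donor–H–acceptor angle exceeds 120°. Backbone mode
restricts donors to amide N–H and acceptors to carbonyl O; side-chain
donors are deliberately excluded by default since the inclusion rule is a
modelling choice, not a physical necessity. When amide hydrogens are absent
(united-atom topologies, X-ray structures) they are constructed 0.1 nm
from N, anti-parallel to the preceding carbonyl C=O bond. This is the
Kabsch–Sander convention; it is used everywhere (a bisector construction
differs by only a few degrees and would otherwise introduce two conventions
for the same atom). *Native* hydrogen-bond counting detects the bond list
in the experimental reference once and then scores each frame by how many
of those donor–acceptor pairs still satisfy the criterion.

**SASA.** Shrake–Rupley sphere-point sampling with a 0.14 nm probe and 960
deterministic points per atom (a golden-spiral construction, so results are
reproducible and rotation dependence stays well below 1%). Atom radii are
configuration data looked up by element; the shipped defaults are standard
van der Waals radii (C 0.172, N 0.155, O 0.152, S 0.180, H 0.120 nm) and
are user-overridable wholesale, e.g. with radii derived from the
Lennard-Jones minima of a specific water–solute model, since the radius
*rule* and the radius *numbers* are separate commitments. Totals are split
into polar and nonpolar by residue: Arg, Asp, Asn, Glu, Gln, Gly, His,
Lys, Ser, Thr and Pro count polar, the remaining nine standard residues
nonpolar.

**Size and distance.** The radius of gyration is mass-weighted. Positional
RMSD is computed after a least-squares rigid-body fit on the backbone heavy
atoms excluding the first and last residue, and evaluated over the same
selection. RMSD₁₀₀ divides by `1 + ln√(N/100)`; chains of 40 residues or
fewer are passed through unchanged because the normalisation is not
validated there.

**Secondary structure.** A self-contained Kabsch–Sander implementation:
electrostatic H-bond energy
`E = 0.084·332·(1/rON + 1/rCH − 1/rOH − 1/rCN)` kcal/mol with the standard
−0.5 kcal/mol cutoff, a 0.9 nm CA-distance prefilter, and a 0.5 Å clash
guard. Four-turn ladders give α-helix (H), three- and five-turn ladders G
and I, bridge patterns give E/B with β-bulge merging (gaps of at most one
residue on one strand and four on the other), then hydrogen-bonded turns
(T) and bends (S, CA-direction change above 70°). Priorities follow the
dictionary: H before E/B before G/I before T before S. Reported percentages
merge E and B into the β fraction, matching the manifest convention. The
implementation is validated against an independent full DSSP implementation
on geometry-built helices and hairpins (expected assignments frozen into
the test suite).

**Dihedrals.** φ(i) is C(i−1)–N–CA–C, ψ(i) is N–CA–C–N(i+1), reported in
(−180°, 180°] with terminal residues absent. Histograms use 5° bins in 1D
and 0.5° bins for Ramachandran densities (bin widths must divide 360
evenly), normalised to sum to one; a per-residue-type mode pools by
3-letter code.

## NMR observables

³J(HN–Hα) couplings are back-calculated per frame from φ via the Karplus
relation with θ = φ − 60° (the phase appropriate when φ is defined over
heavy atoms C–N–CA–C, as in united-atom models). The coefficients are
configuration data: the shipped default is the widely used Pardi
calibration (A = 6.4, B = −1.4, C = 1.9 Hz) because the empirical
calibrations in circulation differ and the choice should be explicit and
swappable, not baked in. Per-residue couplings are averaged over all pooled
frames before the RMSD against experiment is taken.

NOE comparison uses `⟨r⁻³⟩^(−1/3)` averaging of interproton distances over
the pooled replicates — the appropriate convention for short trajectories
where spectral densities cannot be computed — against deposited upper
bounds. Restraints referencing pseudoatoms (Q/M naming) are resolved to
their member protons (geometric centre) or, in united-atom topologies, to
the carrier heavy atom; any prior bound correction is removed and the
pseudoatom correction applied (defaults, in nm: methyl 0.10, methylene
0.10, aromatic ring 0.20, isopropyl 0.24 — literature-standard magnitudes,
overridable). The average violation divides the summed violations by the
*total* restraint count, satisfied restraints included. Restraints with
doubtful assignments can be flagged `ambiguous` by the user; the package
deliberately does not hard-code any dataset-specific reassignment.

## The statistical framework

The unit of analysis is one number per (parameter set, protein, replicate,
metric). The model behind `fit_univariate_mixed()` is

y = μ(parameter set) + b(protein) + c(replicate within protein) + ε,

with Gaussian random intercepts and residuals, fitted by maximum
likelihood (lme4). Replicate labels identify paired runs across parameter
sets, which is what makes the replicate-within-protein variance component
identifiable in a single-metric table. Unbalanced designs — structures
missing for the older parameter sets — are handled by ML on the available
data. Random slopes are not included: the nesting structure is stated by
the design, slopes would be an additional modelling assumption.

Because the residuals must be Gaussian, each metric is first passed through
a Box-Cox transform whose exponent maximises the profile likelihood of a
linear model with protein and parameter set as regressors
(`boxcox_fit()`, grid −2…2 in steps of 0.05, with a 95% profile interval
reported). Metrics with nonpositive values — signed Δq% deviations — are
shifted by −min(y) plus 10⁻⁶ of the range first; the shift is recorded in
the result.

Significance of the parameter-set effect comes from a likelihood-ratio
test of nested ML fits, referred to χ² with df equal to the number of freed
parameters; the df is reported alongside the statistic, and the reference
distribution is named in the output because a simulated null would be an
equally defensible choice. The multivariate variant stacks all metrics
long-form in one `nlme::lme` model with a metric factor, per-metric
residual variances (`varIdent`) and an exchangeable inter-metric
correlation (`corCompSymm`); an exchangeable structure is the default
because an unstructured correlation is expensive to fit and the framework's
conclusions should not hinge on it. The full model frees one parameter-set
effect per metric, so df = (#metrics)·(#sets − 1).

Pairwise reporting follows the convention that makes tables readable:
Δμ = |mean error(older)| − |mean error(newer)| on the *untransformed*
scale (so values are in the metric's own units), significance from the
*transformed* mixed model via `emmeans`, and all p-values adjusted to
Benjamini–Yekutieli false-discovery rates, which remain valid under the
arbitrary dependence between overlapping pairwise tests. Stars follow the
usual thresholds (***, ≤0.001; **, ≤0.01; *, ≤0.05). Fits that trip the
optimizer's convergence checks are flagged, and downstream tests refuse
flagged fits rather than silently reporting from them.

## The synthetic-data generators

`gen_metric_table()` emulates exactly the three-level variance structure
the models assume: fixed per-(set, metric) offsets plus Gaussian protein,
replicate-within-protein and residual components, with protein and
replicate effects shared across parameter sets. Defaults (40 proteins,
3 replicates, four parameter sets, σ_protein = 2, σ_replicate = 0.5,
σ_residual = 0.3) mirror the benchmark design's size and its dominant
protein-level variance. A lognormal option exponentiates the linear
predictor to exercise the Box-Cox path. `gen_ensemble()` jitters a
reference conformation with i.i.d. Gaussian displacements;
`build_ideal_helix()` / `build_ideal_hairpin()` construct poly-alanine
backbones at canonical torsions from standard bond geometry;
`gen_noe_set()` plants restraints with controlled slack. Every generator
is a pure function of its arguments including the seed.

What passing tests on these generators shows — and what it does not: the
statistical machinery is verified to be calibrated (type-I error at the
nominal level) and consistent (planted effects recovered) *when the model's
assumptions hold by construction*. Real trajectories violate them in known
ways: frames are autocorrelated, replicate variances are underestimated at
short run lengths, metrics are bounded and discretised, and conformational
jitter is neither isotropic nor Gaussian. The generators make the code
testable without MD; they do not make short simulations sufficient.

## Numerical choices and degenerate inputs

Superposition uses the SVD-based least-squares fit (bio3d); selections with
fewer than three atoms or collinear geometry raise errors rather than
returning arbitrary rotations. Dihedral values use the IUPAC sign
convention with the half-open range (−180°, 180]. The LRT statistic is
clamped at zero, and a full-model likelihood more than 10⁻⁶ below the
null's raises an optimisation-failure error instead of reporting a
negative statistic. Zero-variance data yield near-zero variance components
(singular fits are tolerated, not errors). A zero reference value makes
Δq% undefined and raises an error; `rmsd100` is the one battery metric kept
on its natural scale since its reference is identically zero. Histogram bin
widths must divide 360°. Chains shorter than three residues are assigned
all-coil.

The test suite's simulation sizes are chosen to make the stochastic checks
sharp but cheap: 500 null simulations of a 10-protein × 3-replicate ×
2-set design for the type-I error of the LRT, a 40 × 3 design for effect
recovery, 25 seeds for the end-to-end recovery property. Occasional draws
whose optimiser trips a convergence check are replaced by the next seed in
the stream, because a converged fit is a stated precondition of the test.

## Known limitations

* XTC/TRR trajectories have no reader in this stack; use DCD or
  multi-model PDB. GRO input is single-frame.
* The Kabsch–Sander implementation omits chain-break bookkeeping and
  multi-chain sheets (the test set is monomeric single-chain); π-helix
  priority follows the classic dictionary, not later revisions.
* Pseudoatom resolution covers the common Q/M naming conventions; exotic
  restraint dialects should be converted to the plain TSV format first.
* The multivariate model's exchangeable correlation is an approximation;
  with many metrics of very different character an unstructured fit (not
  the default) may be preferred at substantial cost.
* Deposited PDB entries are not redistributed; worked examples on specific
  PDB accessions require the user to supply the files.
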