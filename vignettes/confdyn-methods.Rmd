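---
title: "Methods and design of confdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of confdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdyn)
```

`confdyn` is a toolkit for comparative analysis of molecular-dynamics
ensembles of multi-domain proteins such as the Argonaute paralogs. This
vignette is the package's account of the science behind each stage: the
quantities computed, the assumptions behind them, the parameters that
matter, and the design choices made where the methodology was genuinely
open. Nothing here claims an empirical result the test suite or the
acceptance script does not itself compute.

## The data model

Everything operates on an `ensemble`: an atom table, an
`n_atoms x 3 x n_frames` coordinate array in Ångström, and optional
annotations (a `domain_partition`, an RNA chain id, per-atom nonbonded
parameters). Internal residue indexing is 0-based and contiguous in file
order; author/PDB numbering is display metadata only. The reason is
comparative: related isoforms carry different author numbering, so every
cross-isoform statement goes through an explicit correspondence table
rather than through resno arithmetic. PDB reading and writing are
delegated to `bio3d`.

## Distance fluctuations

For Cα atoms i, j the coordination measure is the time-averaged variance
of their distance,
$$\mathrm{DF}_{ij} = \langle (r_{ij} - \langle r_{ij}\rangle)^2\rangle
                   = \langle r_{ij}^2\rangle - \langle r_{ij}\rangle^2 .$$
Low values mean the pair moves as a unit; large values flag relative
flexibility such as interlobe breathing. Distances are invariant under
rigid motion, so no superposition is applied. The implementation is a
single streaming pass accumulating compensated (Kahan) sums of $r$ and
$r^2$; the tests require agreement with a store-everything two-pass oracle
to 1e-8 Å². An optional equilibration skip (default 0 frames) is exposed
because hydration analysis conventionally discards an equilibration
prefix; we make the same knob available, and off by default, everywhere.

## Geometric descriptors and discriminative PCA

Thirteen per-frame descriptors summarise the multi-domain architecture:
eight centre-of-mass distances — PAZ–PIWI, PAZ–N, PIWI–N, PAZ–MID,
(N+PAZ)–(MID+PIWI), PIWI–L2, PAZ–helix7, L1–L2 — and five angles for the
first five of those pairs. A COM is the unweighted Cα centroid. **Angle
construction (open design point).** An "angle between domain X and Y"
admits several readings; we define it as the angle subtended at the
whole-selection centre of mass by the two domain COMs, which uses only
quantities the descriptor list names. It is configurable through
`pair_spec`, and alternative hinge-style definitions can be supplied
without touching the pipeline. The helix-7 sub-selection is user-supplied
(a 12-residue range; synthetic structures record one inside L2).

The pooled frames of all labelled ensembles are standardised to zero mean
and unit variance per descriptor and decomposed by PCA (correlation-matrix
PCA, so the eigenvalues sum to 13). PC signs are fixed so each component's
largest-magnitude loading is positive. Because the dominant components
absorb the shared large-scale conformational modes rather than
between-isoform differences, PC1 and PC2 are excluded; all remaining PC
pairs whose combined explained-variance fraction reaches 0.15 are ranked
by the Calinski–Harabasz score of their labelled 2-D projection,
$$\mathrm{CH} = \frac{B/(k-1)}{W/(n-k)},$$
with $B$ and $W$ the between- and within-label sums of squares ($W = 0$
returns `Inf`). Descriptors are then ranked by their largest absolute
loading on the winning pair. When no pair reaches the variance threshold
the result says so explicitly (`no_qualifying_pair`) instead of falling
back silently. A property worth knowing: because CH is computed on raw PC
scores, among pairs that separate labels equally the score prefers the
partner PC with the smaller within-group scatter, so the variance
threshold is what keeps near-degenerate, tiny-variance components (which
concentrate loadings on near-collinear descriptors) out of the candidate
set. The 0.15 threshold is read as the sum of the two variance fractions.

## Energy decomposition

The residue-pair energy matrix sums atom-pair nonbonded terms within a
10 Å cutoff: Coulomb with $k_e = 332.0637$ kcal·Å/(mol·e²) (the Amber
convention matching the parameter tables the package reads) and 12-6
Lennard-Jones with Lorentz–Berthelot mixing. Three design points:

- **Solvation.** The matrix is nominally
  $E_{ij} = E^{el}_{ij} + E^{vdW}_{ij} + G^{solv}_{ij}$, but no solvation
  method is prescribed by the decomposition itself; the default is
  $G^{solv} = 0$, with a distance-dependent-dielectric mode
  ($\varepsilon(r) = r$) as a screening option. The mode is recorded in
  the output.
- **Bonded neighbours.** Residue pairs with sequence separation < 2 are
  excluded: their interaction is dominated by covalent terms this model
  omits. Configurable (`min_seq_sep`).
- **Per-residue profile.** The leading eigenvector (largest |eigenvalue|,
  sign fixed so its component sum is non-negative) identifies the dominant
  energy couplings. The per-residue stabilisation profile is the
  energy-weighted participation $|\lambda_1| v_i^2$ — non-negative and
  summing to $|\lambda_1|$ — with raw $|v_i|$ available as an option.
  "Electrostatic nuclei" are residues whose profile value is at least
  0.005 kcal/mol (inclusive); the threshold can alternatively be applied
  to the strongest raw matrix entry per residue (`use = "matrix"`),
  since either reading of the cutoff is defensible.

The EDM is evaluated on cluster-representative conformations (average-
linkage agglomerative clustering of superposed Cα RMSD, merge cutoff
ε = 3.0 Å, representatives = medoid frames, populations as weights), not
per frame.

## Interaction networks

Hydrogen bonds: donor–acceptor heavy-atom distance ≤ 3.0 Å and D–H···A
angle ≥ 160°, mirroring the common VMD-style criterion; donors/acceptors
come from editable chemistry tables shipped under `inst/extdata`, and
hydrogens must be explicit (attachment is inferred from ≤ 1.25 Å bonds in
frame 1). Salt bridges: any basic N to acidic O distance ≤ 4.0 Å
(inclusive), the common Cpptraj-style convention. Both cutoffs are
parameters, since different front-end tools default differently.

Persistence is the fraction of frames a bond exists. Bonds mediated by
chemically equivalent atoms (Asp OD1/OD2, Glu OE1/OE2, Arg NH1/NH2,
Phe/Tyr ring pairs) are merged first: the merged persistence is the
arithmetic mean of the members' persistences (the natural reading of
"averaged"; the frame-wise OR trace is kept for classification only).
Then events below 0.05 are dropped (≥ is kept) and events above 0.20
(strict) are flagged as the "most meaningful" set. Per-domain intradomain
hydrogen-bond counts report the per-frame mean ± population SD, which is
what makes the two-frame 3/5 example come out as 4 ± 1.

## Pocket definition and channel volume

The RNA-binding pocket is every protein residue with a heavy atom within
6 Å of an RNA heavy atom in a chosen (crystallographic) frame. Minimal
conserved pockets across isoforms are set intersections in a user-supplied
common residue space, with unmapped residues excluded loudly.

No standard algorithm is attached to "channel volume", so the package
uses a deterministic, oracle-checkable construction: count grid points
(default 0.5 Å spacing) that lie inside the convex hull of the pocket
residues' heavy atoms and farther than probe + vdW radius (probe default
1.4 Å, element radii H 1.2 / C 1.7 / N 1.55 / O 1.52 / S,P 1.8) from
every protein heavy atom, times the cell volume; average over cluster
representatives with population weights. The convex hull is computed by a
small incremental quickhull written for this package (no installed R
package provides 3-D hulls); tests validate it on reference solids and
validate the volume on a hollow-sphere cage with an analytic interior
volume (within 5% at 0.5 Å grid, < 2% change on grid halving). Absolute
volumes depend on the boundary convention, so cross-study comparisons
should use ratios under a fixed convention.

## Water survival probability

For a region defined by anchor atoms and a 4 Å inclusion radius on water
oxygens,
$$P(\tau) = \frac{1}{T_n}\sum_t \frac{N(t,\tau)}{N(t)},$$
where $N(t,\tau)$ counts waters present at origin $t$ and **continuously**
present through $t+\tau$ (intermittency 0; an allowance for k-frame gaps
is a flagged option, since the estimator is also used with endpoint-only
conventions). Origins with $N(t)=0$ are excluded. The trajectory, after an
equilibration skip, is divided into fixed-length windows and $P$ is
averaged across windows; within a window all lags share a common origin
set ($t + \tau_{max}$ inside the window), which guarantees $P(0)=1$ and
monotone non-increase by construction. Physical-time defaults (20 ns
windows, 100 ns skip, τ up to 1 ns) translate to frames through the
declared `frame_interval`; synthetic fixtures use frame units directly.
The synthetic water generator uses memoryless per-frame exchange
(probability $p$, retired ids), giving the closed form
$P(\tau) = (1-p)^\tau$ against which the estimator is tested.

## Allosteric communication

A conformation's Cα contact topology (cutoff 10 Å, the common Gaussian-
network default; the methodology's own cutoff being unstated it is a
parameter) defines the Kirchhoff matrix and an unweighted random walk with
$P = D^{-1}A$. Hit times solve the first-passage systems
$(I - P_{-j})h = \mathbf{1}$ per target; commute times
$C(i,j) = H(i{\to}j) + H(j{\to}i)$ are symmetric and satisfy
$C = 2|E| \cdot R_{\mathrm{eff}}$, which the tests verify against a
Laplacian-pseudoinverse resistance oracle on random graphs. Contact edges
re-weighted by $C$ feed a loopless (Yen) k-shortest-path search between a
source and a target residue set, realised set-to-set through zero-weight
super-nodes; path score is the summed edge commute time, ties broken
lexicographically on the node sequence. Disconnected networks are an
error naming the components — silent largest-component fallback would
corrupt comparisons.

Hotspots are scored by pathway membership (top-k pathways pooled over a
condition's cluster representatives), excluding source/target residues;
the top-15 sets are compared across conditions by intersection size, and
communication efficiency is the mean pathway commute time. The precise
"conserved residue" bookkeeping is not canonical; occurrence counting
across representatives is the simplest order-invariant choice and is what
the package documents and tests.

## The synthetic-data generators

The generators are first-class, tested code, not fixtures. They emulate:
compact rigid domains on a deterministic octahedral layout (per-domain
Gaussian rigid jitter of per-axis SD σ, default 0.5 Å — the scale of
well-converged domain fluctuations after fitting); sinusoidal interdomain
breathing along centroid axes (demo amplitudes 6 and 4 Å, the magnitude
of interlobe opening motions, with incommensurate periods so the two
modes stay independent); labelled ensembles sharing those common modes
with one condition's mean shifted along a named descriptor (demo shift =
5 × the descriptor's jitter SD, i.e. $5\sqrt{2}\,\sigma$); planted on/off
bond traces realised geometrically (2.9 Å linear in "on" frames, 6 Å in
"off" frames, first ⌈f·n⌉ frames on so realised occupancy is exact);
memoryless water exchange; and block-structured energy matrices. All
planted parameters are emitted in machine-readable metadata.

What they deliberately do **not** emulate: anharmonic side-chain
dynamics, solvent friction, correlated inter-domain noise, force-field
realism, or sequence heterogeneity. Passing tests therefore demonstrate
that the estimators recover known structure under their stated
assumptions — not that any particular biological conclusion transfers to
real trajectories.

## Numerical choices and degenerate inputs

Superposition uses the SVD Kabsch construction with determinant
correction (always a proper rotation); < 3 or collinear fit atoms are an
error. Representative-frame ties break to the lowest frame index.
Cluster labels order by population. The leading-eigenvalue degeneracy of
an energy matrix (|λ₁| ≈ |λ₂| within 1e-9) is recorded in the result
rather than silently resolved. An empty pocket (RNA too far, or cutoff 0)
returns an empty, flagged definition with a warning. DF accumulators
clamp the tiny negative variances of exactly rigid pairs to zero. All
generators are pure functions of (spec, seed) and the pipeline rerun is
byte-identical at a fixed seed.

## Problem sizes

The bundled demo and the test suite run at desk scale: 105–160 residue
toy proteins, 150-frame demo ensembles, 500-frame/4-label recovery
studies repeated across 100 seeds, 2000-frame water simulations with 200
waters, contact networks of ≤ 160 nodes, and ≤ 12-node graphs for the
exact oracles. These sizes make every planted effect statistically
decisive while keeping the full suite and the demo pipeline fast on a
single CPU; all of them scale up through the same interfaces.

## Known limitations

- The energetics stage is a fixed-charge, cutoff-based decomposition: no
  Ewald summation, no polarisation, no generalized-Born solvation; the
  eigenvector profile mapping (|λ₁|v²) is one defensible reading of an
  underdetermined convention.
- The angle-descriptor construction is one of several possible; results
  that hinge on angle descriptors should be checked under an alternative
  `pair_spec`.
- Absolute channel volumes are convention-dependent (hull boundary, grid,
  probe); only within-convention comparisons are meaningful.
- Salt-bridge detection treats His as potentially protonated on both
  ring nitrogens; adjust the chemistry table for fixed protonation
  states.
- XTC/DCD trajectories are out of scope for the bundled reader;
  multi-model PDB is the supported interchange format.
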