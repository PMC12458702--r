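# confdyn

Comparative conformational-dynamics analysis of multi-domain protein
ensembles, built around the kind of question posed by the four human
Argonaute paralogs (hAgo1–4): given long molecular-dynamics ensembles of
several related isoforms, where do they differ in coordination, energetics,
interaction networks, hydration, and allosteric communication?

`confdyn` implements the full analysis chain in base R:

- **Distance-fluctuation maps.** DF<sub>ij</sub> = ⟨(r<sub>ij</sub> −
  ⟨r<sub>ij</sub>⟩)²⟩ over Cα pairs; low values mark dynamically
  coordinated residues. Domain-block summaries and bound−apo differences.
- **Geometric-descriptor PCA.** Thirteen descriptors (eight domain
  centre-of-mass distances, five angles at the global centre of mass) per
  frame, standardised PCA over pooled labelled ensembles, then
  discriminative PC-pair selection: PC1–2 are excluded, pairs with
  combined explained variance ≥ 15% are ranked by Calinski–Harabasz score
  CH = [B/(k−1)]/[W/(n−k)], and descriptors by their largest |loading| on
  the winning pair.
- **Energy decomposition matrices.** Residue-pair nonbonded energies
  E<sub>ij</sub> = E<sup>el</sup> + E<sup>vdW</sup> (Coulomb constant
  332.0637 kcal·Å/(mol·e²), Lorentz–Berthelot mixing, 10 Å cutoff), the
  leading eigenvector of the matrix, per-residue stability profiles
  |λ₁|v<sub>i</sub>², and electrostatic "nuclei" at the 0.005 kcal/mol
  profile threshold.
- **Interaction networks.** Hydrogen bonds (3.0 Å / 160°) and salt
  bridges (4.0 Å) per frame, persistence filtering (retain ≥ 5%, flag >
  20%), averaging over chemically equivalent side-chain atoms, and
  intra-/inter-domain classification.
- **Pocket volumes.** RNA-binding pocket by the 6 Å heavy-atom rule,
  conserved minimal pockets across isoforms, and channel volume as a
  cluster-population-weighted, convex-hull-bounded probe-accessible grid
  count.
- **Water survival.** P(τ) = (1/T<sub>n</sub>) Σ<sub>t</sub> N(t,τ)/N(t)
  for waters continuously resident in a 4 Å anchored region, with window
  averaging and equilibration skipping.
- **Allosteric pathways.** Gaussian-network Kirchhoff contact topology,
  Markov hit/commute times (first-passage linear systems), commute-weighted
  Yen k-shortest pathways between residue sets, and hotspot conservation
  across cluster representatives and conditions.
- **Synthetic trajectories.** Every input the pipeline needs can be
  generated with planted, analytically known structure (per-domain
  flexibility, interdomain breathing, labelled descriptor shifts, on/off
  bond traces, geometric water exchange, block energy matrices), so the
  whole chain is testable without any external download.

## Worked example

```r
library(confdyn)

# a 6-domain toy protein with planted interdomain breathing
spec <- synthetic_spec(seed = 1, n_frames = 150,
                       breathing = list(list(pair = c("PAZ", "MID"),
                                             amplitude = 6, period = 37)))
ens <- make_ensemble(spec)
df <- compute_df(ens)
print(df)
#> dfmat: 160 residues, 150 frames; mean DF 2.945 A^2
round(df_block_summary(df, ens$partition)[c("PAZ", "MID"), c("PAZ", "MID")], 2)
#>       PAZ   MID
#> PAZ  0.00 17.49
#> MID 17.49  0.00
```

The planted PAZ–MID breathing (amplitude 6 Å) dominates the block summary:
the PAZ–MID block mean of ≈ 17.5 Å² is close to the theoretical variance
of a 6 Å sinusoid plus jitter (A²/2 + 2σ² ≈ 18.5), while within-domain
blocks are ≈ 0 (rigid domains). The full demo pipeline,

```r
manifest <- run_pipeline(out_dir = "demo", seed = 1)
```

runs every stage on synthetic data in a few seconds and writes CSV/JSON
artifacts plus a manifest; `manifest$summary$descriptors` shows the
planted label-separating descriptor (`d_L1_L2`) recovered as the
top-ranked discriminative feature on the PC3–PC4 pair. A thin CLI wrapper
lives at `inst/scripts/confdyn.R`.

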