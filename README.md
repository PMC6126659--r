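# bphpgeom

Geometric and spectral analysis of bacteriophytochrome (BphP) photosensory
modules.

Bacteriophytochromes are red/far-red photoreceptors built from PAS, GAF and
PHY domains around a biliverdin chromophore. Photoconversion between the
red-absorbing Pr state (λmax ≈ 700 nm) and the far-red-absorbing Pfr state
(λmax ≈ 750 nm) repositions the PHY domains and reshapes the dimer
interface. Comparing crystal structures of these modules therefore comes
down to a small set of geometric descriptors, which this package computes
for any pair or set of coordinate files:

- **Cα pairing** between two structures by Smith–Waterman local alignment
  of their residue sequences (affine gaps, BLOSUM62 by default);
- **superposition r.m.s.d.** by least-squares rigid (Kabsch) fitting with
  iterative rejection of pairs deviating by more than 5 Å;
- **PHY rotation and translation**: the residual rotation angle
  θ = arccos((tr R − 1)/2) and centroid shift of the PHY domain after
  aligning the PAS–GAF cores of two structures;
- **interface offset angle φ**: the angle between the two subunits'
  interface helix-bundle axes (each bundle axis the normalized mean of two
  N→C-oriented helix axes), with antiparallel (AP) dimers flagged;
- **d-centroids and opening angle Ω**: the distance between the two
  PHY-domain Cα centroids and the angle they subtend at a vertex midway
  between the C-terminal ends of interface helices 3 and 6;
- **B-factor displacement**: ⟨u²⟩^1/2 = √(3B/8π²) per domain;
- **chromophore-pocket distances** between named atoms, ligands included;
- **UV–vis spectra**: red/far-red normalization, illuminated-minus-dark
  difference spectra, and absorption-maximum extraction after 5-point
  median smoothing.

A synthetic-data module generates two-chain Cα dimer models whose φ,
d-centroids, Ω and PHY rotation/translation are set exactly by
construction (plus optional Gaussian noise), and absorption spectra as
Pr/Pfr-like Gaussian band mixtures, so that the whole pipeline is testable
against known ground truth without any deposited data.

## Worked example

```r
library(bphpgeom)

ref <- make_synthetic_dimer(dimer_spec(seed = 1))              # phi 46, d 30, omega 54
pfr <- make_synthetic_dimer(dimer_spec(d_centroids = 46, omega = 85,
                                       phy_rotation = 33, seed = 1))
tab <- geometry_table(ref$structure, list(pfr$structure), ref$scheme)
format_geometry_table(tab)
#>         structure phi_deg d_centroids_A omega_deg phy_rotation_deg core_rmsd_A n_pairs flags
#>  synthetic_dimer_seed1    46.0          30.0      54.0             ref.        ref.    ref.
#>  synthetic_dimer_seed1    46.0          46.0      85.0             33.0        0.00     325

rms_displacement_from_b(100)
#>   b_factor rms_displacement
#> 1      100         1.949242
```

The second row reads as: after pairing the PAS–GAF cores (325 Cα pairs,
r.m.s.d. 0.00 Å — same underlying model), the PHY domain of the Pfr-like
dimer is rotated by 33° relative to the reference, its centroids are 46 Å
apart, and they subtend 85° at the interface vertex. A mean PHY B factor
of 100 Å² corresponds to a ~1.95 Å r.m.s. displacement, i.e. domain-level
heterogeneity of about 2 Å.

The `analysis/` directory holds the narrative workflow: `01_simulate.R`
generates the study set (fixtures under `scratch/fixtures/`),
`02_geometry.R` produces the geometry report (`results/geometry.tsv`,
`results/displacement.tsv`), and `03_spectra.R` the spectral summaries
(`results/spectra/`, `results/lambda_max.tsv`).

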