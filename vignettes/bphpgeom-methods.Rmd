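---
title: "Quantifying photosensory-module conformations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photosensory-module conformations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bphpgeom)
```

## The problem

Bacteriophytochromes (BphPs) sense red and far-red light with a
photosensory module of three domains — PAS, GAF and PHY — arranged around a
covalently bound biliverdin chromophore. Isomerization of the chromophore's
ring-D double bond flips the protein between a Pr state (absorption maximum
near 700 nm) and a Pfr state (near 750 nm), and the structural consequence
is a large rigid-body repositioning of the PHY domains of the dimer while
the PAS–GAF cores stay nearly unchanged. Comparing crystal structures of
such modules — wild type against point mutants, Pr against Pfr,
cryogenic against room temperature — therefore reduces to a handful of
geometric descriptors. This package computes those descriptors
reproducibly, and ships a generator of synthetic dimers and spectra with
exactly known ground truth so that every stage of the pipeline can be
validated without access to deposited coordinates.

## Coordinate model and conventions

Structures are flat atom tables (`bphp_structure`) parsed from PDB or
mmCIF via bio3d. Coordinates are in Å, angles are reported in degrees, and
residue ranges are 1-based inclusive in *author* numbering, so that residue
labels such as Thr289 or Arg472 can be used directly. Alternate locations
are resolved to the highest-occupancy conformer (ties go to the first
altloc label): the pipeline is single-conformer and deterministic. Waters
and hydrogens never enter the Cα-based geometry because every descriptor is
computed from Cα traces; `atom_pair_distance()` deliberately sees all
atoms, ligands included, so chromophore-pocket hydrogen-bond distances can
be measured. Insertion codes order alphabetically after the blank code.
Multi-model files contribute only their first model.

Dimers built from a monomeric asymmetric unit are supported by supplying
either a biological-assembly file or an explicit symmetry operator (12
numbers: row-major rotation, then translation) in the YAML configuration;
the package does not interpret space-group symbols, which keeps the
assembly step explicit and auditable.

The default domain scheme (shipped in `inst/extdata/sabphp1_pcm.yaml`)
puts the PAS–GAF/PHY boundary at residue 325 — the helical kink at the
GAF-to-PHY transition — and the sensory tongue at 435–485. Both are
configurable: domain boundaries in these proteins are approximate by
nature, and published figures disagree by a few residues on the tongue's
C-terminal end.

## Residue pairing

Cα positions of two structures are paired by a Smith–Waterman local
alignment of their 1-letter sequences. The scoring is affine (Gotoh): a
gap of length $k$ costs $g_{open} + (k-1)\,g_{ext}$, with defaults
$g_{open}=10$, $g_{ext}=1$ on BLOSUM62. These are ordinary protein
defaults; for the homologous PAS–GAF cores this pipeline compares, the
resulting pair lists (and hence the superposition r.m.s.d.) are insensitive
to the exact choices. Determinism is pinned down explicitly: traceback
starts at the highest-scoring cell (first in row-major order) and prefers
diagonal over up over left, closing gaps in preference to extending them.
Modified residues map to their parent 1-letter code where known, else to X,
which scores through the table's X column. The kernel is ~60 lines of C++
(Rcpp); its scores are checked in the test suite against both an exhaustive
enumeration oracle (all monotone pair sets, sequence lengths ≤ 8 — the
A-side and B-side gap costs of a pair set are independent, so enumeration
is exact and cheap) and Biostrings' independent implementation.

## Superposition and the outlier rule

`kabsch_fit()` is the SVD-based least-squares rigid fit with reflection
correction and optional non-negative weights (uniform by default;
occupancy weighting is available but off, since it mixes refinement
artifacts into geometry). Degenerate inputs — fewer than 3 pairs, or
(near-)collinear configurations, detected by a singular-value ratio
threshold of $10^{-12}$ — are refused rather than silently fitted. The test
suite holds the r.m.s.d. to within $10^{-9}$ Å of an independently
implemented quaternion (Horn) solution over a thousand random instances.

The comparison r.m.s.d. uses `iterative_fit()`: fit, recompute per-pair
deviations, reject pairs deviating by more than the cutoff (default 5 Å),
and refit until the rejected set stops changing (cap: 20 iterations). The
rejected set only ever grows, which guarantees termination and makes the
procedure order-independent. The final r.m.s.d. is over retained pairs
only. The 5 Å rule is exposed as a parameter because it is a convention,
not a law; its effect is logged per run (pairs in, pairs rejected,
iterations) so every report row is auditable.

Rotation angles come from $\theta = \arccos((\mathrm{tr}\,R - 1)/2)$,
clamped to $[0°, 180°]$; arguments up to $10^{-12}$ beyond the arccos
domain are tolerated and clamped, anything worse is an error.

## Dimer descriptors

**Interface offset angle φ.** Each subunit contributes two interface
helices. A helix axis is computed as the screw axis of the least-squares
superposition of the helix trace onto its one-residue shift: for an ideal
helix that superposition *is* the helical symmetry operation, so the axis
is exact (the raw principal axis of a finite helix is biased by up to a
degree, which is why we do not use it), and being least-squares it degrades
gracefully with noise — the Monte-Carlo test holds 0.3 Å coordinate noise
to under 3° of axis error. Axes are sign-aligned N→C; the per-subunit
bundle axis is the normalized mean of its two helix directions, and φ is
the angle between the two bundle axes. If that angle exceeds 135° the
dimer is reported as antiparallel (AP) and φ folded to its supplement. A
perfectly anti-aligned helix pair within one subunit has no bundle axis
and is an error. The exact convention behind published interface angles is
rarely printed; this one reproduces the generator's constructed angles
exactly and is symmetric under subunit relabeling.

**PHY centroid distance and opening angle Ω.** The centroids are the Cα
centroids of the two PHY ranges; the vertex is the midpoint between the
C-terminal Cα of the helix-3-role range of subunit A and the helix-6-role
range of subunit B ("a point between the ends of helices three and six" —
the midpoint of the terminal Cα atoms is the one deterministic reading);
Ω is the angle the centroids subtend there, d-centroids their distance.

**PHY rotation and translation.** Stage 1 pairs and iteratively fits the
PAS–GAF core Cα of the mobile chain onto the reference chain; stage 2
applies that transform to the whole mobile chain and fits the PHY pairs;
the PHY rotation is the rotation angle of the stage-2 transform and the
translation is the PHY centroid shift remaining after stage 1 (over paired
residues). Dimers have two subunits but reports print a single value: the
first paired subunit is reported and the second logged in the row's flags,
matching the single-value convention of published comparison tables. Chain
correspondence between differently labelled dimers is chosen as the
assignment with the lower core r.m.s.d.

**B-factor displacement.** `rms_displacement_from_b()` defaults to the
three-dimensional isotropic form $\sqrt{3B/8\pi^2}$, under which the ~100 Å²
mean PHY B factor of a photosensory module corresponds to ≈ 1.95 Å — the
"about 2 Å" scale of PHY-domain heterogeneity; the 1-D per-axis form
$\sqrt{B/8\pi^2}$ (≈ 1.1 Å at 100 Å²) is exposed as an option. The 3-D
form is the default precisely because it is the reading consistent with
that 2 Å figure.

## Spectra

Spectra are two-column wavelength/absorbance series on 240–800 nm grids;
rows may arrive unordered and duplicate wavelengths are averaged.
Normalization divides by the maximum within a window — default 550–800 nm,
the red/far-red band, which is how published Pr/Pfr traces are displayed —
and is idempotent and scale-invariant; unit-area or other conventions can
be had by changing the window or pre-scaling. No baseline is subtracted by
default. Difference spectra are illuminated minus dark, with the second
spectrum linearly interpolated onto the first grid over their overlap.
The absorption maximum is the grid point maximizing the 5-point running
median (robust to single-point spikes), with ties resolved by raw
absorbance — that tie-break makes detection exact for symmetric noise-free
bands, where the median plateau would otherwise bias the argmax by one
grid step. Sub-nanometre maxima such as 701.5 nm arise from 0.5 nm
instrument grids, never from interpolation; a maximum landing on a window
endpoint is flagged as monotone. Illumination wavelengths (660/740 or
700/750 nm protocols) are carried as opaque labels only.

## The synthetic generator

`make_synthetic_dimer()` builds one subunit from two ideal interface
helices (rise 1.5 Å, twist 100°, radius 2.3 Å — the canonical ~3.8 Å Cα
spacing) plus deterministic lattice point clouds for the PAS–GAF core and
the PHY domain, then places a two-fold-rotated copy as the second subunit
with the bundle axes ±φ/2 off the symmetry axis. The PHY centroids are
positioned on the isoceles solution of the vertex triangle,
$L = d/(2\sin(\Omega/2))$ from the vertex, so φ, d-centroids and Ω equal
their requested values *exactly* at zero noise; PHY rotation/translation
are applied as a rigid perturbation of the PHY ranges (both subunits, same
direction), and the realized centroid shift is recorded as ground truth.
Isotropic Gaussian noise is added last; correlated per-domain displacement
noise (lattice-heterogeneity style) is available as an option. Sequences
are random over the 20 amino acids — unambiguous for the aligner — with an
optional "homolog" mode that introduces substitutions to exercise it; the
sequence seed and the noise seed are separate so that two "crystals" of
the same molecule can share a sequence but not noise. Everything is
bit-reproducible given the spec and seeds.

Defaults are the study conditions: 516 residues per subunit with the core
boundary at 325, φ = 46°, d-centroids = 30 Å, Ω = 54°.

What the generator does *not* emulate: folded protein topology, the
chromophore and its chemistry, crystallographic disorder beyond Gaussian
noise, and sequence divergence patterns of real homolog families. Passing
the recovery suite therefore demonstrates that the measurement pipeline is
correct and noise-stable on rigid-body ground truth — it does not by
itself validate descriptor values on real depositions, which additionally
depend on domain-range and helix-range choices in the configuration.

## Numerical choices and problem sizes

Tolerances used by the validation suite: superposition r.m.s.d. within
$10^{-9}$ Å of the quaternion oracle (1,000 instances); all dimer
descriptors recovered within 0.5°/0.1 Å at zero noise and 3°/1 Å at 0.3 Å
noise over 50 seeded generators at full size (516 residues/subunit);
alignment scores equal to exhaustive enumeration on 200 random short
pairs; normalization idempotent to $10^{-12}$; λmax exact on noise-free
half-nanometre grids. The analysis scripts use a five-structure set at
0.05 Å noise and half-nanometre spectral grids; all of it runs in seconds
on one core.

## Known limitations

No flexible or elastic superposition, TM-score, or hinge-screw
decomposition; no anisotropic B factors; no NMR multi-model support; no
assembly inference from space-group symbols; no global decomposition of
spectra into pure Pr/Pfr basis spectra and no photokinetics. The interface
offset angle follows this package's bundle-axis convention — when
comparing against values produced by other conventions, expect agreement
only to a few degrees, and calibrate the interface-helix ranges in the
configuration first.
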