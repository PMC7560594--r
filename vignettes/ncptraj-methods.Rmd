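---
title: "Geometric descriptors of abasic-site dynamics in nucleosomal DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric descriptors of abasic-site dynamics in nucleosomal DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncptraj)
```

`ncptraj` quantifies how abasic lesions (the deoxyribo-type AP site and
its tetrahydrofuran analog THF) behave inside nucleosomal DNA: whether the
lesion leaves the base stack, whether the orphan base opposite it is
ejected, how bent the damaged section is, which charged histone-tail
groups dwell near the damage, which conformational families the ensemble
visits, and which residues dominate the collective motions. This vignette
is the package's own account of each method, its assumptions, the
parameters that matter, and the choices made where the design was open.

## The analysis section

Analyses operate on a double-stranded section around the damaged site:
a 15-bp window of which the central 13 bp are analyzed
(`extract_section(trim = 1)`), the flanking pair absorbing end fraying.
Residue numbering is crystallographic: strand I runs `1..n` 5'→3', strand
J `n+1..2n` in its own 5'→3' direction, so residue `i` pairs with
`2n+1-i`. All interfaces use these 1-based PDB residue numbers.

## Two-state descriptors and their thresholds

**Extrahelicity.** A lesion is extrahelical in a frame when the distance
between its C1' atom and the facing nucleotide's C1' atom exceeds
`extrahelical_c1p_threshold` (default 14 Å). The criterion is defined on
C1' because abasic residues retain the anomeric carbon although the base
is gone. The reported quantity is the percentage of frames above
threshold — a percentage of time, not necessarily consecutive, hence
invariant under frame permutation. Threshold comparisons are strict
(`>`): a frame exactly at threshold counts as intrahelical. Lowering the
threshold can only increase the percentage (monotonicity), which the test
suite asserts.

**Orphan-base ejection.** The descriptor is the distance between
mass-weighted centers of the orphan base and of its former Watson-Crick
partner, classified ejected above `ejection_com_threshold` (default
10 Å). The atom subset of the center is a genuine design choice: with
strictly nucleobase heavy atoms, ideal Watson-Crick geometry places the
two centers 5.9 Å apart — the purine center lies ~2.0 Å behind N1 and the
pyrimidine center ~1.1 Å behind N3, across a 2.8 Å central hydrogen bond,
so a 6.8 Å strict-base reference is geometrically unreachable in a
canonical pair. Because the field's customary canonical-pair reference
for this descriptor is 6.8 Å, the package calibrates the default subset
to it: nucleobase heavy atoms plus the two sugar atoms at the base
attachment (C1', C2'), which yields 6.74 Å on the deterministic builder's
dA:dT pair. The subset is configurable (`subset = "base"` gives the
strict nucleobase variant and errors on abasic residues, which have no
base).

**Coupling.** `correlate_indicators` reports the phi coefficient —
Pearson correlation of the two boolean indicator series — between
extrahelicity and ejection. Phi is undefined when an indicator is
constant; the function then returns `NA` with a warning rather than a
number.

**Replicate aggregation.** Occupancy tables aggregate replicates with an
equal-weight arithmetic mean (replicates have equal length by design),
rounded half-away-from-zero to one decimal, rounding applied last. Base
R's round-half-even does not reproduce printed one-decimal tables, which
is why `round_half_up` exists.

## Bend angle

The package's bend angle is deliberately simplified — it is not a full
helicoidal-parameter analysis. Each base pair defines a plane through its
nucleobase heavy atoms (either residue suffices when the other is
abasic); the plane normal, oriented along the 5'→3' progression, is the
local helix-axis direction. The bend of a section is the angle between
the normals of its first and last base pair, in `[0, 180)`.

Normals were chosen over base-pair *center* constructions after the
latter failed quantitatively: C1'-midpoint centers wobble helically at a
~2.5 Å radius, so short line fits through them read a phantom bend of
~13° on an ideal straight duplex and systematically under-recover
designed arcs, while curvature fits on phase-averaged axis points are
ill-conditioned on a 15-bp span. Base-pair normals carry no twist phase:
on the ideal straight builder duplex every normal equals the helix axis
(measured bend 0.03°), and designed arcs of 27°, 55° and 60° are
recovered to better than 0.1° without noise, and within ±2° at 0.3 Å
coordinate noise. With per-frame noise the estimate has ~1–4° spread,
which is why the series is reported as mean ± sd. An optional
`end_pairs > 1` averages several terminal normals (rescaled by
`(n-1)/(n-end_pairs)`, exact for uniform curvature) to damp noise.

`bend_arc` provides the matching ground truth: it transports each base
pair rigidly onto a planar circular arc whose end-tangent angle equals
the requested value, preserving within-pair geometry exactly.

## Contact residence

A charged group is in contact with the damaged site in a frame when the
minimum distance between any group atom and any site atom is strictly
below `contact_cutoff` (default 6 Å). The damaged-site atom set defaults
to all heavy atoms of the abasic residue including backbone and
phosphate — the inclusive reading; narrower conventions can be expressed
by passing explicit atom indices. Charged groups are lysine NZ, arginine
NE/NH1/NH2, and the N-terminal backbone amine of each chain; arginines
are detected even though published residence tables often report only
Lys/N-term pairs, since the pair list passed to `contact_table` selects
what is reported.

## Clustering and representatives

Frames are compared by RMSD after per-pair optimal (Kabsch)
superposition over the heavy atoms of the 13-bp section. RMSD after
independent superposition need not satisfy the triangle inequality; the
matrix is used as a dissimilarity, not a metric. Clustering is
average-linkage hierarchical clustering — deterministic given the matrix
— cut either at a height `eps` (default 2.5 Å) or into a fixed `k`;
clusters are relabelled by decreasing size so cluster 1 is the dominant
conformation, and each cluster is represented by its medoid (minimum
mean RMSD to the other members, lowest frame index on ties).

## Internal-coordinate PCA and per-residue importance

Cartesian-coordinate PCA depends on a global superposition; internal
coordinates avoid that. The feature vector of a frame holds, for every
unordered residue pair in the selection, the inverse distance between
residue geometric centers (unweighted heavy-atom means), in stable
lexicographic pair order. The covariance matrix over frames is
diagonalized; eigenvalues are clamped at zero within numerical
tolerance, and a model with zero total variance is flagged degenerate.
Centering is per trajectory; concatenating replicates before fitting is
possible but not the default.

Per-residue importance maps component loadings back to residues: for the
first `n_components` (default 10) components, each pair feature's
loading contributes to both of its residues, weighted by normalized
eigenvalues, and the per-residue sums are normalized to percentages
summing to 100.

Two mappings are implemented. The variance-contribution reading uses
squared loadings; the default uses absolute loadings. The default was
switched to absolute after a systematic failure of the squared variant
on ground-truth data: with inverse-distance features, a nucleobase
flipping out of its stack creates one dominant feature — its distance to
the stacking neighbour — and squaring concentrates the leading component
almost entirely on that single shared feature, so the *neighbour* of the
moving base ranks above a base-less abasic lesion no matter how far the
lesion itself swings (scans over flip amplitudes 110–140° and outward
shifts 0.5–9 Å never changed the ranking). Absolute loadings aggregate
the many coordinated, individually moderate feature changes of a moving
residue; on coupled lesion/orphan trajectories they rank the two
flip-driven residues on top at default generator settings, which is the
behavior a per-residue importance map is meant to have. The squared
variant remains available via `loading = "squared"`. Either way,
residues adjacent to a moving base legitimately receive elevated scores
— their environment genuinely changes — so importance maps should be
read as highlighting regions, not isolated residues.

## The synthetic generator: what it emulates, and what it does not

The generator produces ground-truth ensembles with the statistical
structure the analyses assume, not physical trajectories.

- **Canonical B-DNA.** Idealized nucleotide geometries are placed into
  Watson-Crick pair frames (C1'–C1' 10.87 Å, glycosidic bonds at 54.5° to
  the C1'–C1' line, central hydrogen bond 2.82 Å solved in-plane per base
  pair), stacked at 3.38 Å rise and 36° twist — fiber-model conventions.
  Backbone continuity between steps is approximate (the sugar conformer
  is placed rigidly per residue); analyses here depend on per-residue
  atom positions, not on bonded backbone geometry.
- **Lesions.** `apply_lesion` removes the nucleobase and renames the
  residue; AP additionally carries an O1' hydroxyl pseudo-atom on the
  former glycosidic vector — the single-atom structural difference
  between AP and THF in this representation.
- **Flipping.** The extrahelical conformer rotates the residue about the
  axis through its flanking backbone phosphates (default 110°) and then
  shifts it rigidly away from the facing C1' (default 3.5 Å). Pure
  rotation about that axis cannot move C1' more than ~4 Å from its
  helical position — short of a comfortable margin over the 14 Å
  criterion — hence the added shift, which guarantees templates cross
  the thresholds by ≥2 Å so that label/classification agreement is
  testable (≥99% at noise ≤0.3 Å).
- **Kinetics.** Per-site two-state dynamics: a first-order Markov chain
  (`p_out`, `p_in`; stationary occupancy `p_out/(p_out+p_in)`) or an
  exact-fraction mode placing `round(fraction·n_frames)` extrahelical
  frames evenly spaced — deterministic, non-contiguous, exercising the
  percentage-of-time bookkeeping. Coupled sites (the inchworm-like
  lesion/orphan correlation) follow one hidden chain with independent
  per-frame emission errors; the mechanism is a correlation device, not a
  physical model.
- **Contacts.** A scripted probe (Lys-like bead or N-terminal amine) is
  placed at an exact distance from the nearest site heavy atom during
  episodes and far away otherwise, so designed residence percentages are
  recovered exactly.
- **Noise.** Isotropic Gaussian per-coordinate noise. Real MD noise is
  correlated and anisotropic; synthetic tests therefore validate
  bookkeeping and estimator behavior, not force-field realism. Passing
  them says nothing about the biology of real trajectories — only that
  the descriptors measure what they claim to measure.
- Superhelical wrapping of the full ~145-bp nucleosomal path is not
  simulated; sections are generated directly, since every analysis
  operates on 15/13-bp sections. Arbitrary sequences are accepted;
  `tetramer_sequence` builds the alternating dA-dT / dC-dG tetramer
  pattern typical of designed nucleosomal constructs without claiming
  any specific crystal's sequence.

All stochastic output is fixed bit-for-bit by the seed.

## Numerical choices and degenerate inputs

- Kabsch superposition uses the SVD construction restricted to proper
  rotations; fewer than 3 atoms or a (nearly) collinear selection is an
  error. The test suite cross-checks against an independent
  quaternion-method implementation to 1e-8 Å.
- Unknown elements are a hard error during mass lookup — a silent
  unit-mass fallback would corrupt every center-of-mass quantity.
- Distance series must be positive and finite; empty series,
  length-mismatched indicator pairs, empty atom selections (e.g.
  base-only on an abasic residue) and out-of-range thresholds all raise
  informative errors rather than propagating NaN.
- Cluster labels are deterministic: average linkage on a fixed matrix,
  ties in medoid selection broken by the lowest frame index.
- Abasic residue names are normalized through an explicit alias table
  (`AP`/`AB`/`3DR` → AP; `THF`/`F`/`ORP` → THF) because force-field and
  PDB dialects disagree; file readers preserve names verbatim.

## Problem sizes used in the shipped tests

The suite exercises 15-bp duplexes (≈600 atoms) with trajectories of
50–2000 frames, pairwise-RMSD clustering at up to 250 frames, and a
10^5-frame state-sequence run for the Markov stationary-occupancy check;
these sizes give sub-minute suite runtimes while leaving every statistic
far from its small-sample regime.

## Known limitations

- The bend angle is a two-point axis measure; it does not decompose
  curvature into roll/tilt steps and is not comparable in detail to
  full helicoidal analyses, only in trend.
- The generator's backbone is not covalently continuous between
  residues, so bonded-term analyses (e.g. backbone torsions) are out of
  scope.
- Inverse-distance PCA emphasizes short distances by construction;
  importance maps are relative within the analyzed selection and should
  not be compared across different selections.
- Residence frequencies use a single cutoff; no smoothing or
  dwell-time analysis is performed.
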