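# ncptraj

Trajectory analysis of abasic-site dynamics in nucleosome core particles.

Abasic (apurinic/apyrimidinic, AP) sites are among the most frequent DNA
lesions. Inside a nucleosome core particle (NCP) their behavior differs
sharply from naked DNA: the lesion can flip out of the double helix
("extrahelicity"), the orphan base left without a Watson-Crick partner can
be ejected, and positively charged histone-tail amines that dwell near the
damaged deoxyribose are the geometric precursors of DNA-protein
cross-links. `ncptraj` computes the standard geometric descriptors of these
phenomena from molecular-dynamics-style trajectories, and ships a
deterministic synthetic-trajectory generator so every descriptor can be
validated against known ground truth. It does **not** run molecular
dynamics; it analyzes (real or synthetic) conformational ensembles.

## Descriptors

For a damaged site with lesion residue *L*, facing residue *F*, orphan base
*O* and its former partner *P*:

- **Extrahelicity** — the percentage of frames (not necessarily
  consecutive) with `d(C1'_L, C1'_F) > 14 Å`. Abasic residues retain C1',
  so the criterion applies to AP and THF alike.
- **Orphan-base ejection** — the percentage of frames with
  `d(COM_O, COM_P) > 10 Å`, where COM is the mass-weighted center of the
  nucleobase heavy atoms anchored at the sugar attachment (C1', C2'); on a
  canonical built B-DNA pair this descriptor sits at the 6.8 Å reference.
- **Indicator coupling** — the phi coefficient (Pearson correlation of the
  two boolean indicator series) between extrahelicity and ejection.
- **Bend angle** — a simplified section curvature: the angle between the
  nucleobase-plane normals of the first and last base pair of the analysis
  section, reported per frame as mean ± sd.
- **Contact residence** — the percentage of frames in which a charged
  group (Lys NZ, Arg guanidinium, or an N-terminal amine) lies within 6 Å
  (minimum atom-atom distance) of the damaged residue's heavy atoms.
- **Clustering** — average-linkage hierarchical clustering of the pairwise
  RMSD matrix (Kabsch superposition per pair) of the 13-bp section, with
  cluster occupancies and medoid representative frames.
- **Per-residue importance** — PCA on internal coordinates (inverse
  distances between residue geometric centers); each residue's score
  aggregates the eigenvalue-weighted loadings of all pair features that
  contain it over the first 10 components, normalized to percentages.

Replicate tables aggregate with an equal-weight mean, rounded
half-away-from-zero to one decimal (`aggregate_replicates`), matching the
arithmetic of published occupancy tables.

## Worked example

Three synthetic replicates of a 15-bp duplex with an AP lesion at position
8 and a coupled orphan base, analyzed end to end:

```r
library(ncptraj)

st   <- build_bdna("GCGCATAACGCGCAT")
ap   <- apply_lesion(st, 8, "AP")
spec <- duplex_site_spec(ap, 8)

flips <- list(
  flip_spec(8,  "I", name = "lesion", mode = "markov",
            p_out = 0.03, p_in = 0.06),
  flip_spec(22, "J", name = "orphan", couple_to = "lesion",
            emission_error = 0.05))
trs <- lapply(1:3, function(i)
  simulate_flip_dynamics(ap, flips, n_frames = 2000, seed = i,
                         noise_sigma = 0.2))
names(trs) <- paste0("MD", 1:3)

extra <- sapply(trs, function(tr)
  extrahelicity_percent(c1p_distance_series(tr, spec)))
aggregate_replicates(extra)
#> All: 37.1%  (MD1: 27.9, MD2: 42.8, MD3: 40.6)

com <- com_distance_series(trs[[1]], list(chain = "J", resno = 22),
                           list(chain = "I", resno = 9))
ejection_fraction(com)                       # 29.6 (% of MD1 frames)
correlate_indicators(c1p_distance_series(trs[[1]], spec), com, 14, 10)
#> 0.85                                      # lesion/orphan coupling

sec <- extract_section(trs[[1]], spec, trim = 1)   # central 13 bp
sub <- ncp_trajectory(sec$topology, sec$coords[, , seq(1, 2000, 20)])
cluster_frames(pairwise_rmsd(sub), k = 2)
#> <cluster_result> 2 clusters: #1 73.0% (medoid 11), #2 27.0% (medoid 46)

residue_importance(pca_fit(pair_features(sec)))
#> <residue_importance> 26 residues, 10 components;
#>   top: J:22 36.8%, I:8 13.5%, J:21 10.6%, J:23 6.2%, I:9 3.5%
```

The aggregated extrahelicity (37.1%) is the equal-weight replicate mean;
its per-replicate values track the Markov stationary occupancy
`p_out/(p_out+p_in) = 33%` up to finite-run fluctuation. The strong phi
(0.85) reflects the built-in coupling between lesion flipping and orphan
ejection, and the importance map ranks the two flip-driven residues
(orphan J:22, lesion I:8) on top.

A config-driven front end covers the same workflow from the shell:

```sh
inst/exec/ncptraj analyze --config run.yml --out results/
inst/exec/ncptraj simulate --config run.yml --out trajectories/
inst/exec/ncptraj selfcheck
```

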