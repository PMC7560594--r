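Package: ncptraj
Title: Trajectory Analysis of Abasic-Site Dynamics in Nucleosome Core Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric descriptors for the conformational dynamics of abasic
    (AP) and tetrahydrofuran (THF) lesions in nucleosomal DNA: extrahelicity
    from C1'-C1' distances, orphan-base ejection from nucleobase
    center-of-mass separation, a simplified section bend angle from base-pair
    plane normals, residence frequencies of charged histone-tail groups near
    the damaged site, RMSD clustering of trajectory ensembles with cluster
    occupancies and representative frames, and per-residue importance maps
    from a principal component analysis of inverse pairwise residue
    distances. Includes a deterministic canonical B-DNA builder and a
    synthetic trajectory generator with controllable two-state base-flipping
    kinetics, coupled lesion/orphan ejection, scripted histone-tail contact
    episodes and designed duplex bends, so that every analysis stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
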