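Package: addsim
Title: Structural Profiling, Similarity and Clustering of Polymer Additives
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Cheminformatics toolkit for profiling polymer additives
    (antioxidants, UV stabilizers, quenchers and photoinitiators) from 2D
    molecular structures. Provides a light molecular-graph model with SMILES
    and SDF V2000 input/output, a structural census (molecular formula,
    weight, atom, functional-group and ring counts), Ertl topological polar
    surface area and Wildman-Crippen style LogP/molar-refractivity
    descriptors, Carhart atom-pair fingerprints with Tanimoto similarity,
    an exact and mismatch-tolerant maximum-common-substructure search with
    overlap and Tanimoto coefficients, binning and hierarchical clustering
    with cophenetic linkage selection, internal and stability validity
    indices, bootstrap Jaccard cluster stability, and LogP/TPSA
    environmental-risk flagging. Ships the 24-compound additive study set
    together with seeded synthetic generators and brute-force oracles for
    testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    ChemmineR,
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, Clustering, StructuralPrediction
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'addsim-package.R'
    'atompairs.R'
    'bootstrap.R'
    'census.R'
    'clustering.R'
    'crippen.R'
    'descriptors.R'
    'elements.R'
    'emit.R'
    'fixtures.R'
    'mcs.R'
    'oracle.R'
    'pipeline.R'
    'rings.R'
    'risk.R'
    'sdf.R'
    'smiles.R'
    'synthetic.R'
    'tpsa.R'
    'validity.R'
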