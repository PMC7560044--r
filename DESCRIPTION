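Package: quinsar
Title: CoMSIA-Style 3D-QSAR Modelling of Quinolone Plasma Protein Binding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model the plasma protein binding rate (log fb) of
    quinolone antibacterials with comparative molecular similarity index
    (CoMSIA) fields and partial least squares (PLS) regression. The package
    prepares and aligns small molecules on a shared 4-oxo-quinoline-3-
    carboxylate core, computes five Gaussian similarity-index fields (steric,
    electrostatic, hydrophobic, hydrogen-bond donor and acceptor) on a
    rectangular lattice, fits leave-one-out cross-validated PLS models,
    performs external validation via predictive r-squared, derives
    STDEV*COEFF contour maps for substituent design, enumerates trovafloxacin
    derivative libraries, and provides the post-modelling arithmetic used in
    multi-endpoint screening: binding-rate conversion and relative-change
    tables, Gibbs-energy conversion, vibrational stability checks,
    protein-ligand contact classification, and trajectory RMSD/RMSF
    summaries. A seedable synthetic-data generator with planted linear
    field-activity relationships makes every stage testable without external
    inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with rdkit, used for 3-D conformer
    embedding, UFF minimization, Gasteiger charges and Crippen atomic logP
    contributions via inst/python/molprep.py
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'align.R'
    'comsia.R'
    'pls.R'
    'contour.R'
    'validation.R'
    'endpoints.R'
    'molprep.R'
    'fixtures.R'
    'pipeline.R'
    'synthetic.R'
    'trajectory.R'
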