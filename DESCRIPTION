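Package: qsar3d
Title: Ligand-Based 3D-QSAR with CoMFA and CoMSIA Molecular Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ligand-based three-dimensional quantitative
    structure-activity relationship (3D-QSAR) modelling of small-molecule
    series. Reads SDF/MOL2 structures and activity tables, assigns
    Gasteiger (PEOE) partial charges, superposes molecules on a template
    by common-substructure Kabsch fitting, evaluates CoMFA probe
    interaction fields (Lennard-Jones and Coulomb) and CoMSIA Gaussian
    similarity-index fields on a rectangular lattice, fits partial least
    squares (PLS) models with leave-one-out cross-validation and external
    predictivity statistics, searches all field combinations, and extracts
    stdev*coeff contour maps. Includes a synthetic-data generator with a
    planted field-to-activity relationship for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
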