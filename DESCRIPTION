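Package: ppisite
Title: Protein-Protein Interface Residue Prediction with mRMR Feature
    Ranking, Incremental Feature Selection and Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-based prediction of protein-protein interaction (PPI)
    interface residues. Parses PDB structures, computes per-residue
    solvent-accessible surface area by the Shrake-Rupley method, and labels
    surface residues (relative accessibility above 25%) and interface
    residues (monomer-to-complex burial of at least 1 squared Angstrom).
    Encodes each residue as a 40-component vector (Atchley factors, PSSM
    conservation scores, secondary-structure one-hot, disorder score, and a
    block of 3D structural descriptors) and builds classification samples
    from single residues, sliding sequence windows, or spatial patches of
    nearest residues. Features are ranked by minimum-redundancy
    maximum-relevance (mRMR) mutual information, an optimal subset is chosen
    by incremental feature selection maximizing the Matthews correlation
    coefficient under cross-validated random forests, and class imbalance is
    handled by repeated balanced undersampling with averaged metrics. A
    synthetic-data module generates toy dimer structures and feature tables
    with planted signal for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    ranger,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
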