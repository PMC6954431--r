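Package: sugarcdl
Title: Conformation-Dependent Stereochemical Restraints for Nucleic Acid Sugars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates conformation-dependent bond-length and bond-angle
    restraints for the ribose/2'-deoxyribose moiety of DNA and RNA. Sugar
    fragments are extracted from PDB or mmCIF coordinate files, their
    pseudorotation phase (P) and amplitude (tau_m), glycosidic torsion (chi)
    and side-chain torsion (gamma) are measured, and each fragment is assigned
    targets from a conformation-dependent library: fixed group means, linear
    functions of the pucker amplitude for the endocyclic ring angles, and
    180-degree-periodic functions of chi for the glycosidic link. Restraints
    are written in REFMAC, PHENIX and SHELXL dialects. The package also
    implements the statistical pipeline that derives such a library from a
    fragment-geometry table (robust modified Z-score outlier rejection, Welch
    subgroup discovery, Spearman functional screening, Gaussian-process and
    Bayesian-ridge fitting), together with a synthetic fragment-table
    generator used for closed-loop testing, and a validation layer that
    scores a coordinate model against a restraint dictionary.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
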