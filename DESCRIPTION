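Package: eqshift
Title: E(3)-Equivariant Graph Attention Networks for Carbohydrate NMR
    Chemical Shift Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts isotropic 13C and 1H NMR chemical shifts of
    carbohydrates (and other small organic molecules) from molecular
    structure with an E(3)-equivariant graph self-attention network
    built on irreducible-representation features and tensor-product
    message passing. Molecules enter as SMILES; diverse low-energy
    conformer ensembles are generated with distance geometry and ranked
    by MMFF94 energy; predictions are averaged over the ensemble, which
    also yields a per-shift uncertainty. Includes masked-MAE training
    with conformer-ensemble data augmentation, stratified ten-fold
    cross-validation, structure-exclusion splits, and a synthetic
    E(3)-invariant shift oracle for end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python'
    on the PATH (used for SMILES parsing, ETKDGv3 conformer embedding
    and MMFF94 energies).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
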