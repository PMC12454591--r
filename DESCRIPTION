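Package: dnadduct
Title: Untargeted LC-MS Screening and Targeted Analysis of DNA Adducts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A screening pipeline for DNA adductomics from centroided
    data-dependent-acquisition LC-MS runs of enzymatically digested DNA.
    Covers elemental-formula mass arithmetic and enumeration of candidate
    adducts from the deoxyribose + base + xenobiotic subunit logic, mzML
    input/output, extracted-ion-chromatogram feature finding and alignment,
    treated-versus-control volcano selection with one-way ANOVA and Tukey
    post-hoc testing, adduct verification by diagnostic fragment ions,
    deoxyribose neutral loss and in-source fragment pairing, design of
    targeted MRM transition lists, external calibration, normalization of
    adduct levels to deoxyguanosine content, and a deterministic simulator
    of digested-DNA LC-MS studies with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
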