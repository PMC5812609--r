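Package: ibsa
Title: Image-Derived Body Surface Area from CT with Dose-Banding Impact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic measurement of body surface area from CT volumes
    (iBSA): threshold-plus-morphology body segmentation, iso-surface meshing and
    physical-unit surface-area integration. Companion tooling covers the five
    classical anthropometric BSA formulas (Du Bois, Mosteller, Haycock, Boyd,
    Gehan & George) with first-order error propagation, method-comparison
    statistics (percent relative error, Bland-Altman bias/SD/limits of
    agreement, bootstrap confidence intervals, F- and t-tests), a Monte Carlo
    simulation of chemotherapy dose-band reclassification driven by
    BSA-assessment error, and a synthetic phantom factory with analytically
    known surface areas for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'bsa_formulas.R'
    'ct_io.R'
    'dicom.R'
    'dose_banding.R'
    'ibsa-package.R'
    'mesh.R'
    'metaimage.R'
    'method_comparison.R'
    'phantoms.R'
    'reports.R'
    'segmentation.R'
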