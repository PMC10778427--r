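Package: hypoxmap
Title: Mapping Brain Tumor Hypoxia and Vasculature from Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise mapping of brain tumor oxygenation and vasculature
    from quantitative MRI, with a fully synthetic validation phantom. Fits the
    streamlined quantitative BOLD (sqBOLD) signal model to FLAIR-prepared
    asymmetric spin echo (FLAIR-ASE) data to estimate the reversible
    transverse relaxation rate (R2'), deoxygenated blood volume (DBV) and
    oxygen extraction fraction (OEF); derives leakage-corrected, white-matter
    normalized cerebral blood volume (CBV) and Kiselev-model vessel size maps
    from dual-echo dynamic susceptibility contrast (DSC) series; selects
    percentile-defined biopsy target clusters on the resulting maps;
    quantifies per-biopsy histology (vessel density, vessel diameter,
    HIF-1alpha H-score); and compares MRI against histology with
    Kruskal-Wallis, Mann-Whitney and Spearman tests. A labelled digital brain
    phantom generates every raw input with known ground truth so that each
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
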