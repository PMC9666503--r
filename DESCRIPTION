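Package: qsipr
Title: Taxon-Specific Growth Estimation from Heavy-Water Quantitative
    Stable Isotope Probing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates taxon-specific bacterial growth potential from
    H2-18O quantitative stable isotope probing (qSIP) experiments.
    Takes per-fraction density, DNA concentration, qPCR totals and
    amplicon (16S rRNA gene ASV) counts from CsCl density-gradient
    fractionated samples, computes weighted-average buoyant densities,
    GC-corrected 18O atom fraction excess, and linear growth rates per
    taxon, with replicate-level bootstrap confidence intervals and
    activity classification. Includes treatment-comparison ratio
    statistics (Wilcoxon signed-rank with Benjamini-Hochberg
    correction), qSIP-filtered community diversity, growth-efficiency
    summaries, and a forward simulator of the full gradient experiment
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
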