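Package: fndconn
Title: Weighted-Degree Connectome Statistics for Case-Control Diffusion MRI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of structural connectomes in case-control
    designs, built around the weighted-degree (node strength) summary of
    fractional-anisotropy-weighted brain graphs. Provides covariate-adjusted
    directional group comparisons at node and link level with Benjamini-Hochberg
    false discovery rate control, hierarchical restriction of link findings to
    significant node origins, partial-correlation analysis between adjusted
    weighted degree and clinical severity scores, and a synthetic cohort
    generator with planted nodal effects, mood-mediated confounding and
    clinical coupling for power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
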