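Package: hrdkit
Title: Homologous Recombination Deficiency Scoring and Platinum Response
    Analysis for PDX Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking genomic homologous-recombination-deficiency (HRD)
    scoring to platinum response in patient-derived xenograft (PDX) models.
    Implements large-scale genomic alteration (LGA) calling from binned
    shallow whole-genome copy-ratio profiles (penalized change-point
    segmentation, per-profile minimal copy-number-alteration cutoff, segment
    merging, per-arm break counting), the allele-specific scar scores LOH,
    TAI and LST, tumour-volume response metrics (BestResponse,
    BestAvgResponse, CR/PR/SD/PD classification), RAD51 foci scoring,
    somatic variant filter cascades, fusion-derived deletion detection with
    median-of-ratios normalization, the contingency and survival statistics
    used for biomarker association, and a fully seeded synthetic-cohort
    generator with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    DESeq2
Config/testthat/edition: 3
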