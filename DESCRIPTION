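Package: crmscreen
Title: Computational Readout for Crude-Reaction-Mixture Screening Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis layer for high-throughput crude-reaction-mixture (CRM)
    screening campaigns that couple robotic array synthesis with LC-MS quality
    control and crystallographic readout. Enumerates multi-step reaction arrays
    into expected products with exact-mass and adduct bookkeeping, performs
    MSCheck-style quality control of mzML runs (total-ion-chromatogram peak
    finding, expected-ion matching, success verdicts, reconciliation against
    human annotations and confusion summaries), clusters products by Tanimoto
    fingerprint similarity, assigns stereochemistry from replicate event-map
    densities via mean-positive-density bond profiles and a paired t-test, and
    produces campaign funnel and resource-accounting reports. Includes a
    synthetic-data generator for labelled LC-MS campaigns and density-grid
    fixtures so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml,
    ape,
    mzR,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: python (>= 3.8) with RDKit, used for SMILES
    canonicalization, reaction-SMARTS application and Morgan fingerprints.
Config/testthat/edition: 3
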