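Package: sdtmbridge
Title: Convert Annotated ODM Exports to CDISC SDTM and Integrate Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts clinical-research databases exported in the CDISC
    Operational Data Model (ODM 1.3) format into Study Data Tabulation
    Model (SDTM) domain datasets plus a Define-XML 2.0 metadata document.
    Field-level SDTM mapping triples (domain, variable, test code) embedded
    in the export drive the conversion: controlled-terminology recoding,
    ISO 8601 date normalization, the horizontal-to-vertical pivot for
    findings domains, supplemental qualifiers, and sequence-number
    assignment. Independently mapped studies can then be integrated into a
    single SDTM database with a metadata consistency report of the items
    common to all studies. Includes a synthetic multi-cohort generator for
    end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
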