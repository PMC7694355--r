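Package: tempolink
Title: Patient-Specific Temporal Record Linkage for Emergency Department
    and Hospital Admission Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic, patient-specific record linkage between
    emergency department (ED) visit records and hospital admission
    episode records using temporal proximity rules. Classifies candidate
    visit-episode pairs into six temporal link categories, prunes them to
    a one-to-one matching by shortest absolute arrival-admission time
    difference, chains sequential admissions joined by planned transfers
    into continuous episodes of care, and audits linkage quality against
    ED departure-status and hospital admission-type disposition codes.
    Includes a synthetic frequent-presenter cohort generator with planted
    ground truth so every pipeline stage can be exercised without access
    to protected administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
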