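Package: ehrwas
Title: EHR-Wide Association Scan for New-Onset Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An electronic-health-record-wide association scan around
    new-onset atrial fibrillation (AF). From coded longitudinal primary- and
    secondary-care records the package identifies incident AF cases, samples
    age- and sex-matched controls under incidence-density (risk-set)
    constraints, counts condition-specific healthcare contacts in five-year
    windows before and after the index date, ranks conditions by the
    case/control frequency ratio with balanced-bootstrap percentile
    confidence intervals, classifies conditions into fourteen disease
    groups, and renders the four-panel polar "iris" plot. A synthetic-EHR
    generator with planted effect sizes provides ground truth for testing
    every stage without access to restricted registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
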