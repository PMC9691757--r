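Package: rpmecon
Title: Financial Planning for Algorithm-Enabled Remote Patient Monitoring in
    Pediatric Type 1 Diabetes Clinics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic decision model for the clinic-level economics of
    adopting algorithm-enabled remote patient monitoring (RPM) based on
    continuous glucose monitor (CGM) data review in a pediatric type 1
    diabetes practice. Computes the fee-for-service base case (education
    revenue, CDCES staffing and labor cost), two adoption scenarios
    (capacity-neutral repurposing of routine visits and augmented capacity),
    break-even telemedicine reimbursement rates, outcome-value offsets,
    one-way sensitivity analyses, and a seeded synthetic demand simulator
    that stress-tests the model's full-booking capacity assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
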