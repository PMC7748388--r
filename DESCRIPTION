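Package: colidose
Title: Intravenous Colistimethate Dosing Calculator for Critically Ill Adults
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes loading and maintenance intravenous colistimethate
    regimens for critically ill adult patients across renal-function strata
    and renal replacement therapies. Provides explicit conversion between the
    three colistimethate dose expressions (mg colistin base activity, million
    international units, mg colistimethate), ideal body weight (Devine) and
    Cockcroft-Gault creatinine clearance, a configurable creatinine-clearance
    banded maintenance-dose model with dialysis supplementation and a 300 mg
    CBA safety cap, a local JSON-lines calculation history, a command-line
    interface, and a synthetic mock-patient generator with an independent
    arithmetic oracle for validating the dosing engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
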