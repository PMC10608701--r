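Package: credmet
Title: Isotope-Credentialed Metabolite Annotation from Dual 13C/15N Labeled Reference Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building untargeted metabolomics annotation databases
    from dual stable-isotope (13C and 15N) labeled reference cultures measured
    by LC-MS. Peaks observed across four labeling conditions (unlabeled, U-13C,
    U-15N, U-13C+15N) are matched into co-eluting quartets whose mass shifts
    reveal the carbon and nitrogen atom counts of the underlying metabolite;
    molecular formulas are then enumerated under those atom-count constraints,
    identities assigned against a reference library in confidence tiers (RT
    match to standards, MS2 cosine match, formula only), and results from
    multiple ion sources (ESI, APCI) and polarities merged into one metabolite
    database. Includes a ground-truthed synthetic-data generator for
    four-condition labeled peak sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
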