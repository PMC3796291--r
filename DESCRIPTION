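Package: mrapkpd
Title: Indirect-Response PK/PD Modelling and Therapeutic-Index Estimation
    for Mineralocorticoid Receptor Antagonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for preclinical pharmacokinetic/pharmacodynamic analysis of
    mineralocorticoid receptor (MR) antagonists in rat nephropathy studies:
    compartmental plasma concentration models with time-varying (induced) and
    dose-dependent clearance, indirect-response turnover models linking
    exposure to urinary albumin-to-creatinine ratio (UACR) suppression and to
    double-delta serum potassium and urinary Na+/K+ endpoints, a two-stage
    (piece-wise) population estimation procedure with bootstrap confidence
    intervals, therapeutic-index calculus with protein-binding and in-vitro
    potency normalisation, and a synthetic-study generator emulating chronic
    27-day and acute single-dose designs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
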