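Package: sctape
Title: Stratum Corneum Tape-Stripping Dermatopharmacokinetics
Version: 0.1.0
Authors@R: person("sctape", "maintainers", email = "sctape@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for stratum corneum (SC) tape-stripping
    dermatopharmacokinetic (DPK) studies of topical drug products.
    Converts per-tape SC masses and pooled-group drug assays into
    concentration-depth profiles and per-site areal drug loads (Q),
    derives the input flux J = (Q_Up - Q_Cl)/dt and the first-order
    SC elimination rate constant k = -ln(Q_Cl/Q_Up)/dt, screens
    outliers with Grubbs' test, and summarises with t-based confidence
    intervals.  Companion skin-blanching (vasoconstriction assay)
    routines normalise chromameter a* readings against untreated
    control sites and integrate the response into the signed area
    above the effect curve (AAEC, 0-22 h, trapezoidal rule).  A
    noncentral-t power engine computes the power and sample size
    needed to detect fractional changes in any of these metrics.  A
    seeded synthetic-study generator (finite-membrane Fickian uptake,
    first-order clearance, lognormal tape-mass sampling, TEWL-driven
    stopping rules, LOQ censoring, and an Emax-linked blanching
    response with non-responders) makes the whole pipeline testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
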