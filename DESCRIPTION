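Package: fishbcf
Title: In Vitro Hepatocyte Clearance, IVIVE, and Bioconcentration Factor
    Prediction for Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fish bioaccumulation assessment from in vitro
    biotransformation data.  Estimates first-order substrate-depletion rate
    constants and in vitro intrinsic clearance from hepatocyte assays,
    extrapolates them to whole-body biotransformation rate constants (kB)
    through liver scaling factors, a binding correction and the well-stirred
    liver model, and predicts steady-state bioconcentration factors (BCF)
    with a kinetic mass-balance model for rainbow trout and common carp.
    Also evaluates OECD TG 305 aqueous-exposure studies (time-weighted
    average water concentrations, steady-state BCF, depuration kinetics and
    in vivo kB back-calculation) and ships a synthetic-data generator with
    known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
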