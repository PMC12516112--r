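Package: optcalib
Title: Optimal Calibration Designs for Test Items Under Ability Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Optimal experimental design for calibrating (pretesting) item
    response theory items when examinee abilities are estimated from a set of
    operational items rather than known.  Computes standardized block
    information matrices for 2PL and 3PL items under known abilities, under an
    asymptotic-normal ability posterior, or from Metropolis-Hastings posterior
    draws; derives D- and L/c-optimal allocations of calibration items to
    ability intervals by an exchange algorithm on a discretized ability axis;
    compares designs through relative D- and c-efficiencies; and runs
    parameter-recovery simulation studies of bias and mean squared error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
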