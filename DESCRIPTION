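Package: protonPBA
Title: Pencil-Beam Proton Dose Calculation in Transverse Magnetic Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical pencil-beam dose calculation for scanned proton beams
    inside homogeneous transverse magnetic fields (0-3 T), as needed for
    MRI-guided proton therapy. Combines a relativistic trajectory integrator
    with continuous Bethe-Bloch energy loss, a field-corrected
    water-equivalent depth scaling, a seven-parameter asymmetric lateral
    profile model (Gaussian core with exponentially-modified-Gaussian tails),
    subbeam splitting with dynamic center shifting, and look-up-table
    superposition. Ships a self-contained condensed-history Monte Carlo
    transport engine used both to calibrate the look-up tables and as the
    benchmarking reference, plus the full evaluation battery: integrated
    depth-dose metrics (R80 range, mean local dose difference), lateral
    profile metrics, and the gamma-index (2%/2 mm) comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
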