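Package: strandex
Title: Kinetic Analysis of Recombinase-Driven DNA Strand Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and fitting of the three-step mass-action scheme for
    recombinase-driven DNA strand exchange (presynaptic filament + donor dsDNA
    to two three-stranded intermediates to heteroduplex products), together
    with the assay-signal calibrations used by FRET pairing/displacement and
    2-aminopurine experiments, SDS-quench abortive-assay intermediate
    quantification, and fluorescence-anisotropy estimators for filament
    binding (Hill equation), association (nucleation and elongation
    velocities) and dissociation (single-exponential decay). Includes a
    seeded synthetic-data generator that emulates each assay with known
    ground truth, for estimator validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
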