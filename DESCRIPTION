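Package: helixCT
Title: Helicoidal Lattice Dynamics and Charge Transfer in Double-Stranded DNA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the low-frequency lattice dynamics of double-stranded
    B-DNA as coupled twist and radial base-pair oscillations on a helicoidal
    Peyrard-Dauxois-Bishop lattice, and the resulting charge-transfer band
    structure of a renormalized tight-binding chain whose pi-pi transfer
    integrals depend on the twist and radial coordinates. Provides the
    analytic phonon dispersion relations (acoustic and optical branches),
    characteristic frequencies and sound velocity of homopolymer duplexes, a
    time-domain integrator for the linearized equations of motion with
    helical-wave initial conditions and codon-scale collective variables, the
    phonon-modulated transfer integral, transfer-matrix band structure with
    Chebyshev matrix powers, and the phonon-induced bandgap modulation,
    together with a command-line front end to tabulate and export all derived
    quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
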