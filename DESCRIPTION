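Package: lapdose
Title: Single-Shot Dosimetry for Laser-Accelerated Proton Beamlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and reconstruction toolkit for
    broad-spectrum laser-accelerated (TNSA) proton irradiation of
    biological samples.  Provides relativistic Bethe stopping power,
    CSDA range and multiple-scattering kernels for layered targets, a
    Monte Carlo transport engine for a permanent-magnet quadrupole
    doublet with a scattering filter, radiochromic-film response
    corrections (LET quenching and dose-to-water equivalence), and the
    single-shot reconstruction protocol that recovers the exponential
    source temperature and effective charge of each laser shot from two
    or more film readings and infers the dose delivered to the sample.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
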