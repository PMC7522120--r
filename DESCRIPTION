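Package: atdosim
Title: Cellular and Microtumor Dosimetry for Intraperitoneal Astatine-211
    Antibody Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the chain from antibody-cell binding kinetics to absorbed
    dose in targeted alpha-particle therapy of intraperitoneal micrometastases
    with astatine-211-labeled antibodies. Provides a two-component reversible
    binding model with ligand depletion and wash schedules, radiolabeling
    (specific-activity) arithmetic, mono-exponential intraperitoneal
    pharmacokinetics with a mouse-to-patient translation factor, a
    reaction-diffusion model of antibody penetration into spherical
    microtumors (the binding-site barrier), seeded Monte-Carlo alpha-particle
    transport for single-cell and microtumor dosimetry, efficacy statistics
    (exact Fisher test, log-rank test, uptake regression, dual-isotope
    counting correction, organ-dose arithmetic), and seeded synthetic-data
    generators emulating every measured dataset the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
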