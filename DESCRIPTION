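Package: ddrdyn
Title: Diffusion, Binding and Recruitment Dynamics of Early DNA Damage
    Response Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of the early response to DNA
    double-strand breaks induced by ionizing radiation. Provides forward
    models of fluorescence recovery after photobleaching (FRAP) for pure
    diffusion and for diffusion-reaction with either focus-confined or
    nucleus-wide binding, together with the Stehfest numerical Laplace
    inversion they require; normalization and fitting routines that
    extract effective diffusion coefficients and binding rate constants
    from FRAP curves; mono-exponential time-constant analysis of protein
    recruitment curves versus linear energy transfer (LET); a minimal
    mass-action ODE model of MRN/NBS1-ATM-gammaH2AX-MDC1 focus formation
    with LET-scaled DSB numbers; shared-parameter fitting of that model
    across multi-LET recruitment panels; and a synthetic-data generator
    that emulates both experiment types for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
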