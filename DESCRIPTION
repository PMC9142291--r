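Package: fracsmoke
Title: Fractional-Order PLSQR Smoking Epidemic Model with the
    Atangana-Baleanu-Caputo Derivative
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and stability analysis of a five-compartment
    giving-up-smoking model (potential, occasional and heavy smokers,
    temporary and permanent quitters). Provides the compartmental vector
    field and Jacobian, disease-free and endemic equilibria, the basic
    reproduction number, eigenvalue-based local stability verdicts and
    Volterra-type Lyapunov diagnostics, together with a two-step
    product-integration scheme (Atangana-Toufik method) for the
    Atangana-Baleanu fractional derivative in the Caputo sense, a
    two-parameter Mittag-Leffler evaluator, a closed-form oracle for
    linear scalar fractional relaxation, and a classical Runge-Kutta
    reference. Scenario files, order sweeps with CSV/JSON output and a
    command-line interface make runs reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
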