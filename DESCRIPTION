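Package: spiralsaw
Title: Reduced-Order Simulation of Hybrid Spiral-Microchannel and
    Surface-Acoustic-Wave Cell Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, deterministic simulator of a two-stage label-free
    cell-separation device for circulating tumor cells: a two-loop spiral
    microchannel exploiting inertial lift and Dean drag (passive stage),
    followed by a straight section in which a standing acoustic wave traps
    cells on pressure nodal lines aligned with the outlets (active stage).
    Provides closed-form microfluidic force laws, an analytic rectangular-duct
    flow profile with a parametric Dean-vortex secondary field, Lagrangian
    particle tracing of cell ensembles, acoustophoretic trapping dynamics with
    an analytic overdamped oracle, and a config-driven hybrid pipeline with
    reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
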