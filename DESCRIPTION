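Package: rdmix
Title: Mixed-Dimensional Reaction-Diffusion Simulation on Tagged Simplicial Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles and solves coupled, nonlinear, mixed-dimensional
    reaction-diffusion systems for cell signaling: volume species in 3D or 2D
    subdomains, surface species on co-dimension-1 membranes, and trace-coupled
    fluxes between them, all defined over a single tagged simplicial parent
    mesh. Models are declared as containers of compartments, species,
    parameters and reactions with symbolic rate expressions; the system is
    discretized with continuous piecewise-linear finite elements and advanced
    in time by implicit Euler with Newton-Raphson iterations using exact
    symbolic Jacobians, adaptive time-step control and restart mediation.
    Includes mesh generators and a Gmsh MSH 4.1 reader, conservation-law model
    reduction, a well-mixed ODE reduction, threshold events, pre/post-step
    scalar coupling, post-processing to compartment averages and totals, and a
    verification suite with an analytic membrane-phosphorylation benchmark and
    mesh/time-step convergence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
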