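Package: flowmd
Title: Deferred Data-Flow Work Graphs for Ensemble Molecular Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained data-flow workflow engine for molecular
    simulation scripting: typed work graphs with deferred Futures,
    first-class simulation ensembles, wrapping of external command-line
    tools as graph operations, user-defined operations via a function
    wrapper factory, and dynamic while-loop constructs with subgraph state
    propagation. A bundled toy molecular-dynamics engine (velocity-Verlet
    integration of harmonic systems in reduced units) exercises the
    runtime extension contract: pluggable restraint forces evaluated
    inside the integration loop, stop signals with member or ensemble
    scope, and barrier-style ensemble reductions, culminating in a
    desk-scale restrained-ensemble refinement demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
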