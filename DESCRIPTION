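Package: planarcrn
Title: Qualitative Analysis of Planar Deficiency-One Mass-Action Systems
Version: 0.1.0
Authors@R: person("planarcrn", "maintainers", email = "planarcrn@example.org",
    role = c("aut", "cre"))
Description: Tools for planar mass-action systems whose reaction network has
    deficiency one: structural invariants (deficiency, weak reversibility,
    terminal strong components), existence and computation of the unique
    positive equilibrium for quadrangle cycles, chains of three reactions and
    triples of independent reactions, scaling of the equilibrium to (1,1),
    focal values (Lyapunov quantities) at a fine focus, Bendixson-Dulac,
    reversible-symmetry and Lienard center certificates, degenerate
    Andronov-Hopf parameter searches, and positivity-preserving numerical
    integration with Poincare return maps and limit-cycle witnesses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
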