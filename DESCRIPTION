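Package: fragrescue
Title: Habitat Fragmentation and Microbial Collective Defence by Enzymatic
    Toxin Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models a microbial population that defends itself collectively by
    enzymatically degrading an environmental toxin (the canonical example being
    beta-lactamase-producing bacteria exposed to a beta-lactam antibiotic), and
    asks how partitioning the habitat into many small sub-volumes changes the
    ecological outcome. Provides exact event-driven integration of the
    threshold-switched growth/death dynamics coupled to Michaelis-Menten
    degradation, the closed-form critical-density phase boundary and its
    Poisson-occupancy survival theory, a hybrid discrete-birth-death /
    continuous-antibiotic stochastic engine, a metapopulation simulator for
    fragmented habitats, and a contrasting enzymatic-foraging model in which
    enzymes release nutrients rather than remove a toxin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
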