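Package: mdsoc
Title: Emulator and Performance Model of a Special-Purpose Molecular
    Dynamics System-on-Chip
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A software model of a special-purpose molecular dynamics (MD)
    machine built from system-on-chip nodes on a 3D torus interconnect. The
    package emulates the machine's mixed-precision non-bonded force pipeline
    (32-bit fixed-point coordinates and force accumulation, ROM-table function
    evaluation, action-reaction symmetry, combination rules, soft-core van der
    Waals, group-based cut-offs), a Gaussian-split Ewald mesh solver for
    long-range electrostatics, Amber-form bonded forces with an
    operation-weighted FLOP cost model, the three packet types and latency
    model of the torus network, and an analytic per-timestep performance
    estimator. A small leap-frog MD engine with synthetic system generators
    (Lennard-Jones fluid, rock-salt lattice, toy polymer) ties the components
    into runnable microcanonical simulations with deterministic,
    order-independent force accumulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
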