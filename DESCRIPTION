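Package: oxikinet
Title: Kinetic Reaction-Network Modelling of Vegetable Oil Autoxidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of lipid autoxidation in bulk vegetable
    oils. Implements a 23-reaction radical chain network (initiation,
    propagation, hydroperoxide decomposition, peroxyl radical addition,
    termination and antioxidant scavenging) resolved per fatty acid
    (oleic, linoleic, alpha-linolenic), coupled to two-phase
    headspace-oil oxygen mass transfer. Provides stiff ODE simulation of
    storage experiments, multi-response global estimation of kinetic
    constants from NMR-style product time courses, Monte-Carlo parameter
    uncertainty, local sensitivity analysis, Arrhenius activation-energy
    estimation, cross-kinetic mixing rules for fatty-acid blends, and an
    antioxidant / critical-hydroperoxide acceleration extension, together
    with a synthetic-data generator emulating NMR-quantified oxidation
    time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
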