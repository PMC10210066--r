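Package: zincomp
Title: Competition Equilibria and Differentiated Zinc Affinities of
    Multi-Site Metalloproteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing metal-ligand competition experiments on
    multi-site zinc proteins such as metallothionein-2 (MT2).  Provides a
    mass-balance speciation solver for one divalent metal distributed among
    a multi-site receptor, competing chelators or protein sites and a free
    ion pool; step-wise, cooperative and competitivity-index estimators of
    dissociation constants from transfer observations; readout models for
    chromogenic (PAR), fluorescent (ZnAF-2F), circular-dichroism, enzymatic
    and chromatographic assays; simulators of the bias introduced by the
    single-affinity ("cooperative") stability model; and a seeded generator
    of synthetic assay datasets from a ground-truth seven-site model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
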