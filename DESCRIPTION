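Package: metsplit
Title: Optimal Enzyme Allocation and Pathway Splitting in Two-Member
    Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling and protein-cost optimization of a linear
    biosynthetic pathway shared by two bacterial cell populations that can
    exchange intermediates and end product by passive diffusion.  The package
    fits cost-minimal enzyme allocations at steady state under product
    (feedback) inhibition, maps the symmetric / cheater / metabolic
    complementation regimes over membrane permeabilities and inhibition
    strength, extends the chain to many intermediates to locate the pathway
    splitting point, performs seeded parameter sensitivity analysis, and
    predicts the biological splitting point of real pathways (e.g. tryptophan
    biosynthesis) from SMILES-derived permeability descriptors (TPSA, logP,
    molecular weight) computed with OpenBabel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    deSolve,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
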