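Package: epibarrier
Title: Epithelial Barrier Quantification and Bimodal Gene-Activity Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying epithelial tight-junction function and for
    calling transcriptionally active genes from bulk RNA-seq expression
    tables. Gene activity is decided by fitting a sum of two Gaussian
    components to the binned density of log2-transformed TPM or FPKM values
    and placing a cutoff where the active component exceeds the inactive
    component by a configurable density ratio (default 5-fold). Barrier
    physiology support covers transepithelial electrical resistance (TER)
    with blank-filter correction, apparent permeability (Papp) from tracer
    flux, transepithelial conductance from Ohm's law, and inversion of NaCl
    dilution potentials through the Goldman-Hodgkin-Katz voltage equation to
    the P_Na/P_Cl permeability ratio with cation/anion selectivity
    classification. A seeded synthetic-data module generates expression
    tables, Ussing-chamber runs, and Transwell plate assays with known truth
    so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
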