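Package: nfkblink
Title: Linking NF-kB Signaling Dynamics to Genomic Responses by Forward and
    Reverse Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Connects a signal-transduction cascade to its downstream
    transcriptional response for the IKK-IkB-NF-kB module. Reconstructs
    time-varying NF-kB transcription-factor activity and gene-wise influence
    strengths from time-series gene expression by support-constrained Network
    Component Analysis (alternating least squares on a bipartite
    regulator-target decomposition), simulates nuclear NF-kB dynamics from
    candidate time-varying IKK inputs with a compartmental mass-action kinetic
    model of the NF-kB/IkB(alpha,beta,epsilon) network, and infers the
    upstream IKK activity profile by Pearson-correlation matching of
    data-derived and simulated NF-kB profiles. Includes a synthetic-data
    generator for the full closed loop, TSV/YAML/JSON interfaces, SBML export
    of the kinetic model, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
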