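Package: sigcircuits
Title: Mechanistic Modeling of Signaling Circuit Activities from Gene
    Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms gene expression matrices into per-sample activity
    values for receptor-to-effector signaling circuits defined on signed
    pathway topologies (activation/inhibition edges). Signal is propagated
    recursively from receptors (initial intensity 1) through the circuit,
    each node attenuating by its normalized expression proxy, combining
    incoming activations multiplicatively and applying inhibitory
    attenuation. Includes the expression preprocessing chain (log
    transform, quantile truncation, quantile normalization, unit-interval
    rescaling), in-silico loss-of-function and over-expression perturbation
    simulation with a frozen normalization reference, a multi-tissue
    variant-effect scenario, Wilcoxon rank-sum differential signaling with
    Benjamini-Hochberg FDR control, deterministic synthetic fixture
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
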