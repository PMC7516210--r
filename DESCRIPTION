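Package: segnet
Title: Time-Varying Signed Gene Regulatory Networks from Two-Treatment
    Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers time-varying, signed, weighted, bidirectional gene
    regulatory networks from two-treatment time-course expression data.
    Expression plasticity (the difference between stress and control
    treatments) is fitted with Legendre orthogonal polynomial curves,
    genes are grouped into functional modules by Skellam mixture
    clustering with AIC model selection, and a game-theoretic system of
    ordinary differential equations decomposes each gene's plasticity
    into an independent component and per-regulator dependent components
    selected by a group-lasso penalty. Pairwise interactions are
    classified into an eleven-type taxonomy (synergism, antagonism,
    altruism, coexistence and directional variants), gene networks are
    linked to phenotypic-trait networks through a causal ODE layer, and
    a simulation benchmark scores edge recovery by TPR, FPR and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
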