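Package: plastidorigin
Title: Evolutionary Origin Classification of Plastid-Pathway Proteins
Version: 0.1.0
Authors@R:
    person("Plastid", "Origin Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies the evolutionary origin (vertically inherited,
    endosymbiotically acquired, laterally acquired, or uncertain) of
    nucleus-encoded plastid-pathway proteins from gene trees annotated with
    maximum-likelihood bootstrap and Bayesian posterior supports. Ships a
    registry of the three plastid-localized pathways (C5 heme, chlorophyll a,
    non-mevalonate IPP), newick input/output with dual support labels,
    N-terminal extension detection against bacterial homologs, a
    group-structured gene-family simulator under the Poisson amino-acid
    model, neighbor-joining reconstruction with nonparametric bootstrap,
    and pathway-by-species origin-type aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
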