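Package: molahc
Title: Goal-Directed Molecular Design with a SMILES Language Model and
    Augmented Hill-Climb Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemical language model over SMILES strings (a gated
    recurrent unit network trained by next-token prediction with teacher
    forcing) together with the Augmented Hill-Climb reinforcement-learning
    rule, which fine-tunes the model against a multi-parameter
    desirability reward built from a pluggable structure-based oracle,
    a synthesisability estimate, Crippen-type logP, consecutive rotatable
    bonds, and hydrogen-bond donor counts. Includes drug-like corpus
    curation (property filters, structural alerts, scaffold-cluster
    undersampling, restricted SMILES randomisation), a deterministic
    synthetic corpus generator with a mock docking oracle, and chemistry
    assessment utilities: Bemis-Murcko scaffolds, ECFP4 leader
    clustering, maximum-common-substructure chemotype mining, and
    validity/uniqueness/novelty reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
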