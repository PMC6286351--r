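Package: turnoverML
Title: Machine Learning of Enzyme Turnover Numbers for Enzyme-Constrained
    Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for predicting enzyme catalytic turnover
    numbers (in vitro kcat and in vivo kapp,max) from network, structural and
    biochemical features, and for using the predicted turnover vectors to
    parameterize an enzyme-capacity-constrained metabolic model (MOMENT) that
    predicts quantitative proteome allocation. Includes flux-balance and
    parsimonious flux-balance analysis on toy and SBML/FBC metabolic networks,
    Monte Carlo sampling of growth environments, MFA-constrained flux fitting,
    thermodynamic efficiency features from reaction Gibbs energies,
    reaction-level feature assembly with chained predictive-mean-matching
    imputation, curation of in vitro turnover records, a twelve-member
    regression ensemble with permutation feature importance, and synthetic data
    generators that emulate every required input at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    pracma,
    glmnet,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
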