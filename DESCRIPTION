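Package: aetagger
Title: Named-Entity Tagging of Medication and Adverse-Event Information in
    Spontaneous Adverse-Event-Report Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A nine-class named-entity tagger for medication and
    adverse-event information in spontaneous drug-safety-report
    narratives (FAERS-style free text). Provides a linear-chain
    conditional random field implemented from first principles
    (forward-backward, Viterbi, L2-regularised maximum-likelihood
    training), a dictionary-matching baseline over bundled drug and
    adverse-event lexicons, per-token naive Bayes, six switchable
    feature families for ablation studies, strict and lenient
    span-matching evaluation with precision/recall/F1, token-level
    Cohen's kappa for inter-annotator agreement, k-fold
    cross-validation, and a synthetic narrative generator with a
    perturbation model that simulates a second annotator's boundary,
    missed-entity, and category disagreements. Reads and writes
    BRAT-style standoff annotation and CoNLL-style token-per-line
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
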