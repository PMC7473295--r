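Package: phenolink
Title: Validation of Survey-Reported Chronic Conditions Against Linked
    Electronic Health Records
Version: 0.1.0
Authors@R: person("Platform", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for validating self-reported chronic-condition prevalence
    from population health surveys against linked primary-care (GP, Read-coded)
    and secondary-care (hospital, ICD-10-coded) records. Provides code-list
    phenotyping with condition-specific ascertainment windows ("ever" versus
    "currently treated", i.e. the 12 months before interview), multi-source
    case attribution, survey-versus-clinical contingency matrices with
    sensitivity, specificity, predictive values, Cohen's kappa and prevalence
    confidence intervals, a partial-GP-coverage undercount estimator, and a
    synthetic linked-data generator with a planted-contingency mode for
    end-to-end pipeline verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    optparse,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
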