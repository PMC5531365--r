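Package: shortscreen
Title: Short-Form Construction and Validation for Ordinal Screening Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating brief versions of ordinal
    screening questionnaires against a binary diagnostic criterion. Implements
    partial credit Rasch calibration by joint maximum likelihood (category
    probabilities, item and test information, infit/outfit diagnostics,
    principal components analysis of standardized residuals), four item
    selection strategies (Rasch regression with anchored person measures,
    test-information matching, forward stepwise logistic regression, stepwise
    discriminant function analysis), ROC cut-point optimization with Youden's
    index, and classification-agreement statistics (Cohen's kappa, percent
    agreement, Pearson chi-square, Cronbach's alpha, Spearman correlation,
    one-way ANOVA with eta-squared). A synthetic-cohort generator produces
    latent-trait-driven item responses and DSM-5-style symptom counts so the
    whole pipeline can be exercised and tested without access to respondent
    data. The worked application is the 8-item CUDIT-R cannabis screening
    instrument and its 3-item short form.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
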