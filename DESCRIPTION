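Package: pcmckit
Title: Post-Conflict Matched-Control Analysis of Consolation and Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-conflict/matched-control (PC/MC) method of
    quantitative ethology, applied to consolation and reconciliation in a
    semi-free bonobo colony. Provides readers, writers and validation for
    observational records (roster, conflicts, 10-minute focal follows, scan
    samples), an agent-based synthetic-colony generator with the covariate
    structure the analyses assume, attracted/dispersed/neutral pair
    classification with triadic and conciliatory contact tendencies and the
    consolation index, dyadic affiliation indices from scan samples,
    Wilcoxon signed-rank and Kaplan-Meier log-rank comparisons of censored
    first-contact latencies, self-directed-behavior stress proxies with
    Bonferroni correction, and binomial and Gaussian mixed models with
    exhaustive AIC model selection and null-model likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
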