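Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("mrpipe", "maintainers", email = "mrpipe@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: instrument construction (genome-wide significance filtering,
    greedy LD clumping, F and R-squared instrument-strength statistics),
    exposure/outcome harmonization with frequency-based resolution of
    palindromic variants, causal-effect estimators (Wald ratio,
    inverse-variance-weighted, MR-Egger, weighted median, weighted mode),
    sensitivity analyses (Cochran Q, Egger intercept, I-squared for the
    NOME assumption with SIMEX correction, MR-PRESSO outlier detection and
    correction), analytic power calculations for binary outcomes, and a
    seeded generator of synthetic two-sample GWAS summary statistics with
    known causal truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
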