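Package: svcea
Title: Cost-Effectiveness of Early Versus Late Sacubitril-Valsartan
    Initiation in Acute Decompensated Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lifetime Markov cohort model with monthly cycles comparing
    early initiation of sacubitril-valsartan (during the index admission for
    acute decompensated heart failure), late initiation (after three
    consecutive non-hospitalized months), and enalapril throughout, from the
    Chinese healthcare-system perspective.  Provides the rate-to-probability
    parameter derivations, CPI inflation and currency conversion of costs,
    the six-state cohort engine with tunnel states for the post-discharge
    vulnerable phase, half-cycle-corrected discounted accrual of costs,
    QALYs and life-years, incremental cost-effectiveness ratios and net
    monetary benefit, one-way (tornado) sensitivity analysis, and a
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.  An individual-level micro-simulation oracle and
    a synthetic parameter-set generator support verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
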