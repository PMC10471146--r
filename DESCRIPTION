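Package: ptmcCEA
Title: Cost-Effectiveness of Active Surveillance Versus Early Surgery for
    Papillary Thyroid Microcarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort state-transition model comparing active
    surveillance (AS) with early surgery (ES) for low-risk papillary thyroid
    microcarcinoma (PTMC) from a Chinese healthcare-system perspective.
    Provides rate/probability conversions, age-banded progression schedules,
    annual-cycle cohort simulation with discounted cost and QALY accrual,
    incremental cost-effectiveness metrics (ICER, CER, net monetary benefit,
    willingness-to-pay thresholds), one-way deterministic sensitivity
    analysis (tornado), probabilistic sensitivity analysis with beta/normal
    parameter distributions (cost-effectiveness plane and acceptability
    curves), and a synthetic, calibratable hospital cost schedule standing in
    for unpublished unit-cost data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
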