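Package: suturetension
Title: Phase Analysis and Relaxation Modelling of Knotted-Suture Tension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates, segments and models the tension a knotted
    monofilament suture exerts on soft tissue during the first hour after
    knotting. Force-versus-time traces are decomposed into a rapid cutting
    phase, a constant declining phase and a plateau phase; the declining
    phase is fitted with the relaxation model y = a*exp(-b*t^c) + d; and
    tissue-level summaries, nonparametric group comparisons and
    collagen-content correlations are assembled into a cohort report. A
    seeded synthetic-trace generator parameterized by published tissue
    characteristics makes the whole pipeline testable without sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
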