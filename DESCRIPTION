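Package: mrpe
Title: Sequential Expected-Loss Designs for Micro-Randomised Process Evaluations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Design engine for micro-randomised process evaluations (MRPEs)
    of mobile-health app features with binary survey-completion outcomes.
    Implements a Beta-Bernoulli expected-loss stopping rule for sequential
    two-arm comparisons, a Monte-Carlo simulator of the design's operating
    characteristics (probability of choosing the better option, sample size
    used), a synthetic app-cohort generator emulating twice-weekly and
    weekly survey schedules over a 12-week follow-up, and computation of
    survey-completion outcomes (overall completion rate, proportion of high
    completers, low-completer flags, retention).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
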