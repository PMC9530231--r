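Package: crowdcontext
Title: Context-Dependent Wisdom of Crowds Under Influence Centralization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when centralized social-influence structures help
    or hurt collective numerical estimation. Implements a generative model of
    initial estimates indexed by an influence-centralization parameter that
    coincides with Freeman centralization, Monte-Carlo estimation of the
    probability that a centralized collective estimate beats the decentralized
    mean, an analytic lower bound on that probability with numerical
    phase-transition detection, a heavy-tailedness feature of an estimation
    context based on the relative log-likelihood of log-normal versus normal
    fits, a synthetic trial-table generator emulating multi-study group
    estimation experiments, and a trial-level reanalysis pipeline with
    mixed-effects moderation models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
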