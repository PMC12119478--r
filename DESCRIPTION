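Package: healthmarket
Title: Dynamic Equilibrium Simulation of Healthcare Markets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, deterministic multi-agent simulator of healthcare
    markets with consumers, providers, an insurer and a government.
    Implements intertemporal consumer demand under quadratic utility,
    moral hazard and effective prices, bounded and dampened dynamic
    pricing, adverse-selection and risk-adjusted insurance premiums with
    an explicit-Euler premium adjustment rule, budget- and
    smoothness-constrained incentive allocation with elasticity
    targeting, welfare accounting with subsidy/tax dynamics, and tabular
    policy-gradient reinforcement learning over a subsidy/tax decision
    process. Also provides an economic-impact summarizer for
    per-patient cohort tables with missing cells, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
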