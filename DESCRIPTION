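Package: curvecause
Title: Causal Discovery for Functional Dynamic Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns the direct causes and distance-bounded indirect causes of a
    functional dynamic target: a quantity observed as a curve over time (for
    example a growth trajectory) whose mean function depends on discrete causal
    factors. Provides likelihood-ratio independence tests between discrete
    factors and curve-valued targets based on grouped nonlinear least-squares
    fits of classical growth families (Logistic, Gompertz, Richards, Hossfeld,
    Double-Logistic), a high-dimensional screening step with an adaptive
    significance level, a screening-plus-structural-learning algorithm over the
    screened factors, and a local algorithm that first learns the direct causes
    and then expands outwards parent-children set by parent-children set.
    Includes mixed-graph utilities (d-separation, v-structure orientation,
    Meek's rules, CPDAG construction), a synthetic causal-Bayesian-network
    simulator with curve-valued targets, and evaluation metrics for structure
    recovery and prediction error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
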