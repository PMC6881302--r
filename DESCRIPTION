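Package: twostepRL
Title: Hybrid Model-Based/Model-Free Reinforcement Learning for Social
    Two-Step Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a social variant of the
    two-step sequential decision task, in which participants choose
    financial advisors who lead deterministically to stocks paying
    slowly drifting rewards. Provides the task engine (Gaussian
    random-walk payouts with reflecting bounds, deterministic
    transitions), a hybrid model-based/model-free Q-learning agent with
    a weighting parameter w, per-subject maximum a posteriori parameter
    estimation with empirical priors, extraction of final latent
    advisor values, the model-agnostic stay/switch lagged regression,
    the post-task liking regression on latent values with w-moderation
    and simple-effects recentering, a synthetic-cohort generator with
    known ground truth, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
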