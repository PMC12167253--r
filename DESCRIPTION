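Package: endonav
Title: Safe Reinforcement Learning for Dual-Device Endovascular Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and learning toolkit for the second stage of
    mechanical thrombectomy: autonomous navigation of a micro-guidewire and
    micro-catheter from the internal carotid artery to a target in the middle
    cerebral artery. Provides a synthetic planar vascular-tree generator with
    scaling augmentation, a kinematic two-device navigation environment with a
    guidewire tip-force proxy, the six shaped reward functions (dense,
    IRL-derived, combined, each with and without a tip-force penalty),
    maximum-entropy inverse reinforcement learning from demonstrations, a
    recurrent Soft Actor-Critic controller, and the evaluation metrics
    (success rate, procedure time, path ratio, mean tip force) with paired
    t-test and ANOVA comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
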