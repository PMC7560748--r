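Package: mrsrs
Title: Transforming Self-Reported Stroke Register Outcomes to the Modified Rankin Scale
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <maintainer@example.com>
Description: Implements the mRS-RS transformation algorithm, a rule-based
    crosswalk from seven self-reported questions of the Swedish national
    stroke register (Riksstroke) three-month follow-up to modified Rankin
    Scale (mRS) grade bands, together with the evaluation machinery used to
    assess such crosswalks: confusion matrices, classification accuracy,
    the no-information rate, Fleiss-Cohen quadratic weighted kappa with
    asymptotic confidence intervals and Landis-Koch interpretation, and a
    from-scratch conditional inference tree classifier (permutation-test
    recursive partitioning) for ordinal targets.  A seeded synthetic
    registry simulator generates cohorts with configurable answer noise
    and missing-data contamination so the whole pipeline is testable
    without access to the restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
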