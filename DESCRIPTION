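Package: bundleval
Title: Behavioral and Neural Models of Consumer Bundle Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for studies of how people value
    bundles of consumer items relative to the items' individual values.
    Provides generators for willingness-to-pay (BDM auction) bid data, an
    interleaved item/bundle choice-task design, and trial-wise multivoxel
    response patterns under selectable value-coding schemes; mixed-effects
    fitting and BIC comparison of four bundle-value model families (linear,
    power, logarithmic, divisive normalization); closed forms for the
    divisive-normalization value code and its concavity and attenuation
    predictions; cross-condition ridge-regression decoding with
    leave-one-run-out cross-validation and group-level Wilcoxon/FDR tests;
    and representational similarity analysis comparing absolute and
    normalized value codes, including a context-dependent normalization
    model with trial-type specific value coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    lme4,
    nlme,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
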