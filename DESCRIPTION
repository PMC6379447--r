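Package: ttcquant
Title: Semi-Automated Quantification of Infarct Size in TTC-Stained Brain Sections
Version: 0.1.0
Authors@R:
    person("ttcquant", "maintainers", email = "maintainers@ttcquant.dev",
           role = c("aut", "cre"))
Description: Quantifies ischemic infarct size in photographs of
    2,3,5-triphenyltetrazolium chloride (TTC) stained rodent brain
    sections. Implements the two-stage supervised colour-threshold
    method used in stroke research: the pale infarct area is extracted
    by brightness binarization, the deep-red viable tissue by a
    red-channel threshold gated through a hue-band "digital red filter",
    and the infarct size is reported as a percentage of the whole
    coronal section area. Ships a seeded synthetic-section generator
    with pixel-level ground truth, the method-comparison statistics
    used to validate such tools against manual tracing (paired t,
    Pearson correlation, least-squares regression, Kolmogorov-Smirnov
    normality check, variance F-test), and a command-line interface for
    single-section analysis, threshold sweeps, batch studies and method
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
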