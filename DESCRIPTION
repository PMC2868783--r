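Package: bilispec
Title: pH-Dependent Speciation, Solubility and Host Binding of Unconjugated Bilirubin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the diprotic acid-base speciation of unconjugated bilirubin
    (UCB), its dianion dimerization, pH-dependent solubility and supersaturation,
    and its binding to pH-insensitive host systems: phosphatidylcholine vesicles
    (diacid partition), beta-cyclodextrin (dianion-proportional ellipticity),
    dodecylmaltoside micelles, and taurocholate micelles (per-species
    micelle/water distribution ratios, apparent pKa shifts, and a two-component
    circular-dichroism model). Includes titration-curve midpoint analysis,
    no-intercept least-squares fitting, and synthetic titration-data generators
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
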