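Package: traysub
Title: Fixed-Area Laboratory Subsampling of Terrestrial Invertebrate Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for a three-phase laboratory
    protocol that subsamples terrestrial invertebrate samples (pitfall and pan
    traps) on a gridded circular tray: a 4 mm sieve separates large specimens,
    a fixed number of randomly selected grid cells is counted and extrapolated
    to the whole tray by the cell-equivalent multiplier, and a quick visual
    scan of the remainder records rare taxa for richness. Includes a seedable
    synthetic community generator (long-tailed rank abundance, large-specimen
    fractions, imperfect detection, optional spatial clustering), the plug-in
    abundance estimator with its percent-accuracy score, taxa-richness
    accumulation across phases, abundance-category classification and the
    full-count decision rule, and a Monte-Carlo engine that evaluates accuracy
    and richness as functions of the number of subsamples. Tabular text
    input/output supports real per-cell tally sheets as well as simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
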