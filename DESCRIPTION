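Package: chronotree
Title: Relaxed-Clock Timetrees, Tip Dating, Rate-Autocorrelation Testing
    and Evolutionary Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building timetrees from rooted phylogenies with
    branch lengths using a relative-rate (RelTime-style) relaxed-clock
    framework. Converts relative node times to absolute times with
    probability-density node calibrations (normal, lognormal, exponential,
    uniform, point and hard bounds) and Monte-Carlo confidence intervals;
    dates serially sampled sequences from tip sampling times (RelTime with
    dated tips); tests for autocorrelation of evolutionary rates among
    lineages (CorrTest-style score with a simulation-calibrated P-value);
    computes neutral evolutionary probabilities (EP) of alleles in a focal
    sequence given a multispecies alignment and timetree; and provides a
    site-configuration-compressed maximum-likelihood engine with JC, HKY
    (+ discrete gamma) and Poisson amino-acid models. Includes a seedable
    synthetic-data generator (Yule timetrees, branch-rate models, sequence
    evolution) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
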