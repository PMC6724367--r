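Package: wolbtiter
Title: Quantification of Wolbachia Endosymbiont Titer from Confocal Stacks and qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring Wolbachia endosymbiont abundance in host
    tissues. Counts bacterial nucleoids (DNA puncta) in 3D confocal z-stacks by
    connected-component particle analysis, including the semi-automated
    half-depth-doubling convention for large late-stage egg chambers and an
    inter-plane signal-redundancy estimator. Estimates absolute gene copy
    number from qPCR threshold cycles via plasmid standard curves, with
    relative wsp/rpl32 ratios and per-fly back-extrapolation. Chooses
    two-sample tests through a Shapiro-Wilk/Levene decision tree (Student,
    Welch, Mann-Whitney, or a bootstrap randomization t-test) and estimates
    empirical power by subsampling titer datasets with replacement. Ships a
    synthetic-fixture generator (image stacks, qPCR plates, titer tables) with
    known ground truth so the whole pipeline runs and is tested without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    igraph,
    car,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
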