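Package: emdetwin
Title: Expectation-Maximization Detwinning for Serial Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resolves the merohedral indexing ambiguity that arises when
    merging snapshot diffraction patterns from many randomly oriented
    crystals, as in serial femtosecond crystallography (SFX). Each still
    pattern records only partial reflections, so auto-indexing cannot
    distinguish twin-related indexing modes; merging then mixes the modes
    and the data appear twinned. The package implements an
    expectation-maximization algorithm that iteratively assigns an indexing
    mode to every pattern by Pearson correlation against a cumulatively
    merged full-intensity model, together with Monte Carlo merging of
    partial reflections, a synthetic partial-reflection simulator (Wilson
    intensities, uniform or resolution-dependent partialities, Poisson shot
    noise), and reference-based evaluation tools (consistent/alternative
    indexing-mode labelling, resolution-shell model correlations, multi-run
    consistency, dataset-size sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
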