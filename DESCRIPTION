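Package: fitscape
Title: Magnesium-Dependent RNA Fitness Landscapes from In Vitro Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combinatorial RNA fitness landscapes measured
    by in vitro selection and deep sequencing across a magnesium titration.
    Converts merged amplicon reads (or variant count tables) into per-genotype
    relative fitness, classifies pairwise epistasis (magnitude, sign, reciprocal
    sign) over all mutational squares, computes landscape ruggedness and the
    roughness-to-slope ratio, fits Hill dose-response curves and an exponential
    decay of fitness with mutational distance, and runs Wright-Fisher
    simulations of populations adapting on the empirical landscapes. Includes a
    synthetic-data generator that emulates the selection-and-sequencing
    experiment with a known ground truth, so the whole pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
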