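Package: hiddenproj
Title: Two-Level Non-Regular Fractional Factorial Designs and Hidden
    Projection Analysis
Version: 0.1.0
Authors@R:
    person("Hidden", "Projection Maintainers", email = "maintainers@hiddenproj.example.org",
           role = c("aut", "cre"))
Description: Construction and analysis of two-level screening designs for
    multi-factor intervention studies. Builds regular fractional factorial
    designs from generator words (with defining contrast subgroup, word
    length pattern, resolution, and alias structure), and non-regular
    orthogonal-array designs derived from Hadamard matrices (Sylvester,
    Paley type I and type II quadratic-residue constructions). Verifies
    orthogonal-array strength by exhaustive level-combination counting,
    and quantifies hidden projection properties: the percentage of factor
    subsets whose intercept + main-effects + two-factor-interaction model
    matrix has full column rank, computed with an exact integer rank and a
    floating-point cross-check. Includes a command-line interface and
    config-driven case studies comparing regular and non-regular designs
    by run count, strength, and projection coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
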