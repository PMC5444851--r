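Package: meiorec
Title: Crossover Landscapes and Interference in Diploid and Allotriploid
    Backcross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of meiotic crossovers scored from backcross genotyping
    data: crossover calling with flanking-marker midpoints, Kosambi genetic
    maps, recombination landscapes and their shape comparison via equal-count
    binning, a model-free crossover-interference index based on the
    Kullback-Leibler divergence between observed inter-crossover distance
    distributions and a shuffle-derived no-interference null (with permutation
    tests on index differences), a truncated-Poisson test of post-meiotic
    viability selection, and two-pathway gamma-sprinkling interference model
    fitting with resimulation confidence intervals. Includes a synthetic
    meiosis generator (stationary gamma renewal Class I pathway plus Poisson
    Class II pathway, chromatid thinning, optional viability truncation) so
    every analysis stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
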