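Package: biocrustr
Title: Quantitative Assessment of Biocrust Soil-Restoration Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative assessment of biological soil crust
    (biocrust) restoration experiments: soil aggregate-stability indices
    (mean weight diameter, geometric mean diameter, percentage of aggregate
    destruction) from dry- and wet-sieving fraction data, chain-method crust
    surface roughness, a principal-component / minimum-data-set Soil Quality
    Index with communality weighting and piecewise linear indicator scoring,
    Grey Relational Analysis ranking of treatments against an ideal
    reference sequence, control-relative treatment effect tables, and a
    seeded synthetic-data generator that emulates a four-treatment pot
    experiment so every analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
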