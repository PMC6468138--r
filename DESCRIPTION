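Package: rmtniche
Title: Macronutrient Niche Analysis with Right-Angled Mixture Triangles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating realized macronutrient niches from
    proximate food composition and scat-based diet tables. Converts
    proximate analyses (crude protein, ether extract, available
    carbohydrate) to metabolizable-energy macronutrient profiles using
    standard 4/9/4 kcal/g factors, mixes food profiles into diet points by
    relative-frequency weighting, projects compositions into the
    right-angled mixture triangle, and compares macronutrient niche
    breadth between groups as convex-hull area ratios. Bundles the
    proximate and diet tables for Asiatic black bear in two Nepalese study
    areas and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
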