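Package: fcbscore
Title: Fuzzy Expert-System Scoring of Farmed Aquatic Species for Food,
    Climate, and Biodiversity Potential
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts biological and ecological trait values of farmed
    aquatic species into three 1-100 indices of potential contribution to
    food security (F), climate change mitigation and adaptation (C), and
    biodiversity (B) goals.  Trait values are fuzzified with overlapping
    trapezoidal and triangular membership functions, heuristic
    trait-to-potential rules are fired above a membership threshold,
    conclusions are combined with the MYCIN certainty-factor accumulation
    algorithm, and the accumulated memberships are defuzzified into crisp
    index scores.  Includes a jackknife trait-removal sensitivity
    analysis, non-parametric rank statistics (Kendall rank correlation,
    Kruskal-Wallis with Dunn's post-hoc comparisons, extreme-subset
    permutation tests), and a synthetic trait-table generator emulating
    FishBase-like data for finfish, crustaceans, molluscs, and algae.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
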