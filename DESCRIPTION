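Package: burnplanimetry
Title: Longitudinal Burn Wound Planimetry from Triangulated 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for objective longitudinal monitoring of burn wound healing
    from structured-light 3D surface scans. Reads triangulated surface meshes
    (PLY, OBJ, STL) with per-vertex colours and label sidecars, extracts wound
    regions of interest by vertex labels or colour rules, and measures curved
    wound surface area by triangle summation. Computes the standard area-based
    healing metrics: absolute and percentage area reduction, Du Bois body
    surface area, TBSA-normalised wound burden and its change, early-phase
    reduction, and daily healing rate; aggregates them into cohort-level
    tables and summaries. Ships a pilot burn cohort (18 patients, 43 wounds)
    and a synthetic scene generator that produces curved-anatomy meshes
    bearing wound patches of closed-form area following prescribed healing
    trajectories, so every pipeline stage can be validated against analytic
    ground truth without a scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
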