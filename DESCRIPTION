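Package: soilmatch
Title: Reference-Soil Matching for Enzyme Biosensor Bioassays
Version: 0.1.0
Authors@R:
    person("soilmatch", "developers", email = "soilmatch@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting enzymatic soil bioassays against a
    database of standard (reference) soils. A test soil is described by
    eight characteristics: residual butyrylcholinesterase activity (RA),
    residual bioluminescence of a two-enzyme (T2) and a three-enzyme (T3)
    bacterial-luciferase system, optical density of the aqueous extract at
    250 nm (D250), humus content, pH (in KCl), and the physical clay and
    sand fractions. The package finds the closest reference soil by
    Euclidean distance, classifies the enzymatic impact of a sample from
    residual luminescence, reports normalized side-by-side comparisons,
    reads and writes the flat JSON database format (including a
    JavaScript-wrapped dialect), and generates seeded synthetic reference
    databases that emulate the structure of a 51-sample standard-soil
    collection for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
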