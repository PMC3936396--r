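Package: hedgesim
Title: Individual-Based Simulation of Bet-Hedging via Developmental Instability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, genetically explicit simulation of the evolution of
    developmental instability (diversified bet-hedging) and local adaptation in
    a metapopulation arranged along a linear environmental gradient. Individuals
    carry diploid deterministic loci that set the mean phenotype and diploid
    instability loci that set the standard deviation of a Gaussian developmental
    deviate. Demes experience Gaussian stabilizing viability selection toward a
    local optimum that can fluctuate over time as a stationary AR(1) process,
    independently per deme or synchronized across the metapopulation. Dispersal
    follows either a stepping-stone kernel (movement probability and distance
    tied to one Gaussian scale) or island migration, under two life-history
    orders (selection before or after dispersal). Includes soft-selection
    reproduction to carrying capacity, replicate and parameter-sweep runners
    with extinction retry logic, summary statistics (mean instability, local
    adaptation, mean fitness), and tabular CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
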