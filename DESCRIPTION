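Package: rhoclock
Title: Time-Dependent Rho Estimation of Coalescence Ages from
    Mutation-Annotated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates coalescence ages (TMRCA) from rooted phylogenies whose
    branch lengths are mutation counts, using a modified rho statistic that
    decomposes the genealogy into coalescent periods and applies a
    time-dependent scaling of the mutation rate in each period.  Includes
    classic diversity statistics (rho, pi, segregating sites) for comparison,
    Poisson-based uncertainty intervals, neutral fixation and substitution
    rate relations under fluctuating population size, and a Kingman
    coalescent simulator with Poisson mutations for validation experiments.
    Motivated by human mitochondrial DNA haplogroup dating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
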