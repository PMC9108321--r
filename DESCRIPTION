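Package: drivesim
Title: Deterministic Models of Gene Drive Suppression and Resistance Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic, discrete-generation genotype-frequency recursions
    for population-suppression gene drives confronting unlinked resistance.
    Implements a three-locus model of one or two male-limited homing drives
    against a dominant cost-free mechanistic resistance allele, haploid-sex
    models of homing and ClvR (cleave-and-rescue) toxin-antidote drives
    confronting an allele that enforces sib mating, closed-form equilibrium
    mean-fitness theory across drive systems, and a ceiling
    density-dependence ecological model coupling drive genetics to population
    dynamics, periodic knockdown, and extinction. All recursions are built by
    exhaustive enumeration of parental matings weighted by gamete-production
    rules, and ship with grid-search utilities for resistance-free
    suppression limits and sib-mating invasion thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
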