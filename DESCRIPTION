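Package: sexrolesim
Title: Individual-Based Simulation of Parental Sex-Role Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based evolutionary simulation of the conflict between
    the sexes over parental care. A state-structured life cycle (juvenile,
    pre-mating, mate search, caring) is iterated in daily time steps for a
    population of haploid individuals carrying four sex-limited loci: female
    and male care durations, a female mating preference and a costly male
    ornament. Offspring survival saturates with total parental effort and is
    density regulated; a daily mating market pairs searching females and males.
    The package provides the closed-form model functions, the Mendelian
    inheritance and mutation kernels, a fast compiled simulation engine,
    observers for fitness profiles, equilibrium classification, bimodality and
    regime-switch detection, a numerical invasion (adaptive-dynamics) analysis
    that locates the evolutionary branching point, and scenario presets with
    replicate management for studying bistable sex-biased care, transient
    within-sex polymorphisms, evolutionary lability, care-driven sexual
    selection and pre-mating-investment effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
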