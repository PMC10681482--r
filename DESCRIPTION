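Package: silvigen
Title: Demo-Genetic Simulation of Even-Aged Forest Stands Under Silviculture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based, demo-genetic simulation of monospecific even-aged
    forest stands. Trees carry a heritable growth-deviation trait ("vigor")
    controlled by diallelic quantitative trait loci; they grow by a
    distance-independent stand growth model, die by density-dependent
    self-thinning and by stochastic non-selective disturbance, are thinned by
    configurable silvicultural scenarios, and reproduce with Mendelian
    inheritance, seed and pollen dispersal and fertility-weighted mating.
    Density-dependent natural selection and its modulation by management emerge
    from the coupled dynamics. The package computes per-generation evolutionary
    rates (haldanes) and standard dendrometric outputs over multi-cycle runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'core_state.R'
    'genetics.R'
    'growth.R'
    'mortality.R'
    'regeneration.R'
    'silviculture.R'
    'engine.R'
    'metrics.R'
    'fixtures.R'
    'config_io.R'
    'show-methods.R'
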