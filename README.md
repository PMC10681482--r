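# silvigen

Individual-based, demo-genetic simulation of managed even-aged forest
stands.

## The problem

Forest trees are long-lived, managed over multiple generations, and under
*density-dependent soft selection*: competition kills the relatively
smallest trees of a stand (self-thinning), and reproductive success scales
with tree size. Thinning and disturbance remove trees too — but
non-selectively — so management does not only change stand structure, it
*regulates natural selection* on growth-related traits. `silvigen` couples a
forest dynamics model with a finite-loci quantitative genetic model so this
interaction can be simulated explicitly, for users studying
eco-evolutionary feedbacks in even-aged silvicultural systems (population
and quantitative geneticists, forest scientists, evolution-oriented
managers).

## The model in brief

Each tree carries a heritable trait, **vigor** — its individual deviation
(cm y⁻¹) from the baseline diameter-increment prediction — controlled by
diallelic QTL (additive, no dominance: the genotypic value is the sum of
allelic effects ±aₗ) plus a fixed environmental deviation, with target
additive variance V_A = 0.0042 cm² y⁻² and h² = 0.3. Annually, each 15-m
pixel of the stand receives a basal-area increment
ΔG = η·ΔH_dom·G^γ·s(RDI), allocated to trees linearly in circumference above
a dynamically solved threshold; vigor then shifts each tree's diameter
increment. Pixels above the Reineke carrying capacity
N_max = k_R·C_g^(−1.6) lose their smallest trees (selective mortality);
stochastic disturbance regimes (annual Weibull-drawn potential mortality,
mean ≈ 2 % or ≈ 12 %) kill neutrally. At the end of a cycle a seeding cut
leaves 110 seed trees/ha; seedlings establish from a fat-tailed dispersal
kernel (mean 240 m) with fecundity-weighted mothers and dbh²-weighted
fathers, inherit Mendelian genotypes with Haldane recombination, and are
recruited at age 25 with the density reset to 2800 stems/ha.

The headline statistic is the evolutionary rate in haldanes over four
generations,

    H0 = |z̄_end − z̄_start| / sqrt((s²_start + s²_end)/2) / n_gen,

computed on vigor between the founders and the recruits produced after the
fourth cycle, both at age 25.

## Worked example

```r
library(silvigen)

cfg <- simConfig(width = 105, height = 105,      # 1.1-ha stand
                 scenario = "U-long",            # unthinned, 100+3 y cycles
                 regime = "none", nQtl = 50,
                 setupSeed = 11, inventorySeed = 2, dynamicsSeed = 3)
run <- runSimulation(cfg)
run
#> SimRun: U-long / none disturbance / 50 QTL
#>   312 annual records over 4 cycle(s)
#>   evolutionary rate H0 = 0.394 haldanes

cycleSummaries(run)[, c("cycle", "startMeanGv", "selDiff", "qmdEnd", "deadST")]
#>   cycle  startMeanGv    selDiff   qmdEnd   deadST
#> 1     1 -0.001290379 0.04907609 44.76916 2175.964
#> 2     2  0.050672456 0.04071174 51.76392 2311.111
#> 3     3  0.094053708 0.03573229 56.73487 2382.766
#> 4     4  0.132902521 0.04582490 60.85407 2428.118
```

Reading: within every 100-year cycle, self-thinning kills ~2200-2400 trees/ha
(the smallest first), which raises the genetic mean of vigor (`startMeanGv`
climbs by ~0.04 cm y⁻¹ per generation — the realized selection differential
`selDiff` of the previous cycle), and the end-of-cycle quadratic mean
diameter of the survivors grows across generations. The run's H0 of 0.394
haldanes sits inside the range of empirical microevolution estimates for
wild populations. Under `scenario = "B-long"` (six random thinnings per
cycle) self-thinning is pre-empted (`deadST ≈ 0`) and H0 collapses by
roughly 75 % — non-selective management suppressing natural selection.

`writeAnnualRecords()`, `writePedigree()` and `writeQtlMap()` export the
standard per-year output table (codes `Nha`, `muG.Vig`, `VA(Vig)`, `He`,
`VhaProd`, `QMD`, `DeadS-T`, `DeadD`), the pedigree and the genetic map;
`readSimConfig()` reads a YAML run configuration, and
`inst/scripts/silvigen-run.R` is a command-line wrapper around it.

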