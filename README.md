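# fwdgwas

Forward-time simulation of realistic samples for genome-wide association
studies.

`fwdgwas` grows a large present-day population out of a small phased
haplotype panel by explicit Wright–Fisher simulation — mutation, map-based
recombination, natural selection, migration and rapid demographic expansion
— and then draws analysis-ready samples (case-control panels, affected-offspring
trios, admixed cohorts) under configurable penetrance models. Because every
individual is simulated explicitly, the method can do what resampling and
coalescent simulators cannot: introduce selective sweeps at chosen markers,
pin disease-allele frequencies at the present day, track individual ancestry
through an admixture event, and generate new haplotypes by recombination and
mutation while preserving the allele-frequency spectrum and block-wise
linkage disequilibrium (LD) of the input panel.

It is aimed at statistical geneticists who need benchmark data sets with a
*known* genetic architecture — known disease loci, known selection history,
known population structure — to evaluate association tests, family-based
methods or admixture-mapping procedures.

## The method in brief

1. **Initial population.** A phased panel (VCF or Oxford haps/sample, or the
   built-in synthetic generator) is filtered by region, marker name and
   minor-allele frequency (MAF), assigned genetic positions from a fine-scale
   recombination map, and instantiated as diploid founders.
2. **Expansion.** The population grows to `N_T` diploids over `T`
   generations (linear growth `N_t = N_0 + t (N_T − N_0)/T` by default:
   faster early growth preserves founder diversity and yields a larger
   harmonic-mean effective size `N_e = T / Σ 1/N_t` than exponential
   growth). Each generation, parents are chosen with probability
   proportional to fitness; gametes recombine at Haldane fractions
   `r = ½(1 − e^{−2d})` from the map distance `d` (Morgans) and mutate
   symmetrically at rate μ per locus. An optional scaling factor λ runs
   `N/λ` individuals for `T/λ` generations with λ-magnified forces — a
   diffusion-justified shortcut valid for weak, additive selection.
3. **Disease-allele control.** The frequency path of each disease-predisposing
   allele is pre-simulated — forward from its panel frequency (restarting
   until the present-day frequency lands in a target window) or backward
   from the present until the mutant is lost — and then enforced exactly
   during evolution by a controlled mating scheme that accepts offspring by
   their genotypes at the controlled loci.
4. **Sampling.** Affection status is assigned from a penetrance model
   (`Pr(affected | genotype, environment, ancestry)`; logistic two-locus
   gene–gene/gene–environment, single-locus logistic, genotype table, or
   ancestry-linear), and samples are drawn directly or by rejection
   sampling of simulated offspring.

## A worked example

Simulate a panel, expand it 20-fold under purifying selection at one marker
while forcing that marker's frequency from its panel value down to 5%, and
draw a case-control sample:

```r
library(fwdgwas)

gen   <- generate_panel(synthetic_panel_spec(n_haplotypes = 200, n_loci = 50,
                                             seed = 61))
panel <- gen$panel
pop   <- initialize_population(panel)
dpl   <- which.min(abs(colMeans(panel$haps) - 0.3))    # a ~30% marker
allele_frequency(pop, dpl)
#> [1] 0.3

sizes <- round(seq(100, 2000, length.out = 101))       # linear expansion
f     <- fitness_triple(1, 0.98, 0.96)                 # selection against alt
set.seed(1)
tr    <- simulate_forward_trajectory(allele_frequency(pop, dpl), f, sizes,
                                     x_range = c(0.04, 0.06))
tr$loci <- dpl
tr
#> <trajectory> 1 locus/loci over 100 generations; origin at 0; accepted after 4 attempt(s)

cfg <- evolution_config(demographic_model(100, 2000, 100, sizes = sizes),
                        mu = 1e-8, selection = selection_model(dpl, f),
                        seed = 7, watched_loci = dpl)
res <- evolve(pop, cfg, controlled = tr)
res$population
#> <population> generation 100; 1 subpop(s) of size 2000; 50 loci
c(allele_frequency(res$population, dpl), tr$freqs[101])
#> [1] 0.0435 0.0435
```

The final frequency equals the trajectory's endpoint exactly: the controlled
mating scheme makes the allele count at the disease locus `round(2 N_t x_t)`
in every generation `t`. From here a rare-disease sample:

```r
model <- single_locus_logistic_model(-3, 1.2, locus = dpl)
set.seed(2)
cc    <- draw_case_control_rejection(res$population, 500, 500, model)
cc
#> <gwas_sample> 1000 individuals (500 affected) x 50 loci
write_ped_map(cc, "sample")          # PLINK-ready PED/MAP
```

A command-line mirror of this workflow is in `exec/fwdgwas`
(`fwdgwas synth | init | evolve | sample`, YAML configs; PED/MAP, covariate
and scan TSVs out; exit codes 0/2/3/4 for ok / config error / infeasible
trajectory or quota / I/O error).

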