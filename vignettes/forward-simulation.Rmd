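---
title: "Forward-time simulation of GWAS samples: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-time simulation of GWAS samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwdgwas)
```

## The simulation model

`fwdgwas` implements a discrete-generation Wright–Fisher model with
selection, over a fixed marker panel. The state is a set of diploid
individuals in one or more subpopulations, each carrying two phased binary
haplotypes over a shared locus list. One generation consists of:

1. **Migration** (optional). Stepping-stone exchange between adjacent
   subpopulations, or continuous gene flow from a source into a sink.
2. **Mating.** For every offspring, a father and a mother are drawn
   independently, with replacement, with probability proportional to
   fitness. Fitness is multiplicative over the selected loci: an individual
   with `g` copies of the selected allele at a locus contributes that
   locus's fitness-triple entry `w(g)`. Each parent transmits one gamete
   formed by standard meiosis — a fair-coin starting haplotype, then a
   source switch at interval `i` with the Haldane probability
   `r_i = ½(1 − exp(−2 d_i))`, `d_i` the inter-marker map distance in
   Morgans, with free recombination (`r = ½`) across chromosome
   boundaries — followed by symmetric mutation (each site flips 0↔1 with
   probability μ).
3. **Bookkeeping.** Offspring sex is a fair coin; offspring ancestry is the
   mean of the parental ancestry values, so mating alone never changes a
   subpopulation's expected mean ancestry.

Assumptions worth stating: generations are non-overlapping; there is no
selfing control (a parent can be drawn twice, with probability `O(1/N)`);
the genetic map is sex-averaged; markers are biallelic with no missingness.
Sexes are tracked and fathers/mothers are drawn from the male/female pools,
but if a subpopulation loses one sex entirely (possible at very small scaled
sizes) mating falls back to ignoring sex, with a warning, rather than
aborting the run.

### Demography

`demographic_model(N0, NT, T, schedule)` supports linear
(`N_t = round(N0 + t (NT − N0)/T)`), exponential
(`N_t = round(N0 (NT/N0)^(t/T))`) and constant schedules, with endpoints
pinned exactly. Linear growth is the default for human-panel expansion
because it grows fastest immediately after the bottleneck, preserving
founder diversity; its harmonic-mean effective size
(`harmonic_ne`, `N_e = T / Σ_{t<T} 1/N_t`, final census excluded) is several
times larger than the exponential schedule's. For the 993 → 100,000
expansion over 500 generations the exponential schedule gives
`N_e ≈ 4604`; the linear schedule gives ≈ 21,000 by the same direct
summation. The per-generation granularity is deliberate: "adding the same
number of individuals each year" collapses to linear interpolation of `N_t`,
since no within-generation event could observe yearly substeps.

### λ-scaling

`scale_config` rewrites a run with scaling factor λ: `round(T/λ)`
generations at sizes `round(N_{round(tλ)}/λ)`, mutation `λμ`, per-interval
recombination probabilities `min(λ r, ½)` (the probability is scaled, not
the map distance), and fitness deviations `w′ = 1 + λ(w − 1)`, clipped at 0
with a warning. This is the diffusion-consistent choice and is only valid
for weak, nearly additive selection; the CLI therefore refuses λ > 1 when
any fitness triple deviates from additivity beyond a configurable tolerance
(default 10⁻⁸) unless `--force` is given. Migration rates are not scaled:
the scaling literature magnifies mutation, recombination and selection, and
the per-generation migrant *fraction* is already dimensionless.

### Trajectory control

Disease-allele frequencies at the present generation are controlled by
pre-simulated paths. The forward kernel is deterministic viability-selection
response
`x′ = (x²w22 + x(1−x)w12) / w̄` followed by binomial resampling of `2N_t`
alleles; whole paths are re-drawn until the ending frequency lands in the
target window. The backward kernel is the inverse: the package *inverts the
deterministic response by monotone bisection* (to 10⁻¹² in `x`; the
round-trip error is below 10⁻¹⁰) and then resamples binomially, stepping
back until the allele is lost. This "invert, then resample" kernel is not
dictated by the problem — the choice is recorded here — but it is testable
via the inverse property and matches the behaviour expected of
trajectory-simulation methods in this area. Paths that absorb at 1, or
whose origin is older than `max_origin_gen`, are re-drawn; on exhaustion the
error reports the mean ending frequency (forward) or mean trajectory length
(backward) so selection parameters can be adjusted.

For multilocus disease models the controlled loci must be unlinked (the
package refuses same-chromosome selected loci in `marginal_fitness`), and
each locus's trajectory uses its marginal fitness — for a multiplicative
model, the locus's own triple up to a genotype-independent factor.

During evolution the trajectory is enforced *exactly*: the controlled
mating scheme generates offspring by the usual fitness-weighted mating and
accepts a candidate with allele counts `c_l` iff `c_l ≤ q_l` and
`q_l − c_l ≤ 2(S − 1)` for every controlled locus, where `q_l` is the
remaining allele quota and `S` the remaining offspring slots. The
accept/reject rule was chosen over the classical two-stack
(carrier/non-carrier) bookkeeping because it extends to multiple controlled
loci without approximation; at one locus the two schemes coincide in
distribution. Quotas are `round-half-up(2 N_t x_t)` — frequencies stay real
numbers everywhere else and are only discretized here. Infeasible quotas
(the allele absent or fixed in the parental pool) abort with the locus
named, and a bounded retry multiplier guards against near-infeasible
targets.

### Migration, admixture and ancestry

Stepping-stone migration moves `round(m N_i)` uniformly chosen individuals
from deme `i` to each adjacent deme, reciprocally, all moves computed from
the frozen pre-migration state; `m N < 0.5` yields zero migrants that
generation. Whether the pre-admixture phase's exchange should be one-way is
not determined by the sources for this design; it is implemented reciprocal.

Continuous gene flow replaces `round(p N_sink)` uniformly chosen sink
individuals with copies drawn (with replacement) from the source, so
migrants make up fraction `p` of the post-migration sink and the sink's
mean ancestry follows `a_{t+1} = (1 − p) a_t + p`, i.e. `1 − (1 − p)^t`
from `a_0 = 0` — the standard continuous gene-flow recursion (≈ 0.4013
after ten generations at `p = 0.05`).

Admixture uses positive assortative mating: individuals split into two
groups at an ancestry threshold (default 0.5); with probability
`assort_within` (default 0.8) both parents come from the group of a
uniformly drawn index individual, otherwise from the whole subpopulation.
This slows homogenization and produces a realistic spread of individual
ancestry values, while leaving the expected mean ancestry invariant.

## Disease models and sampling

Four penetrance families are provided: the two-locus logistic model with
gene–gene and gene–environment terms
(`logit P = α + β₁g₁ + β₂g₂ + β₃g₁g₂ + γ₁g₁e + γ₂g₂e`, binary environment
`e` with `P(e=1) = env_p`); a single-locus logistic; a free genotype
table; and the ancestry-linear model `P = base + slope · ancestry` (default
`0.05 + ancestry/6`). Design points:

- `env_p` defaults to 0.5 — the environment is described only as a
  two-state random factor, so the uninformative choice is documented rather
  than hidden.
- A constructor variant (`logistic_disease_model_paired`) enforces
  `β₁ = β₂/2, γ₁ = γ₂/2` for the "first locus has half the effect" design;
  the numeric effect sizes shipped in the examples (β₂ = 0.4, γ₂ = 0.4,
  β₃ = 0.2) are package defaults chosen to give detectable but not
  overwhelming marginal effects at a 1% prevalence, not values taken from
  any external study.
- `calibrate_intercept` solves for α by bisection against the *exact*
  prevalence — the expectation of penetrance over the 3×3×2
  genotype–environment classes under Hardy–Weinberg at the supplied
  disease-allele frequencies — to |error| < 10⁻¹⁰. Prevalence is monotone
  in α, so bisection cannot mis-converge.
- The single-locus logistic predictor is used *as configured*, including
  negative slopes (risk decreasing in the selected-allele count); a sign
  switch is a one-line config change, so both directions are first-class
  rather than second-guessed.

Sampling never mutates the source population. Direct case-control draws are
uniform within strata. Rejection sampling draws a *fresh uniform* parent
pair per candidate offspring — uniform, not fitness-weighted, because
postprocessing happens after evolution and applies no further selection;
one offspring per pair avoids sibship correlation that the sampled designs
do not model. Control quotas are filled by unaffected offspring from the
same rejection stream (the closest reading of an "offspring population with
exactly n cases and n controls"). Trio sampling keeps the drawn parents
with each affected offspring; parents can recur across trios only by
chance redraw.

## The synthetic panel generator

`generate_panel` builds test panels with the two statistical properties the
simulator actually relies on from real reference panels: *block-wise LD*
(high |D′| within haplotype blocks, near-independence between blocks) and a
*minor-allele-frequency floor*, at kb-scale marker spacing. The
construction is a mosaic of blocks: geometric block lengths (mean
`block_len`), `n_block_haps` founder haplotypes per block with frequencies
drawn once from a symmetric Dirichlet(1), and per-locus founder alleles
resampled (bounded retries) until the *realized* panel MAF meets the floor
exactly. Marker gaps are exponential (default mean 1810 bp, a typical
dense-panel spacing); the genetic map places a hotspot rate (default
10 cM/Mb) on block boundaries and a background rate (0.05 cM/Mb) inside
blocks, mirroring the observation that fine-scale maps concentrate
recombination between haplotype blocks.

This was chosen over a coalescent simulation deliberately: it is O(H·L),
dependency-free and seed-deterministic, and it reproduces exactly the
properties the engine's behaviour depends on. What it does *not* emulate:
mutation–drift-equilibrium site-frequency spectra, allele-age/frequency
correlation, LD decay *within* blocks, or any population-specific
demographic signature. Tests that pass on synthetic panels therefore
validate the *mechanics* of the simulator (transmission, control, sampling,
statistics), not the demographic realism of any particular human data set.

## Numerical choices and degenerate inputs

- Coordinates are 1-based; region filters are closed intervals on both
  ends; MAF filters use ≥.
- Alleles are stored 0/1 with 1 the alternate allele; PED export codes
  alleles 1/2 and phenotype 1/2 (unaffected/affected, −9 unknown).
- Empty marker selections warn and return an empty panel; an empty
  population is an error for frequency queries (never silently 0/0).
- LD: haplotype frequencies are counted directly (phase is always known);
  monomorphic loci yield flagged results and are excluded from decay
  profiles; distance bins are half-open `[k·bin, (k+1)·bin)`.
- FST: the default estimator is the classic fixation-index form — the
  ratio of summed sample-size-weighted between-subpopulation variances of
  allele frequency to summed `p̄(1−p̄)`, a ratio of sums across loci. It
  satisfies the exact identities (duplicated subpopulations → 0,
  fixed differences → 1) that make simulation sanity checks crisp.
  Weir–Cockerham's θ (1984) is available as `method = "wc"`; its
  finite-sample correction is the better choice for *estimating* FST from
  small samples but is slightly negative for identical subpopulations by
  construction, which is why it is not the default here.
- χ² association tests count alleles (2 per individual) in a 2×2 table,
  Pearson without continuity correction; a zero margin returns p = 1,
  flagged.
- The RNG is R's global stream: every run is reproducible from
  `evolution_config(seed = ...)`, and population snapshots (RDS containers
  with a format-version field) round-trip bit-exactly, including the
  stored RNG state.
- Rounding of scheduled sizes and allele quotas is round-half-up, so
  quota arithmetic is platform-stable.

## Scale of the shipped checks

The test suite exercises the distributional properties at sizes chosen to
give clean separations at 3-standard-error tolerances while keeping the
default run fast: neutral fixation at `N = 50`, `p₀ = 0.2` over 2000
replicate runs; Hardy–Weinberg restoration at `N = 10⁴` over 20 runs; 10⁵
(4×10⁵ in the acceptance script) meioses for the Haldane fraction; LD decay
at `N = 10⁴`, `r = 0.1`, `t = 10` over 200 replicates; trajectory control
on a 50-marker panel expanded 100 generations to `N = 2000`; admixture over
8 replicate populations of 2000. The λ-scaling comparison uses a 200-marker
synthetic panel: five unscaled replicates (`N = 500`, `T = 100`) against
one λ = 5 run (`N = 100`, `T = 20`), compared on binned mean-r² decay
curves; the scaled curve is required to sit within the unscaled replicates'
Monte-Carlo envelope. One point worth knowing when writing similar checks:
the `D_t = D_0(1−r)^t` recursion assumes founder genotypes are a random
union of gametes — founders constructed as all coupling double
heterozygotes decay faster in the first generation (by `r/2 · (1 − 2D_0)`
relative terms), which is a property of the initial condition, not of the
transmission engine.

## Known limitations

- No overlapping generations, age structure, or sex-specific maps.
- Only biallelic markers; no genotype uncertainty or missingness; no X/Y
  inheritance.
- Scaling is unsound for strong or non-additive selection — the guard can
  be forced off, at the user's risk.
- Trajectories of *linked* disease loci cannot be controlled jointly
  (refused, not approximated); time-varying selection coefficients are not
  supported.
- The bottleneck inherent in expanding a small founder panel loses rare
  haplotypes; raising μ generates new haplotypes but cannot recover the
  founders' rare variation.
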