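---
title: "Simulating G-matrix evolution under fluctuating trait optima"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating G-matrix evolution under fluctuating trait optima}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctG)
```

## The model

`fluctG` simulates haploid populations of constant size $N$ in which the
genotype–phenotype map itself evolves. Each individual carries two classes
of heritable elements: a vector of *weight genes* $\mathbf{a} \in
\mathbb{R}^{n_a}$, and a *contribution matrix* $\mathbf{c} \in
\mathbb{R}^{n_t \times n_a}$ whose entry $c_{ij}$ routes weight gene $j$
onto trait $i$. Every entry of $\mathbf{a}$ and of $\mathbf{c}$ is an
independent gene (a scalar real allele). The phenotype is the linear
read-out

$$ z_i = \sum_{j=1}^{n_a} c_{ij}\, a_j , $$

so pleiotropy is not fixed by assumption: a weight gene is pleiotropic
exactly to the extent that its column of $\mathbf{c}$ has evolved nonzero
entries on several traits. Fitness is Gaussian and multiplicative across
traits, with per-trait variance 1 around a moving optimum
$\mathbf{z}^\circ$:

$$ w(\mathbf{z}) = \exp\!\Big[-\tfrac{1}{2}\sum_i (z_i - z_i^\circ)^2\Big]. $$

Log-fitness is additively separable over traits, so there is no
correlational selection *within* a generation; any build-up of genetic
covariance must come from the multigenerational pattern of optimum
changes.

Reproduction follows a Moran birth–death scheme: each event draws one
parent with probability proportional to fitness (two parents under the
sexual option, combined by free recombination — each element from either
parent with probability $1/2$), mutates the offspring, and replaces a
uniformly chosen individual. $N$ events make one generation. Mutation hits
each weight gene with probability $\mu_a$ and each contribution gene with
probability $\mu_c$ per birth, adding a $\mathcal{N}(0,\,0.5)$ increment
to the parental allele.

## Environments

Trait optima live on a step lattice: every `period_generations` (default
10) each *stepping unit* moves by $\pm$`step_size` (default 0.2) with
probability $1/2$. The three regimes differ only in what a unit is:
**correlated** (all traits move in synchrony), **independent** (each trait
moves on its own), and **block-correlated** (synchrony within blocks,
independence between). Marginally, every trait performs the same
one-dimensional walk in all three regimes; only the cross-trait coupling
differs.

In the bounded default the optima are confined to $[-1, 1]$: a proposed
step that would leave the interval is cancelled, so a trait at a boundary
stays with probability $1/2$ and moves inward with probability $1/2$. This
reflecting rule makes the transition matrix doubly stochastic, hence the
stationary distribution is exactly uniform over the 11 lattice points
(`walk_transition_matrix()` exposes the matrix; the test suite checks the
uniform law both exactly and by simulation). Trajectories are pre-drawn
per replicate (`make_trajectory()`) so that the simulator and any
re-analysis see identical environments.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `N` | 1000 | population size (constant; Moran) |
| `n_traits`, `n_a` | 4, 4 | traits and weight genes (20 genes total) |
| `mu_a` | 1.25e-3 | per-birth mutation probability per weight gene |
| `mu_c` | 3.125e-4 | per-birth mutation probability per contribution gene |
| `mut_var` | 0.5 | variance of the mutational increment |
| `selection_var` | 1 | per-trait variance of the Gaussian fitness function |
| `step_size`, `period_generations` | 0.2, 10 | optimum step and cadence |
| `bounds` | [-1, 1] | optimum interval (bounded phase) |

With the defaults, an $N = 1000$ population receives on average 5
weight-gene and 5 contribution-gene mutations per generation
($n_a \mu_a N = 16 \mu_c N = 5$). Populations start genetically uniform
with all alleles at 0 (phenotypes at the origin) and the optimum at the
lattice centre; both are configurable.

## Measurements

**Total genetic (co)variance** (`total_vcv()`) is the covariance of trait
values across individuals, with the population denominator $1/N$. The
model has no environmental noise, so phenotypic covariance *is* total
genetic covariance. The denominator convention cancels from every
between-treatment ratio.

**Pleiotropy vs linkage disequilibrium** (`shuffle_decompose()`): permuting
the alleles at every locus independently among individuals destroys
between-locus associations (LD) while leaving each locus' allele content
and its within-individual trait effects intact. The (co)variance of the
shuffled population is therefore the pleiotropy component, and LD = total
− pleiotropy, exactly, by construction. The default is a single shuffle
per snapshot; `n_shuffles` averages several for a less noisy pleiotropy
estimate. Note the permutation null of a covariance is not exactly zero at
finite $N$ (its expectation is $-\mathrm{cov}/(N-1)$); the tests account
for this.

**Additive (co)variance** (`additive_vcv()`): random couples (uniform,
with replacement, ignoring fitness), offspring by free recombination
without mutation, averaged per couple. Heritability of trait $i$ is the
OLS slope of mean-offspring on midparent; the additive variance is that
slope times the phenotypic variance of the trait, and the $(i,j)$
covariance is the slope of offspring trait $j$ on midparent trait $i$
times the phenotypic variance of trait $i$. We use the phenotypic variance
rather than the variance of the midparent values themselves: for a purely
additive map (shared $\mathbf{c}$), the expected offspring equals the
midparent, the slope is 1, and the estimator then recovers the full total
matrix — the defining calibration of an additive-variance estimator. The
$(i,j)$ estimator is inherently asymmetric, so both the raw matrix and its
symmetrised average are returned. Traits with zero midparent variance
yield `NA` (undefined, never silently zero). Offspring per couple
(`n_offspring_per_pair`, default 10) controls regression attenuation from
Mendelian sampling noise in the offspring mean.

**Mutational matrices** (`sample_mutational_moments()`): each draw takes a
random individual (pooling all snapshots of a replicate), perturbs one
uniformly chosen gene of the requested class by $\mathcal{N}(0, 0.5)$, and
records the phenotype $\mathbf{z}$ and its change $\Delta\mathbf{z}$. The
per-mutation change in the (co)variance matrix is

$$ M^*_{ii} = \mathrm{Var}(\Delta z_i) + 2\,\mathrm{Cov}(\Delta z_i, z_i),
\qquad
M^*_{ij} = \mathrm{Cov}(\Delta z_i, \Delta z_j)
 + \mathrm{Cov}(z_i, \Delta z_j) + \mathrm{Cov}(\Delta z_i, z_j), $$

symmetric by construction; plain sample covariances are used (the pre- vs
post-mutation centring conventions agree in expectation). The genomic
matrix combines the classes by their rates,
$M_{tot} = n_a \mu_a M^*_a + n_t n_a \mu_c M^*_c$ (the 4/16 weighting at
the defaults). Only weight genes can be pleiotropic — each contribution
gene touches a single trait — so the $a$-class off-diagonals are where an
evolved pleiotropic architecture shows up in the mutational spectrum.

**Evolvability transplant** (`fix_pleiotropy()`, `evolvability_assay()`):
after phase 1, each replicate's contribution matrix is frozen at the modal
allele per locus (exact-value frequencies; ties go to the value carried by
the lowest-indexed individual, a deterministic rule), $\mu_c$ is set to 0,
and three copies of each population evolve under each regime with
*unbounded* optima restarted at the origin. Each run is summarised by mean
fitness over the last 10% of the recordings.

## Design choices made where the design was open

- **Moran conventions.** Parent and death slot are drawn independently
  (the parent may be the one replaced); under sexual reproduction the two
  parents are drawn independently and may coincide (selfing possible).
  These are the simplest standard conventions.
- **Fitness caching.** Per-individual fitnesses are cached and refreshed
  only for the replaced individual and whenever the optimum moves; parent
  selection walks the exact partial sums each event. A naive engine that
  recomputes every fitness at every event is kept in the same code path
  and is bit-identical at a fixed seed — the suite asserts this.
- **Zero-fitness fallback.** If every fitness underflows to zero (a
  population stranded far from the optimum, possible in the unbounded
  phase), the parent is drawn uniformly rather than crashing; this is the
  neutral limit of fitness-proportional sampling.
- **Seeding.** One master seed per batch yields recorded per-replicate
  seeds; each replicate draws its environment first and then its event
  stream, so runs are reproducible bit-for-bit and order-independent.
- **Statistics.** Between-regime comparisons are Welch two-sample t-tests
  on per-replicate time-averaged values. Within-block vs between-block
  covariance is compared with a *paired* t-test, since both numbers come
  from the same replicate populations. Degenerate (zero-variance) groups
  are reported as failures, never as fabricated p-values.
- **Stationarity check.** Occupancy counts of consecutive walk steps are
  strongly autocorrelated (relaxation time ≈ 24 steps for the 11-state
  walk), so the empirical uniformity test thins the simulated chain to
  every 150th state before the chi-square; without thinning the
  multinomial assumption fails and the test rejects a provably uniform
  law.

## What the generator emulates, and problem sizes

The reference configuration is the full design: $N = 1000$, 5,000
generations (5 × 10⁶ events) per replicate, 500 replicates per regime,
snapshots every 10 generations over the last tenth (50 per replicate), 10⁶
mutational perturbations per class, a 2,000-generation transplant phase.
That is a cluster-scale computation. The packaged desk scale
(`scale_preset("desk")`) keeps every structural rule and shrinks the
numbers: $N = 200$, 1,000 + 500 generations, 20 replicates per regime, 10⁵
perturbations — a couple of minutes on one CPU; `scale_preset("smoke")` is
a seconds-long schema check.

Two caveats follow. First, the desk scale shrinks both the mutational
input per generation (rates are per birth, so a smaller $N$ gets fewer
mutations) and the adaptation time, while drift noise grows; the regime
effects on covariance keep their direction but their *significance* at 20
replicates is marginal — expect one-sided p-values of order 0.01–0.2 for
the correlated-vs-independent covariance contrast and the modularity
contrast, not the vanishingly small values the full design yields. The
acceptance checks encode the full directional battery at this scale and
report whatever the committed seed produces. Second, the generator is the
model: it has no environmental variance, no dominance or diploidy, no
linkage map (free recombination only), and no demographic stochasticity,
so passing tests validate the method's internal logic and its behaviour
*under this model*, not its fit to any empirical system.

## Known limitations

- Ratios of covariances between regimes have near-zero, noisy denominators
  at reduced scale; they are reported alongside the group means and should
  be read with the p-values, not alone.
- The additive-covariance estimator's asymmetric raw form is retained only
  because its two halves differ by sampling noise; no inferential meaning
  attaches to the asymmetry.
- Snapshot archives use R's native serialization (plus a JSON manifest)
  rather than a cross-language array format; `vcv_tidy()` and the CSV
  exporters are the interchange surface.
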