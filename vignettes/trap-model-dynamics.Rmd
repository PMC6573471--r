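---
title: "Simulating TE invasions under the piRNA cluster trap model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TE invasions under the piRNA cluster trap model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pirnatrap` simulates the spread of a single transposable-element (TE)
family through a diploid, panmictic Wright–Fisher population in which the
host's only (or main) line of defence is the *trap model*: the TE family
remains active in an individual until at least one family member has
inserted into a piRNA cluster, whereupon piRNAs silence every copy of the
family in that individual's germline.  Silencing is dominant and acts in
trans — one heterozygous cluster insertion suffices — and, in the basic
model, is permanent once a cluster insertion is fixed in the population.

Each generation the engine executes, in order:

1. two parents per offspring are drawn with probability proportional to
   fitness (with replacement; the two parents may coincide);
2. each parent contributes one recombinant gamete, built per chromosome
   from a Poisson number of crossovers (no interference, uniform
   breakpoints) with a random starting haplotype, so chromosomes assort
   independently;
3. if the parent is *active* (it carries no cluster insertion), each
   non-reference copy on the gamete is excised independently with
   probability `v`;
4. if the parent is active, the gamete receives `Poisson(u * k)` novel
   insertions, `k` being its non-reference copy number, each at a
   uniformly drawn bp; a draw landing on a site already occupied on that
   gamete is discarded, not resampled;
5. the zygote is the union of the two gametes;
6. cluster insertions are counted, 7. fitness is evaluated, and 8. the
   per-generation record is emitted.

Haplotypes are sparse sorted sets of occupied sites at single-bp
resolution (0-based, half-open intervals).  Every bp of the genome is an
insertion target, so a class of sites (cluster, reference, ordinary
genomic) is hit in proportion to its share of the genome.

## Genome architectures

`build_architecture()` places a piRNA cluster at the start and an
optional neutral *reference region* at the end of each chromosome.
Reference insertions are inert on every axis — they do not silence, do
not transpose, are immune to excision, and carry no fitness cost — which
makes them a neutral marker class against which selection on cluster
insertions can be measured (`selection_contrast()`).

The default genome mirrors a *Drosophila*-like setup: five 10 Mb
chromosomes at 4 cM/Mb with a 300 kb cluster each, i.e. clusters occupy
3% of the genome; the default population size is `N = 1000`, the default
transposition rate `u = 0.1` per copy and generation, no excision, and
neutral insertions.  `predefined_scenario()` bundles the architecture
variants used throughout: a single non-recombining 1 Mb cluster
("flamenco", the somatic pathway), the same megabase distributed over
five chromosomes ("germline"), both with recombining-cluster variants,
and 200 Mb genomes with 3.5% (germline) or 0.15% (somatic *flamenco*)
cluster content.  Setting `cluster_recombining = FALSE` excludes
crossover breakpoints from the cluster interval and removes it from the
chromosome's map length, so the cluster segregates as one Mendelian
locus.

## Fitness models

Three fitness models act on the diploid copy number (reference copies
never count):

* linear, `w = 1 - x n`, every copy including cluster copies costs `x`;
* exponential, `w = 1 - x n^t` with `t >= 1`, for synergistic costs such
  as ectopic recombination;
* cluster-neutral, `w = 1 - x n_genomic`, where cluster insertions are
  cost-free.

Fitness is floored at 0 (the closed forms go negative for large `n`;
proportional selection needs non-negative weights), and an individual
with `w = 0` never reproduces.  A run stops with status `"extinct"` when
population mean fitness drops below 0.1, and with `"lost"` when no copy
remains.

## Invasion analytics

For `n` seed insertions each at frequency `1/(2N)`, the probability of
establishment is approximated by `pe = 1 - (1 - 2u)^n`
(`establishment_probability()`); the per-copy factor `2u` is a small-`u`
branching-process approximation, so simulated establishment falls
somewhat below `pe` at large `u` (e.g. `u = 0.1`).  A second closed form,
`fa = prod((1 - p_i)^2)` (`fraction_active()`), gives the expected
fraction of individuals that escape all segregating cluster insertions
under Hardy–Weinberg random union of gametes; it ignores linkage between
cluster sites and is accurate to a few percent in simulated populations.

`annotate_phases()` splits a trajectory into the three invasion phases:
*rapid invasion* (unconstrained amplification), *shotgun* (containment by
many segregating cluster insertions), and *inactive* (a cluster insertion
has fixed).  The shotgun onset is the moment at which 99% of individuals
carry a cluster insertion.  Two conventions for the onset exist and give
noticeably different summary statistics: applying the threshold to each
replicate separately (used by `annotate_phases()`), or to the
replicate-averaged carrier fraction (`shotgun_onset(convention =
"averaged")`); the averaged convention is the one behind published
"cluster insertions at onset" values, and reads about 0.3–0.4 insertions
higher because laggard replicates delay the common crossing.  Phase
stability is the standard deviation of the per-generation population-mean
copy number within the phase.

`classify_outcome()` labels a finished run `lost`, `extinct`,
`three_phase` (a fixed cluster insertion exists, or at least 99% of
individuals are carriers) or `tsc_balance`.  The
transposition–selection–cluster balance is recognised operationally: TEs
persist (at least ~1 copy per diploid on average), no cluster insertion
is fixed, fewer than 99% of individuals carry one, and the ordinary
least-squares slope of mean copy number over the trailing 20% of
generations is below `1e-3` copies/generation.  The abundance floor keeps
a flat remnant of one or two copies *en route* to loss from counting as
balance; the slope tolerance is a package choice, as no operational
stability criterion is published.

## Numerical and design choices

* **Randomness** — all draws (R and C++ alike) run through R's RNG, so a
  single `set.seed()` reproduces a run bit-for-bit.  Replicate `k` uses
  the derived seed `(seed + 104729 k) mod (2^31 - 1)`, making any
  replicate reproducible in isolation.
* **Transposition convention** — the Poisson mean uses the *gamete's*
  copy number, giving the canonical per-copy rate `u` per diploid
  generation in expectation.  Because novel copies land on the source
  gamete, amplified copies start out linked; this raises the variance of
  lineage growth and measurably lowers establishment below the
  independent-branching value at high `u` (about 0.73 vs 0.80 observed
  for 10 seeds at `u = 0.1`).
* **Collisions** — an insertion drawn onto an occupied site of the same
  gamete is discarded (not resampled), so very small genomes lose a
  fraction of transpositions.
* **Mating** — parents are drawn independently per offspring with
  replacement and selfing is allowed; forbidding selfing would change
  drift variance only at order `1/N`.
* **Coordinates** — bp-resolution sites keep the occupied-site collision
  rate realistic for genomes from 1 Mb to ~2 Gb (the supported maximum is
  `2^31 - 2` bp).
* **Degenerate inputs** — zero-fitness populations raise an explicit
  extinction error in `step_generation()`; `run_invasion()` instead
  records the terminal status.  Empty clusters, empty populations and
  one-site genomes are all legal.

## What the simulations do and do not emulate

The engine generates the full joint stochasticity of drift,
recombination, transposition, excision and selection for one focal TE
family in a closed population of constant size.  It does not model TE
sequence evolution or escape mutants, insertion-site preferences or
orientation (e.g. the antisense bias of *flamenco*), multiple interacting
families, paramutation-like conversion of euchromatic insertions, siRNA
pathways, demography, or separate sexes.  Passing checks on synthetic
invasions therefore validate the population-genetic mechanics of the trap
model, not these additional layers of real piRNA biology.

## Scale of the shipped checks

The test-suite and `scripts/acceptance.R` rerun the main experiments at
desk scale, chosen once as follows: establishment counts use 1,000
replicates with early stopping; the invasion-slowdown statistics use 45
replicates at the full default size (`N = 1000`, 500 generations); phase
stability and fixation checks scale the population to `N = 250` and
`N = 100` (fixation time grows as `2Ne`, so horizons scale
accordingly); selection contrasts use `N = 250` with 80 replicates,
evaluated while cluster sites still segregate (generation 400–500) —
after ~4N post-silencing generations drift erases the contrast.  For the
cluster-neutral contrast the experiment uses `u = 0.3`: the indirect
advantage of a cluster allele is roughly the transposition load it
prevents per generation (~`u`, nearly independent of `x` since abundance
equilibrates near `u/x`), and at `N = 250` a larger `u` is needed for
selection to beat drift.  Parameter-space scans draw `(u, x)`
log-uniformly (matching the log-scaled axes on which the outcome
quadrants are defined) with 1,000 seed insertions per point and 3,000
generations at `N = 250`.

## Limitations

The trap model here is deliberately minimal: one insertion silences
completely and permanently, every cluster bp is an equally good trap, and
fitness depends only on copy number.  Quantities tied to the late shotgun
phase (e.g. the residual novel-insertion rate hundreds of generations
into containment) are sensitive to the exact transposition bookkeeping
and to replicate timing spread, and show the largest relative deviations
from published reference values; early-phase dynamics, establishment,
onset statistics and all ordinal contrasts are reproduced closely.
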