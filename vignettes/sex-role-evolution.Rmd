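---
title: "Modelling the evolution of parental sex roles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of parental sex roles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexrolesim)
```

## The model

`sexrolesim` is an individual-based simulation of the conflict between the
sexes over parental care. The population lives in discrete days. Every
individual is haploid, carries four loci — a female care duration `Tf`
(days), a male care duration `Tm`, a female mating preference `p` and a male
ornament size `s` — and is, on any day, in one of four states: juvenile,
pre-mating, mate search, or caring. Each locus is expressed only in the sex
it belongs to; all four are carried and transmitted by everyone.

The daily cycle is:

1. **Mortality.** Each individual survives the day with probability
   `1 - m[sex, state]`; males additionally pay the ornament viability cost
   `1 - beta * s^2` as a multiplicative factor. The default mortality of
   0.001 per day in every state makes the expected lifespan 1000 days, which
   we equate with one generation for reporting.
2. **State advancement.** Maturation, pre-mating and care countdowns tick
   down; juveniles whose maturation (20 days) has elapsed enter the
   pre-mating state, which lasts a fixed sex-specific number of days (0 by
   default, i.e. straight into mate search).
3. **Clutch resolution.** When the longer-caring parent of a clutch stops —
   by finishing its intended care or by dying — the clutch resolves. Each of
   the `clutch_size` offspring (1 by default) survives with probability
   `S(Ttot) / (1 + gamma * N)`, where `Ttot = Tf_real + Tm_real +
   sigma * Tf_real * Tm_real` is the realized total effort,
   `S(T) = T^2 / (T^2 + B^2)` the saturating survival curve, and `N` the
   number of living individuals on the day of resolution. A parent that dies
   mid-care contributes the days from mating to death instead of its
   intended duration.
4. **Mating market.** Searching females are processed in random order; each
   encounters one uniformly drawn searching male. Under random mating every
   encounter mates; with female choice the female accepts with probability
   `1 / (1 + kappa * exp(alpha * (p - s)))`. Mated pairs enter the caring
   state with their sex's expressed care allele as the countdown; a rejected
   pair loses the day. Nobody has more than one encounter per day.

Inheritance is Mendelian per locus (a fair coin between the parents), with
mutation probability `mu = 0.005` per locus: care loci step ±1 day with
equal probability (clamped at 0), the continuous loci add a Cauchy(0, 0.01)
step clipped to ±0.05. Offspring sex is a fair coin.

The benchmark constant `B = 20` has a useful interpretation: with no
pre-mating period, a lone caring parent re-mates immediately after each
bout, so its lifetime reproductive success is proportional to
`W(T) = S(T)/T`, which peaks exactly at `T = B`. The density term
`1/(1 + gamma * N)` regulates population size without distorting relative
fitness; at `gamma = 0.003` the baseline population fluctuates around 2000
females and 2000 males.

## What the simulations show

From a symmetric egalitarian start `(Tf, Tm) = (20, 20)` the mean care of
both sexes first declines to about 5 days — the evolutionary branching
point, which `find_singular_strategy()` recovers independently from the
renewal model (see below) — where selection turns disruptive. A transient
within-sex polymorphism of no-care and care-around-10 morphs appears in
both sexes, and resolves by associating one morph with each sex: the
population jumps to one of two stable, strongly sex-biased equilibria near
`(17.5, 2.5)` or `(2.5, 17.5)`, each satisfying `Tf + Tm ≈ B`. Symmetric
starts pick either equilibrium with equal probability. On long time scales
the regimes switch spontaneously, passing back through the branching point;
switching accelerates at smaller population sizes and with a pre-mating
period. With biparental synergy `sigma = 0.2` the population instead stays
egalitarian but inefficient (about 5 days per sex, total effort well below
`B`), retaining a broad strategy polymorphism. With female choice enabled,
female-biased care drags preference and ornament upward (a Fisherian
runaway seeded by the care pattern), while male-biased care leaves
preferences at the random-mating level.

## Fitness profiles: renewal estimator and phantom probes

The per-strategy expected lifetime reproductive success shown by
`estimate_fitness_profile()` is computed from an absorbing-chain renewal
model: a searching individual mates on a given day with the market's
empirical daily mating probability (matings per searcher-day), survives
each state at its per-day rate, cares for the probe duration `T'`, and each
mating contributes the expected offspring value averaged over (i) the
focal's own realized-care distribution (it may die mid-care) and (ii) the
empirical distribution of partner realized care taken from actual matings.
Using the mating-weighted partner distribution matters: partners are
sampled in proportion to their availability, which is what makes no-care
strategies self-limiting — as they spread, most encounters are with other
no-care partners and the strategy's clutches fail.

The independent check is `probe_fitness_mc()`: phantom individuals with a
fixed strategy are injected into a frozen copy of the population
(mutation off). They search, mate and care like residents, but their
clutches recruit nobody; each resolved clutch credits the phantom with its
expected offspring number. Phantoms perturb the market they are measuring,
so keep them below roughly 5% of the population; with that precaution the
two estimators agree within Monte-Carlo error across the strategy grid.

The numerical invasion analysis (`invasion_fitness()`,
`find_singular_strategy()`) applies the same renewal model to a rare mutant
in a monomorphic resident market, treating care as sex-independent as an
adaptive-dynamics analysis requires. Market statistics come either from a
short mutation-off simulation or from a deterministic balance of state
flows. The balance mode corrects the daily mating probability for
Poisson-scale fluctuations of the searcher pools
(`m = 1 - 1/sqrt(pi * lambda)`); it deliberately ignores a slower finite-N
effect, the stochastic sex-ratio queue, in which the momentarily
overrepresented sex accumulates waiting searchers. The queue noticeably
depresses the surplus sex's mating rate for long-caring residents, so the
balance mode is most accurate for short care cycles; both modes locate the
same singular strategy, which is the quantity the analysis exists for.

## Desk-scale study conditions

The full-size model (about 4000 individuals) reproduces the phenomena but
is unnecessarily slow for testing. We therefore run most analyses at a
documented desk scale, chosen once:

* **Single trajectories** (branching level, biased equilibria, synergy):
  density scale 8, i.e. `gamma = 0.024`, about 250 individuals per sex.
* **Replicate ensembles**: the 30-replicate symmetric-start ensemble and
  the long lability run use density scale 16 (about 125 per sex), where
  outcomes resolve and regimes switch fastest; the 20-replicate
  sexual-selection ensemble and the 10-replicate pre-mating ensemble stay
  at scale 8 because their signals (preference differentiation, the
  pre-mating survival burden) drown in drift or collapse the population at
  smaller sizes. Replicate seeds derive as `base_seed + replicate`.
* **Mutation rate scaled by 8** (`mu = 0.04`) in both cases, so that the
  mutational input per generation, which scales with `N * mu`, stays
  comparable to the full-size population; without this the approach to the
  branching point stretches several-fold.
* **Horizons** of 1200–8000 generations depending on the question, with the
  equilibrium runner stopping once two consecutive 100-generation windows
  agree on a biased regime (|bias index| > 0.5) and then settling 200 more
  generations for averaging.

Smaller populations drift more and switch regimes faster — a feature the
model itself predicts — so ensemble labels are taken at the moment a stable
regime is first reached, and equilibrium averages use the settle window.
Two desk-scale caveats are worth knowing: starting a small population at
the branching point (rather than passing through it) can collapse it,
because no-care × no-care matings recruit nobody; and with long risky
pre-mating periods the stationary population shrinks further, which is why
the pre-mating ensemble uses a 7-day period at scale 8 rather than anything
longer or smaller.

## Numerical and design choices

* **Event order and off-by-ones.** The verbal model description fixes only
  that mortality opens the day. We resolve the remaining freedom as:
  mortality → advancement → resolution → mating. A carer's realized care is
  finalized on its last intended care day (so an undisturbed pair's clutch
  resolves exactly `max(Tf, Tm)` days after mating) and the carer re-enters
  search the following day, making the care–search–care cycle `T + 1` days.
  A parent dying `k` days after mating contributes `k` days of realized
  care.
* **Density term.** `N` counts all living individuals (both sexes, all
  states) on the resolution day; unresolved-clutch offspring do not exist
  as individuals and experience no mortality before recruitment.
* **Ornament cost** is applied multiplicatively to per-day survival
  (`(1 - m)(1 - beta s^2)`), the "percentage" reading; at `beta = 1e-6`
  the additive-hazard alternative is numerically indistinguishable.
* **Boundaries.** Care alleles clamp at 0 (a decrease from 0 stays 0,
  a weak upward boundary bias). The ornament clamps at 0 (a physical size;
  `ornament_floor = FALSE` lifts this); the preference is unbounded and
  may drift negative — the acceptance formula remains valid there.
* **Survival proportionality.** Offspring survival is taken as
  `S * density` with `clutch_size = 1`; this lands the full-scale
  demographic equilibrium at the expected ~2000 per sex, which is the
  empirical justification for leaving the proportionality constant at 1.
* **Extinction** is an outcome, not an error: runs truncate with a flag.
* **RNG.** The engine uses an internal xoshiro256++ stream seeded from
  `params$seed`; trajectories are bitwise reproducible from the parameter
  set alone, independent of R's RNG state.

## What the generator does not emulate

The synthetic populations are exactly the model's world: no spatial
structure, no environmental variation, no condition-dependent care, no
good-genes benefits, haploid genetics with four unlinked loci. Passing
tests therefore show that the implementation reproduces the model's
phenomenology at the stated scales — not that real populations behave this
way. Quantities tied to deep time (mean switching intervals at full scale)
are out of desk-scale reach; the tests check their existence and direction
at reduced scale instead.

## A worked example

```{r example, eval = FALSE}
p <- sim_params(gamma = 0.024, mu = 0.04, n0_per_sex = 250, seed = 1,
                init_careF = 20, init_careM = 20)
tr <- run_to_equilibrium(p, max_gen = 4000)
tr$label
branching_care_level(tr)$level
classify_equilibrium(tr, window = 200)[c("Tf", "Tm", "bias")]
plot(tr)

find_singular_strategy(sim_params(), range = 1:15, mode = "balance")[1:2]
```
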