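---
title: "Simulating cryobank semen use in a selected cattle breed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cryobank semen use in a selected cattle breed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Intensively selected dairy cattle breeds accumulate inbreeding and lose
ground on functional traits (fertility, longevity) that are negatively
correlated with the production trait under selection. National gene banks
store frozen semen of "original" bulls, and a standing question for breed
managers is what that stored semen is actually good for several generations
later: can it redirect the selection goal towards a deteriorated functional
trait, or restore genetic diversity, and at what cost to the production
trait?

`cryosire` answers this by forward simulation of a stylized but complete
progeny-testing scheme, with an explicit pedigree, exact coancestry
bookkeeping, rule-based cryobank sampling, and a one-time reuse of stored
bulls partway through the scheme.

## The simulated breed

Thirteen discrete generations (0–12), each of 100 male and 10,000 female
calves. Four parent paths are selected each generation:

| path              | selected | from        |
|-------------------|---------:|-------------|
| sires of males    |       10 | 100 bulls   |
| dams of males     |       50 | 10,000 cows |
| sires of females  |       20 | 100 bulls   |
| dams of females   |   10,000 | 10,000 cows |

Mating is random within the selected lists (each calf draws its sire and dam
independently and uniformly), so progeny sizes vary multinomially; the
dam-to-dam path is unselected.

## Genetic model

Two traits: A, a production trait under selection, and B, a functional trait
that deteriorates through a genetic correlation of ρ = −0.3. Both traits
have unit genetic standard deviation in the base population and follow a
purely polygenic (infinitesimal) model:

* Founders: `A ~ N(0, 1)` and `B = ρA + sqrt(1 − ρ²) β`, β standard normal.
* Offspring: mid-parent mean plus a Mendelian sampling deviation with
  standard deviation `sqrt(0.5 [1 − (F_sire + F_dam)/2])`; the per-offspring
  deviation pair for (A, B) is bivariate normal with correlation ρ, built by
  the same Cholesky construction as the founder draw (any bivariate normal
  construction with these moments is equivalent).
* EBVs are imposed rather than estimated: `EBV = CD·g + e·sqrt(CD(1 − CD))`
  with accuracy CD (squared correlation between EBV and true value) of 0.6
  for bulls and 0.4 for cows, both traits, all generations. There is no
  BLUP machinery and no re-evaluation: each animal is evaluated once at
  birth, on its realized (uncentered) genetic value. Within a cohort this
  leaves rankings — the only thing selection uses — unaffected. Uncentered
  EBVs do shrink across-generation EBV comparisons towards zero by the
  factor CD; the one place where across-generation EBVs are compared (the
  total-merit choice among banked bulls, below) therefore favours recent,
  high-A bulls, which is the behaviour the reference scheme describes.
* The total merit index is `TMI = w_A·EBVA + w_B·EBVB`, `w_B = 1 − w_A`.

## Kinship bookkeeping

Selection decisions and all diversity statistics rest on exact pedigree
coancestries. Because the scheme only ever mates animals of the previous
generation (plus, once, stored bulls), the package propagates a dense
cohort-by-cohort coancestry matrix instead of a relationship matrix over the
~131,000-animal pedigree:

* `phi(o1, o2) = ¼ [phi(s1,s2) + phi(s1,d2) + phi(d1,s2) + phi(d1,d2)]`,
  diagonal `½ (1 + phi(s, d))`; an offspring's inbreeding coefficient is its
  parents' coancestry.
* Bulls that may be used again later (cryobank candidates) keep explicitly
  propagated cross-rows against every subsequent cohort.
* The kernel is written in C++ and writes into a small pool of preallocated
  buffers; a full-scale cohort matrix is 10,100², about 0.8 GB, and the
  recursion costs one pass over it per generation. Matrices are stored in
  double precision throughout.
* A memoized pairwise recursion (`kinship_pair()`) provides an independent
  oracle; the test suite checks the vectorised propagation against it
  entrywise on random pedigrees.

Average kinship statistics are means over *distinct* pairs: including
self-kinships would mix the inbreeding level into what is reported as
between-animal coancestry, and the two are reported side by side.

## Stage 1 and cryobank sampling

During generations 0–8 every selected path uses EBVA only. While this runs,
young bulls enter the cryobank under the French-style rules for "original"
bulls, applied with the empirical mean and standard deviation of each
100-bull cohort and strict inequalities:

1. EBVA more than 3 s.d. above or below the cohort mean,
2. EBVB more than 2 s.d. above the cohort mean (functional trait: only the
   upper tail is worth storing),
3. a sire of sires none of whose sons was selected on either sire path,
   assessed one generation after his use.

Rules 1–2 cover the male cohorts of generations 0–7 and rule 3 sires of
sires born in generations 0–6, so that the lagged assessment still falls
inside stage 1; these windows also reproduce the reference mean birth
generations of the banked bulls (≈3.5 for the threshold rules, ≈3.0 for the
unused sires). A bull satisfying several rules is stored once with merged
reasons. A store-everything variant (`bank_mode = "all_young_bulls"`) keeps
every young bull of the eligible cohorts instead.

## Stage 2 scenarios

At generation 9, four cryobank bulls may be chosen — either the best on the
TMI (computed among banked bulls from their stored EBVs, default
`w_B = 0.5`) or those with the lowest mean kinship with the whole current
population — and sire a fraction (0, 40 or 80%) of the 100 male calves; dams
are drawn from the regular 50 dams of bulls, and stored semen is used in
this single generation only. Generations 9–12 then run under the scenario's
selection criterion:

| code | cryobank bulls | % of sons | criterion | male lines |
|------|----------------|----------:|-----------|------------|
| b1   | best TMI       |        40 | EBVA      | unchanged  |
| b2   | none           |         0 | TMI       | unchanged  |
| b3   | best TMI       |        40 | TMI       | unchanged  |
| d1   | min. kinship   |        40 | EBVA      | unchanged  |
| d2   | none           |         0 | EBVA      | conserved  |
| d3   | min. kinship   |        40 | EBVA      | conserved  |

Under male-line conservation each sire of sires gets exactly ten sons; the
best son (on EBVA) of each sib group becomes the next sire of sires and the
two best become sires of dams, so each paternal line keeps exactly one
sire-of-sires slot regardless of across-line merit — without this
protection, sons of low-merit stored bulls are simply never selected (which
is precisely scenario d1's outcome). The criterion switch in b2/b3 applies
to all selected parent lists.

Two design points were genuinely open and are resolved as follows:

* **d3 at generation 9.** Line conservation fixes 10 paternal lines of 10
  sons, but 40% cryobank siring suggests 4 bulls × 10 sons plus 10 regular
  sires × 6 sons — 14 lines, which breaks both the line size and the 10/20
  sire counts from generation 10 on. The package instead gives the 4
  cryobank bulls and the 6 best regular sires one 10-son line each: exactly
  10 lines, the stated 40% cryobank share, and unchanged parent counts.
* **"Existing population" for the minimum-kinship choice** is read as the
  full generation-8 cohort, males and females together.

The expected genetic contribution of the used bulls to any later generation
is computed by the exact labelled-gamete recursion through the pedigree
(`expected_contribution()`), which is the infinite-run limit of gene
dropping; the Monte-Carlo `gene_drop()` is kept for validation.

## Replicates, seeds and problem sizes

`run_replicates()` gives every replicate its own L'Ecuyer-CMRG stream
derived from one master seed, and branches each replicate's stage-1 state
into all requested scenarios on sub-streams — scenarios therefore share
stage-1 histories exactly, as in the study design, and every run is
bitwise reproducible from `(master_seed, replicate, scenario position)`.

The reference results average 1000 replicates. Because every reported
quantity is already a mean over a 10,100-animal cohort, across-replicate
standard errors are small: the package's own acceptance checks use 10–20
full-scale replicates and state tolerances as the larger of the quoted
absolute band and three across-replicate standard errors. The bundled
`scripts/acceptance.R` uses 20 replicates (~10–15 minutes on one core); the
test suite uses 10.

## What the generator does and does not emulate

The simulation reproduces the structural features that drive the reference
results: truncation selection at fixed accuracies, multinomial progeny
sizes, inbreeding-adjusted Mendelian sampling, exact coancestry dynamics and
rule-based gene-bank sampling. It does not model overlapping generations,
unbalanced use of reproducers beyond random mating, semen-dose limits,
marker or QTL effects, genomic selection, or re-estimated breeding values.
Passing tests therefore validate the scheme dynamics under the stated
idealizations, not the behaviour of any real breed; in real populations the
unequal use of sires alone makes effective sizes much smaller than census
numbers.

## Numerical choices

* Ties in every truncation or within-line selection break by ascending
  animal id: a measure-zero event under continuous EBVs, fixed for
  reproducibility.
* The 10 sires of males and 20 sires of females are independent truncations
  of the same cohort (under one criterion the former is a subset of the
  latter); exclusivity is never imposed.
* Threshold rules use strict inequalities; a cohort with zero EBV spread
  samples no bull.
* With a constant accuracy per sex, `var(EBV) = CD`, and the empirical
  cohort thresholds make the expected rule-2 yield per 100-bull cohort about
  2.19 rather than the naive `100·P(Z > 2) = 2.28` (order-statistic
  effect); both are checked by Monte-Carlo in the tests.
* Coancestry matrices are exact to double precision; the propagation is
  checked to 1e-12 against the pairwise recursion.

## Known limitations

* One-time cryobank use only; multi-generation reuse and dose accounting
  are out of scope.
* Female-path cryopreservation is not modelled.
* `scale < 1` configurations shrink cohorts proportionally for fast tests
  but change selection intensities, so scaled runs do not reproduce
  full-scale magnitudes.
* The Welch two-sample test behind `contrast_replicates()` is the package's
  choice for comparing replicate-level metrics; the reference study does not
  name its test.
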