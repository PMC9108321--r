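---
title: "Deterministic models of suppression gene drives and unlinked resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic models of suppression gene drives and unlinked resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivesim)
```

## The problem

A population-suppression gene drive is a selfish genetic element engineered
to spread through a pest population while reducing its fitness. Whether the
suppression lasts depends on whether resistance evolves first. This package
implements deterministic, discrete-generation genotype-frequency recursions
for three confrontations between a drive and *unlinked* resistance:

* one or two **male-limited homing drives** versus a dominant, cost-free
  allele that blocks segregation distortion outright (mechanistic, "type-M"
  resistance);
* a **two-sex homing drive** and a **ClvR (cleave-and-rescue) toxin-antidote
  drive** versus an allele that forces a fraction of a mother's progeny to
  sib mate (population-structure, "type-P" resistance);
* a male-limited homing drive embedded in an explicit **ecology** with
  ceiling density dependence, where the drive's viability cost can be
  density-independent or density-dependent.

Every recursion is built the same way: enumerate all parental matings,
weight each by the parents' (fitness-weighted) frequencies, multiply by the
gamete or offspring distribution the parental genotypes produce, sum, and
renormalize. There is no mutation, migration, linkage, or drift; loci are
unlinked with two alleles each.

## Core engine

`enumerate_genotypes()` builds the genotype tables (`3^L` diploid genotypes
or `2^L` haplotypes for `L` loci) in a fixed lexicographic order, so every
exported table is bit-for-bit reproducible. `diploid_model()` /
`next_generation()` implement random union of sexes with sex-specific
gamete rules and fitnesses. Because generations are discrete and
non-overlapping, weighting parental genotypes at gamete production
("fitness effects operate on adults during gamete production") is the same
operation as viability selection before mating; each model module states
which interpretation its parameters carry.

The haploid-sex models use `family_model()`: haploid females and males pair
into families, each family is a single diploid in which distortion,
conversion and viability act, and the diploid releases haploid progeny at a
1:1 sex ratio. Mothers carrying the sib-mating allele Q force a fraction
`m` of their progeny to mate within the family; the brothers so used are
removed from the random mating pool (equal male and female mass leaves the
family), which prevents sib mating from gaining an automatic transmission
advantage. Sib-mated daughters whose family has no surviving brothers are
treated as unmated (their mass is lost); in the mass-action recursion this
case has measure zero, but the individual-based test oracle needs the
convention.

### Homing as a conversion event

Imperfect homing (`d < 1`) is modelled as a germline conversion event: with
probability `2d - 1` the heterozygous germline converts and produces only
drive gametes, otherwise it segregates Mendelianly. The marginal drive
output of a heterozygote is `d`, so random mating — which only sees the
marginal — is unaffected by this choice. Sib-mated pairs, however, draw
both gametes from the *same* germline, so the conversion state correlates
sibs' genotypes and increases the between-family variance that sib mating
feeds on. This distinction is invisible at `d = 1` and in the diploid
random-mating models, but in the sib-mating model it is consequential: with
independent per-gamete draws the imperfect drive's fixation range at
`m = 0.2` shrinks by only 0.01 and the polymorphic-zone mean fitness rises
by at most 0.19; with the conversion event the shrinkage is 0.05 and the
rise 0.26, the behaviour the robustness analyses report.

## Parameters

| symbol | meaning | range | default / figure value |
|---|---|---|---|
| `s`, `s1`, `s2` | homing-drive homozygote fitness reduction | [0, 1] | scanned |
| `d` | distortion: marginal drive-gamete fraction of a heterozygote | [0.5, 1] | 1 |
| `h` | heterozygote fitness reduction (per locus) | [0, 1] | 0 |
| `sigma` | ClvR CC fitness reduction | [0, 1] | scanned |
| `m` | sib-mating fraction enforced by Q mothers | [0, 1] | 0.2 / 0.5 / 0.95 |
| `f` | fixed inbreeding coefficient (closed form only) | [0, 1) | 0 |
| `b` | per-female birth rate | > 0 | 3 |
| `K` | ceiling threshold on progeny number | > 0 | 1e9 |
| `sb`, `sK` | density-independent / -dependent AA viability reduction | [0, 1] | scanned |

Initial frequencies follow the published experiments: drives 0.01 (single)
or 0.005 (pairs), resistance from 0.005; sib-mating runs start drive and Q
at 0.01; ClvR runs start C and Q at 0.07; ecology runs start drive and
resistance at 0.0005 with the population at `K`.

## Numerical choices

* **Fixation / loss.** An allele is declared fixed at frequency
  `1 - 1e-8`, lost at `1e-8`. Deterministic recursions approach boundaries
  asymptotically, so any finite criterion is a convention; this one is far
  inside the printed precision of every reproduced number.
* **Convergence.** Iteration stops when the largest per-genotype (or
  per-family) frequency change falls below `1e-13`, or at the generation
  cap: `1e4` generations for the two-drive scans, `1e5` for the sib-mating
  homing model, `2e4` for ClvR, `5e3` for ecology runs.
* **Grid searches.** Resistance-free maxima and invasion thresholds are
  defined on 0.01 grids of the scanned coefficient (for two drives the grid
  is on the *combined* suppression `1 - (1 - s1)(1 - s2)`, with equal
  per-drive effects). Outcomes are monotone along these grids — an
  invariant the test suite certifies against exhaustive scans — so the
  default search bisects over the grid and returns the identical grid
  point at a fraction of the cost; `method = "scan"` remains available.
* **Boundary grid points.** Exactly at an analytic boundary the recursion
  is marginal: e.g. the sib-mating homing drive at `m = 0.2`, `s = 0.80`
  sits at drive frequency 0.999997 after `1e5` generations, so a grid
  classification there measures only the fixation threshold. Where a
  perfect-drive range limit is needed as a reference (the robustness
  comparisons), the analytic bound `1 - m` is used instead and the
  recursion is checked just inside it.
* **The `sigma = 1` ClvR boundary.** For every `sigma < 1` the ClvR
  recursion from an intact background fixes the null allele G and leaves C
  at `1/(1 + sigma)`. Exactly at `sigma = 1` (CC lethal as well as ccGG)
  the approach time diverges and the recursion settles on a neutral curve
  of interior equilibria whose position depends on the initial G frequency
  (verified against an independent four-gamete recursion). The evolved
  suppression state the closed form describes — G fixed, only Cc viable,
  mean fitness 0.5 — is reached by iterating from the converted background
  (`init_G = 1`), which is how the package evaluates that endpoint.
* **Ecology conventions.** Births are `N = b x` adult females (half the
  adults); knockdown multiplies that generation's `N` by the retained
  fraction (a proportional cull; a reset-to-initial variant is available
  behind `mode = "reset"`, but proportional culling is the only reading
  that stays meaningful once the population size has moved away from its
  initial value). Extinction is a census convention (< 1 adult) on an
  otherwise continuous-mass model; resistance-free scans therefore let the
  allele race continue past the census threshold (`stop_at_extinction =
  FALSE`), since truncating at the convention would misreport the genetic
  outcome by one grid step at low birth rates.

## What the models do and do not show

The recursions are infinite-population mass-action models. Passing tests
show that the implementation reproduces the analytic thresholds
(`s < 1 - m` fixation, `s > 1/m - 1` loss, polymorphic frequency
`1/s - m/(1 - m)`, equilibrium ClvR frequency
`(1 - f sigma)/[(1 + sigma)(1 - f)]`), the closed-form mean-fitness curves,
and the figure-level grid results; a single generation also sits within the
sampling noise of an individual-based Wright-Fisher style simulator with
`1e6` progeny (the only stochastic component in the repository — drift
lives in the test oracle, never in the engine). They do not show anything
about finite populations: no drift, no stochastic loss of rare drives, no
Allee effects, and no demographically induced sib mating as populations
shrink. The ecology model's density dependence is a hard ceiling; other
regulation forms (Beverton–Holt, Ricker) would change the quantitative
knockdown results.

Two model-level caveats surfaced during validation and are retained as
documented behaviour rather than patched:

* In the density-dependent ecology mode at low birth rates the drive's own
  suppression of density relaxes selection against it (the relative
  viability of AA rises toward `2/b` as the population settles at
  `K(1 - sK) b/2` progeny), so the no-knockdown resistance-free limit at
  `b = 3` is 0.85, well above the 0.43 that holds whenever births keep the
  population at the ceiling through the sweep (`b = 6` and the
  density-independent mode at any `b`). At `b = 1.5` the population is not
  self-sustaining at all (`b/2 < 1`).
* The sib-mating invasion classifier for ClvR is "ClvR lost by the cap and
  Q above its initial frequency": once ClvR is lost Q is neutral and stops
  rising, so a fixed multiple of the initial frequency would misclassify
  genuine invasions.

## Problem sizes

The figure-level scans used throughout the package run 99–100 grid points
per curve with the generation caps above; a full acceptance recomputation
(`scripts/acceptance.R`) takes about a minute on one core, and the test
suite a few minutes, dominated by the `1e6`-individual stochastic oracle
and the `1e5`-generation sib-mating runs.
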