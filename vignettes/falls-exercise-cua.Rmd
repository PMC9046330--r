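---
title: "A Markov cost-utility model of supervised exercise for falls prevention during ADT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of supervised exercise for falls prevention during ADT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtfalls)
```

## The decision problem

Men receiving androgen deprivation therapy (ADT) for non-metastatic prostate
cancer lose muscle mass, strength and bone mineral density, which makes them
an unusually high-risk population for falls and fall-related fractures. The
package evaluates, from a health-system perspective, whether a 12-month
programme of twice-weekly supervised group exercise is good value compared
with usual care (advice to exercise only), measuring value as quality-adjusted
life years (QALYs) gained and Australian dollars (2019) spent or saved.

The decision statistic is the incremental net monetary benefit at a
willingness-to-pay threshold $\lambda$ = AU\$50,000 per QALY:

$$\mathrm{iNMB} = \lambda \, \Delta E - \Delta C,$$

where $\Delta E$ and $\Delta C$ are the discounted QALY and cost increments of
exercise over usual care. A positive iNMB means the intervention is
cost-effective at $\lambda$; if it is simultaneously cheaper and more
effective it *dominates*, and no incremental cost-effectiveness ratio is
reported (a negative ratio has no interpretation).

## Model structure

A cohort Markov model with 3-month cycles over a 3-year horizon (12 cycles),
starting age 68. Seven operational states:

1. **at risk (pre-fall)** — everyone starts here, utility 0.79;
2. **at risk of recurrent fall** — entered after any first fall and never
   left except by falling again or dying; carries a fear-of-falling (FOF)
   utility of 0.72 (usual care) or 0.74 (exercise);
3.–6. **major fracture, minor fracture, major injury, minor injury** —
   single-cycle tunnel states entered on a fall, with event utilities
   0.475/0.565/0.47/0.765 and one-off treatment costs of
   \$20,724/\$8,797/\$10,040/\$1,115 charged on entry;
7. **dead** — absorbing.

Each cycle, an at-risk individual falls with the per-cycle probability
derived from the annual probability (0.36 in the first-fall state, 0.65 in
the recurrent state) by the constant-rate transform $1-(1-p)^{1/4}$.
Conditional on a fall, the event tree routes the faller:

* fracture with probability 0.12, split 62%/38% major/minor;
* otherwise a non-fracture injury with probability 0.88, of which 6% are
  major; the minor-injury state also receives fallers without a treated
  injury — its utility estimate is labelled "minor injury/no injury" and its
  \$1,115 cost is an average over all such fallers, including the quarter who
  seek no care;
* only **major** events carry a risk of death (0.043 at ages 65–69, 0.065 at
  70–74), reflecting the assumption that minor injuries and fractures are
  never fatal.

Background all-cause mortality acts on non-fallers and on tunnel occupants.
The published model cites national life tables without printing them, so the
package ships a synthetic table of representative annual male death
probabilities (0.6%–2.7% over ages 60–75), documented as external defaults
and override-able; over three years this competing risk is small and
identical in both arms.

### How the exercise effect enters

The programme reduces the annual fall probability by RR 0.76, and the
*marginal* annual risks of fall-related fracture and injury by RR 0.44 and
0.70. Because the fracture and injury risks are conditional branch
probabilities in the tree, the exercise arm's conditional branches are scaled
by $\mathrm{RR}_{\text{outcome}}/\mathrm{RR}_{\text{fall}}$, so the printed
marginal relative risks are preserved after the fall probability itself has
been reduced. The scaled conditional injury probability saturates at 1 (every
non-fracture faller injured); a conditional fracture probability above 1 is
rejected as an infeasible decomposition.

This structural reading — printed probabilities as conditional branch
probabilities, death attached to major events only, uninjured fallers sharing
the minor-injury state — was selected from the small set of readings the
source tables support, as the one that reproduces the published base-case
panel; the alternatives (dividing the fracture probability by the fall
probability, applying fall death to every fall, or routing uninjured fallers
straight to the recurrent state with no cost) each misstate the published
cost or QALY increments by 30% or more. The package's base case gives
$\Delta C = -\$1{,}355$, $\Delta E = 0.0366$ QALYs and iNMB $\$3{,}186$
against published values of $-\$1{,}183$, $0.04$ (its unrounded,
table-implied value is $0.0366$) and $\$3{,}010$.

### Rewards, discounting, half-cycle correction

QALYs accrue as state membership × state utility × cycle length (0.25 y),
half-cycle corrected in the standard life-table form: the initial and
terminal occupancy rows get half weight. Event costs are charged once, on
tunnel entry, in the entry cycle only, discounted by that cycle's factor
$(1+r)^{-t/4}$ at $r = 0.05$/year, and are excluded from the half-cycle
correction (they are point events, not continuous rewards). The intervention
cost of \$767 is charged up front, undiscounted; this matches the published
scenario arithmetic, where raising the intervention cost to \$3,304 lowers
the iNMB by exactly the nominal difference.

```{r base-case}
params <- load_parameters()
run_cua(params)
```

### Duration of the exercise effect

The 3-year horizon is justified in the source as one programme year plus a
documented two-year sustained effect. The package therefore ties the
risk-reduction RRs to an `effect_years = 3` window: when the horizon is
extended the RRs lapse after year 3, while the arm-specific FOF utilities —
properties of the state, not of a time window — persist. Under this choice
doubling the horizon raises the iNMB by a factor of about 1.74 ("almost
doubled"), whereas letting the RRs run for six years nearly triples it.

## Deterministic sensitivity analysis

One-way ranges default to each parameter's published 95% CI. The exception is
the intervention cost, whose published one-way analysis explored scenario
costings up to \$3,304 per participant (supervised exercise in smaller
groups, plus out-of-pocket travel and gym fees); the package uses
\$743–\$3,304 for that bar. Scenario analyses apply the three published cost
figures (SA2a \$2,338, SA4 \$2,154, SA4a \$3,304) as pure cost substitutions;
by the upfront-cost linearity, each shifts the iNMB dollar-for-dollar, e.g.
the SA4a iNMB is the base value minus \$2,537.

A known divergence: with CI-based ranges the two FOF utilities (each CI ±0.02
around means 0.72/0.74, applied to every cycle spent at recurrent risk in one
arm only) produce the second- and third-largest tornado spreads, displacing
the fall RR (narrow CI 0.70–0.81) and first-fall probability named as most
influential in the source, whose one-way ranges were published only in
supplementary material. The package reports what its ranges imply rather than
adopting unprinted ranges.

## Probabilistic sensitivity analysis

Each parameter with a CI is sampled independently: beta for probabilities,
proportions and utilities, gamma for costs, lognormal for relative risks
(printed value treated as the median), all fitted by the method of moments
with $\mathrm{se} = (\text{CI width})/3.92$. The minor fracture/injury shares
are complements of their sampled major counterparts, preserving sum-to-one.
Draws whose sampled RRs make the conditional fracture or injury decomposition
infeasible are rejected and redrawn (about 7% of draws, driven by the wide
injury-RR interval; clamping instead would bias the marginals), with the
count reported. Each parameter has its own deterministically derived
substream, so draws do not depend on parameter ordering, and the whole run is
reproducible from its seed.

```{r psa, eval = FALSE}
psa <- run_psa(params, n_iterations = 10000, seed = 20260920)
psa$ceac        # acceptability curve on a $0-$100,000 grid
```

A second known divergence, stated plainly: the published PSA reports a 58%
probability of cost-effectiveness and a \$554-wide 95% CI on the mean
intervention NMB over 10,000 draws. Both numbers imply a per-draw NMB
standard deviation near \$15,000. Distributions fitted to the printed CIs —
the method both the source and this package state — give a per-draw standard
deviation near \$800, hence a probability of ~1.0 and a CI width near \$35.
No reading of the printed intervals yields seventeen-fold more variance, so
the package reproduces the published *mean* NMB (within 0.3%) but not the
published spread; the discrepancy is documented rather than patched over.

## Validation by microsimulation

An individual-level Monte Carlo twin simulates the exact stochastic process
the cohort engine integrates, with the same conversions, event tree,
half-cycle weights and discounting applied to realised trajectories. Its
large-$n$ means converge to the cohort totals at the $1/\sqrt{n}$ rate, and
`compare_to_cohort()` turns the comparison into z-scores. Two modes exist:
`"engine"` samples from the engine's own transition matrices (isolating
reward-accumulation bugs) and `"independent"` re-derives every per-cycle
probability from the raw annual parameters in separate code (an end-to-end
check). At $n = 200{,}000$ per arm all |z| < 3.

```{r microsim, eval = FALSE}
compare_to_cohort(params, n = 200000, seed = 1, mode = "independent")
```

What the microsimulation does *not* emulate is real-world heterogeneity:
there are no individual frailty differences, no covariates, and no deviation
from the homogeneous-cohort assumption — so agreement validates the engine's
arithmetic, not the model's fidelity to any patient population.

## Numerical choices and problem sizes

* Occupancy conservation is enforced to 1e-9 and transition rows to 1e-12.
* Distribution fits must round-trip their target moment to 1e-9.
* The test suite runs the PSA at 200–10,000 draws and the microsimulation at
  20,000–200,000 individuals; the analysis drivers use 10,000 draws and
  200,000 individuals, sizes at which Monte Carlo error is well below every
  tolerance of interest.
* Ages advance by exact quarter-years; the fall-death band uses fractional
  age and background mortality the completed year of age.
* Ties on the acceptability curve (iNMB exactly zero) count as
  cost-effective.

## Limitations

* Structural choices the source leaves open were fixed by matching its
  printed base case; other readings remain defensible.
* The published PSA spread and tornado ordering cannot be recovered from
  printed inputs (see above).
* Background mortality is a representative synthetic table, not official
  life-table values.
* Costs are fixed 2019 AUD; no re-indexing or currency conversion.
* No residential-care state, no metabolic comorbidity extensions, no
  individual heterogeneity.
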