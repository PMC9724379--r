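---
title: "Decision-tree cost-utility analysis with cuatree: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree cost-utility analysis with cuatree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuatree)
```

## The model

`cuatree` evaluates two-strategy decision trees for cost-utility analysis.
A tree starts at a decision node whose children are the competing
strategies; chance nodes split on event probabilities; terminal nodes carry
a payoff of (cost, health-state utility). The expected cost and expected
QALYs of a strategy are the probability-weighted sums over all
root-to-leaf paths, computed by leaf-to-root rollback (`rollback()`).
An exhaustive path enumerator (`enumerate_paths()`) is kept as an
independent oracle; the test suite checks that the two agree to 1e-12 on
hundreds of randomly generated trees.

Strategies are compared by incremental cost $\Delta C$ and incremental
QALYs $\Delta Q$. When the intervention is strictly cheaper *and* strictly
more effective it is *dominant*; in that quadrant (and its mirror,
*dominated*) the ratio $\Delta C / \Delta Q$ has a misleading sign, so the
ICER is withheld and the verdict reported instead. Otherwise
$\mathrm{ICER} = \Delta C / \Delta Q$. Value at a willingness-to-pay
threshold $\lambda$ is summarised by net monetary benefit,
$\mathrm{NMB} = \lambda\,Q - C$, and its increment
$\mathrm{INMB} = \lambda\,\Delta Q - \Delta C$; $\mathrm{INMB} > 0$ is the
cost-effectiveness criterion that also drives the acceptability curve.

## The worked configuration

`build_om85_model()` (equivalently `inst/extdata/om85.json`) encodes a
published-style evaluation of the oral bacterial lysate OM-85 BV versus
placebo for children aged 1–6 with recurrent respiratory tract infections
(RTI), over a six-month horizon, societal perspective, 2021 USD, and the
Colombian threshold $\lambda$ = US\$5180 per QALY. In each arm the child
either avoids a repeat RTI episode (utility `u_base` = 0.94) or suffers
one; a repeat episode costs `c_rti` = \$2022, carries utility
`u_rti` = 0.87 if survived, and is fatal with probability
`p_mort` = 0.008. The placebo repeat probability is `p_repeat` = 0.20;
OM-85 multiplies it by $(1 - \text{reduction})$ with reduction = 0.65, and
adds the drug cost `c_drug` = \$74 to every treated child.

Three modelling choices deserve emphasis:

* **Death utility is 0** for the remainder of the horizon. The source
  table leaves it unstated; 0 is the standard convention anchoring the
  utility scale.
* **QALYs are reported on the utility scale over the six-month horizon**,
  *not* multiplied by 0.5 years. The published per-person QALYs this model
  emulates are on that scale, so no annualization is applied anywhere.
* **The episode cost accrues on both the survive and the die branch**:
  the episode is treated before its outcome resolves. Equivalently, the
  drug cost can be attached to the strategy rather than to each terminal;
  the test suite proves both formulations give identical rollbacks.

At base values the rollback gives placebo (cost 404.40, QALY 0.924608)
and OM-85 (cost 215.54, QALY 0.934613): OM-85 dominates, with
$\Delta Q = 0.0100$ (rounds to 0.01) and INMB = 240.68 at the threshold.
These are the package's reproduction anchors; the headline per-patient
cost/QALY/NMB figures printed in the emulated study are mutually
inconsistent and cannot be derived from its own input table, so they are
deliberately *not* targets.

## Parameter uncertainty

Each uncertain input is given as (mean, SD, family) and mapped to its
distribution by the **method of moments** — standard HTA practice when
only two moments are published, and recorded in run metadata:

* beta (probabilities, utilities):
  $\nu = m(1-m)/s^2 - 1,\ \alpha = m\nu,\ \beta = (1-m)\nu$; requires
  $s^2 < m(1-m)$ (every shipped row passes; `u_rti` with SD 0.2 passes
  because $0.04 < 0.87 \times 0.13 = 0.1131$).
* gamma (costs): shape $(m/s)^2$, scale $s^2/m$.
* lognormal (the effect parameter): $\sigma^2 = \log(1 + s^2/m^2)$,
  $\mu = \log m - \sigma^2/2$, so the *natural-scale* mean and SD match.

The fits are analytically exact and checked empirically at $10^6$ draws.
Draws of unit-interval parameters are clamped to [0, 1] with a counted
warning. For the reduction’s lognormal the exact exceedance mass is
$P(X > 1) \approx 2.4\times10^{-5}$ — about 24 clamps per $10^6$ draws,
rare enough to leave the moments intact but not literally zero, and the
test asserts the observed count against that exact Poisson rate.

## Sensitivity analysis

**One-way DSA / tornado.** Each parameter is set to
$\text{base} \times (1 \pm 0.25)$ — utilities are clipped at 1 with a
warning when +25% leaves the scale — except the effect parameter, whose
range is the 2.5th–97.5th percentile of its lognormal, standing in for
the published confidence interval that is not printed on the reduction
scale. The outcome metric is the INMB at $\lambda$ = 5180: with a
dominant base case the ICER is undefined, so a monetary outcome is the
only one that stays well defined across every scenario. Entries are
sorted by spread (widest first), ties broken alphabetically. On the
shipped model all 14 scenario INMBs stay positive: dominance is robust to
every one-way excursion.

**PSA.** `run_psa()` is a second-order Monte Carlo: each of the 10,000
default replications draws every non-fixed parameter once from its fitted
distribution and evaluates *both* strategies on that shared binding, so
parameters common to the arms correlate them, exactly as a single tree
re-evaluated per replication. Parameters are sampled independently (no
correlation structure is asserted by the inputs). Sampling uses one
L'Ecuyer-CMRG substream per parameter derived deterministically from the
master seed: runs are bitwise reproducible and adding a parameter does
not perturb the draws of the others. The rollback is vectorised over the
draw matrix, so the full 10,000-replication PSA takes well under a second.

Results are summarised on the cost-effectiveness plane by quadrant
proportions keyed by the signs of $(\Delta Q, \Delta C)$ — quadrant
*numbers* are never emitted because numbering conventions are ambiguous —
with zero deltas counted on the favourable side so the four proportions
sum to exactly 1. The CEAC evaluates
$P(\lambda\,\Delta Q - \Delta C > 0)$ on a WTP grid (default: 51 points
from 0 to $2\lambda$), recomputed from the stored deltas; its endpoints
obey the identities $\mathrm{CEAC}(0) = P(\Delta C < 0)$ and
$\mathrm{CEAC}(\infty) = P(\Delta Q > 0)$, which the tests assert exactly.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` produces patient-level records with the first-order
structure the tree assumes: Bernoulli repeat-RTI events (placebo rate
`p_repeat`, treated rate `p_repeat * (1 - reduction)`), Bernoulli death
given an event, gamma-distributed episode costs, and *assigned* state
utilities. Utilities are deliberately not sampled per patient: the
uncertainty about a state utility is epistemic (second-order) and lives
in the PSA, not in patient-to-patient variation. `estimate_params()`
closes the loop, recovering event rates, the implied reduction
$1 - r_1/r_0$ (delta-method SE), the death rate, and the gamma cost
moments (SD from event costs only; zero-cost non-events excluded), each
with standard errors; the acceptance suite demands recovery within 3 SEs
at 50,000 patients per arm and a $\sim 1/\sqrt{n}$ error decay.

The cohorts do **not** simulate times-to-event, seasonality, repeated
episodes per child, or adverse events (the emulated study found no
adverse-event difference and models none). A green recovery test
establishes internal consistency of generator, estimator and rollback —
not external validity of the inputs themselves.

## Numerical and interface choices

Chance-node probabilities must sum to 1 within 1e-9 (validation
diagnostic and hard evaluation error); rollback/enumeration equivalence
is asserted at 1e-12; monetary values are carried at full precision and
rounded to 2 decimals only in display tables. Probabilities, costs and
utilities in a tree may be literals, bare parameter names, or arithmetic
expressions over parameters (`"p_repeat * (1 - reduction)"`); an
expression referencing an undefined parameter is an error naming it. The
JSON configuration dialect is strict — unknown keys are rejected, the
schema version is checked, and *all* validation errors are reported
together. Every CLI run writes machine-readable metadata (config MD5,
seed, n, package version); defaults for `--out` and `--seed` are logged
whenever applied, never silent.

## A known red line in the acceptance suite

The emulated study reports a "100%" probability of cost-effectiveness at
$\lambda$ = 5180, and the acceptance criterion demands at least 99.5%
before rounding. Under the printed inputs that bar is unreachable: the
repeat-episode utility's SD of 0.2 moment-matches to Beta(1.59, 0.24),
which piles mass near 1, so $\Delta Q < 0$ in roughly 57% of replications
— consistent with the study's own plane shares of 42%/57% — and in about
0.8% of replications the QALY loss outweighs the cost saving, leaving
$P(\mathrm{INMB} > 0) \approx 99.2\%$ (stable across seeds). The
companion quantities reproduce closely (cost-saving proportion ≈ 99.5%
vs the printed 99%; quadrant shares ≈ 43/57 vs 42/57), so the package
keeps the criterion faithful and visibly red rather than loosening it:
a reader of the test output learns that "100%" cannot be literal under
the model's own stated uncertainty.

## Limitations

Single-root decision trees only: no Markov cohorts, discounting (none is
applied over the six-month horizon), half-cycle correction, extended
dominance or efficiency frontiers beyond two strategies, and no
value-of-information analysis. Plots are not generated; all outputs are
CSV/JSON tables from which any standard figure can be drawn.
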