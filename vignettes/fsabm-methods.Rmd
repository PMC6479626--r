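---
title: "Agent-based models of faecal sludge reuse: methods and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agent-based models of faecal sludge reuse: methods and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsabm)
```

`fsabm` simulates two linked problems in urban faecal sludge (FS)
management economics, at a daily time step over a 2000-day (about
5.5-year) horizon:

1. **Skyloo adoption** — can a small business profitably market, build and
   loan-finance raised twin-vault composting toilets ("Skyloos") in a
   flood-prone peri-urban neighbourhood, and how many households adopt?
2. **Municipal FS site operation** — under which tariff, fine and
   enforcement regimes do vacuum-tanker companies dispose of sludge at the
   municipal site rather than dumping it illegally, and what revenue does
   the city council collect?

Both models are deliberately small and transparent: every monetary and
behavioural parameter is a named configuration field, every run is a pure
function of its configuration and seed, and every ledger closes exactly.

## The synthetic environment

The household population emulates what a field survey plus GIS layers
would provide. Defaults (`environment_config()`): 3026 households, 50/50
owner/tenant, household size drawn from a rounded normal with mean 6 and
SD 2 (floored at one person), 0.3% of households already owning a Skyloo,
and 64/148 of households open to reusing composted FS in agriculture.

**Income.** The survey moments are mean ≈ SD ≈ MK44,000/month — a
coefficient of variation of 1, which rules out a normal distribution
(16% of mass would be negative). `sample_income()` draws from a lognormal
moment-matched to both targets: `sdlog² = log(1 + (sd/mean)²) = log 2`,
`meanlog = log(mean) − sdlog²/2 ≈ 10.345`, giving a median of
`mean/√2 ≈ MK31,100` and the right-skewed shape typical of urban incomes.

**Space and flood risk.** Households are uniform on an abstract square
map (side 1000 units) with a 100-unit flood-prone strip ("dambo") along
one edge. `flood_proximity` is the perpendicular distance to the strip,
normalised to [0, 1]; plot sizes are uniform on 150–1500 area units.
Neither the original GIS normalisation nor the multiplier endpoints are
published, so both are configuration: receptiveness multipliers slide
linearly from 1.5 (inside the strip / smallest plot — pit latrines flood
or leave no room for replacement pits there) to 0.75 (far edge / largest
plot). The map scale, strip width and plot range are stylised choices; a
different geography changes *which* households are receptive but not the
population-level moments, which are what the model consumes.

## The contact network

Word of mouth travels on a Watts–Strogatz small world: households are
ordered on a ring, linked to their four nearest ring neighbours, and each
lattice edge is rewired with probability 0.2 to a uniform non-duplicate
target (home endpoint kept — one-endpoint rewiring, which preserves the
edge count `n·k/2 = 6052` exactly). This follows the ring-based
convention of the classic NetLogo small-world model; whether the original
rewired one endpoint or both is not stated, and at `p = 0.2` the
difference is immaterial for clustering and path length.
`network_stats()` (backed by igraph) confirms the small-world signature:
mean degree exactly 4, local clustering far above the random-graph level,
path lengths collapsed relative to the pure lattice.

## The Skyloo adoption model

Each day: word of mouth (below), then deterministic adoption decisions,
then the business builds for the head of the waiting list (at most one
Skyloo per day, and only with cash ≥ MK200,000), then households waiting
more than 30 days abandon the technology permanently, and at every
30-day boundary loans repay and the MK85,000 operating cost falls due.

**Awareness.** At day 0 the business markets to 300 random households,
each becoming aware with probability 0.25 scaled by its multipliers
(tenant ×0.8, flood, plot size). Thereafter any aware household passes
knowledge to each naive network neighbour with probability 0.03 per
**month** (one word-of-mouth round every `neighbour_period = 30` days).
Two calibration choices deserve emphasis, because the source material
gives the 3% figure without a cadence or a source-set:

* *Cadence.* Read as a per-day per-link probability, word of mouth
  saturates the entire 3026-household network within ~200 days; the
  observed adoption curves instead grow for the full 5.5 years. The
  monthly reading reproduces the multi-year diffusion. The per-day
  variant remains one line of configuration away
  (`neighbour_period = 1`).
* *Source set.* `spread_from = "aware"` (default): any household that has
  heard of the technology can pass knowledge on. The alternative
  `"adopters"` (only waiting/installed households spread) makes final
  adoption a site-percolation cluster over the ~10% of eligible
  households, capping adoption near 85 regardless of financing — too
  strong an interaction between affordability and reach.

**Adoption.** An aware household adopts iff it is open to FS reuse *and*
the monthly repayment is affordable. The affordability bar is
`repayment ≤ affordability_fraction × income` with default fraction
**0.12**: solving `P(income ≥ 9320/f) = 5/38` under the lognormal income
model — 5 of 38 surveyed households were observed effectively paying at
least the MK9320 repayment — gives `f = 0.118`. The often-quoted "22%"
describes the MK9320 repayment relative to *average* income, not a
household-level pass rate; used as a pass rate it admits half the
population and produces implausibly large, queue-choked adoption waves.

**Finance.** Loans are issued at the MK200,000 build cost and repaid at a
fixed monthly amount (scenario values MK9320 and MK7000) starting the
month after installation, with 1%/month interest accruing on the balance
(`B ← B(1+r) − payment`, final payment truncated). `required_payment()`
gives the annuity-due payment — MK9321.5, i.e. MK9320 at MK10 granularity
for the two-year MK200,000 loan — and `loan_schedule()` the implied term
(34 months at MK7000). The run tracks both business **cash** (liquidity;
the exact identity `cash = startup + repayments − builds − operating`
holds at every tick) and business **capital** = cash + outstanding loan
book: issuing a loan converts MK200,000 of cash into a receivable, and
capital is the measure on which the high-startup scenarios end around
MK8–10M. Strict end-of-run *cash* cannot be large while builds continue,
because every repayment is immediately recycled into the next build — an
accounting point that matters when comparing financing scenarios.

**What the defaults produce** (100 repeats, computed by
`scripts/acceptance.R` and the acceptance tests, not asserted here): mean
installed Skyloos at day 2000 ≈ 173 under MK10M/MK7000 and ≈ 148 under
MK10M/MK9320, with a further ~65–90 households having adopted and then
un-adopted; adoption ordered by start-up capital and by repayment;
capital ordered by start-up capital. The MK2M scenarios stall near 18
installs: ten builds exhaust the capital and ten loans repay less per
month than the operating cost, so the business never recovers — the model
's sharpest statement about why start-up finance matters.

## The municipal FS-site model

Agents: 5 disposal companies (a 3 m³ tanker load each with probability
0.2/day), 15 farmers (an acquisition attempt with probability 0.1/day),
and one guard (present with probability 0.65/day at the unrefurbished
site, always present after refurbishment, which also adds a fence).

Each interaction is resolved by current propensities and the guard's
daily stance, money moves between four ledgers (company, farmer, guard,
council — bribes never reach the council), and the acting agent then
updates its propensity with the payoff-learning rule
`p ← clamp(p + 10⁻⁶ · (actual − potential))`, where *potential* is the
counterfactual payoff of the alternative action under the same guard
state (with fresh draws where the counterfactual needs them, e.g. being
caught dumping). The published pseudocode's second branch literally adds
a negative quantity after a better-than-alternative outcome; it is
implemented symmetrically (probability of the performed action rises when
it out-paid the alternative), as the multiplier's sign convention clearly
intends.

Payoffs: a legal visit costs the per-visit fee MK9000 (or a MK3000 bribe
if the guard is corrupt, or nothing if the guard is absent or a monthly
permit is in force); illegal dumping costs the MK2000 fine with
probability 0.1, else nothing. A 50 kg bag of sludge is worth MK5000
to a farmer; theft costs a bribe (corrupt guard), a MK20,000 fine
(enforcing guard), or nothing (absent guard), and is physically
impossible at the fenced, permanently guarded refurbished site — an
enforcing guard there still catches and fines the attempt, a corrupt one
yields nothing because the bribe cannot open the fence. Raw sludge
matures into compost after 180 days at 50% volumetric yield, 0.05 m³
per bag (50 kg at ~1000 kg/m³); matured bags are bulk-sold at each
six-month boundary. Under the monthly permit every company renews at
each 30-day boundary (first month is a start-up grace period, so a
2000-day run bills exactly 66 renewals).

The fleet calibration (5 companies × 0.2 jobs/day × 3 m³ ≈ one load per
day; initial legal propensity 0.01) is chosen so that the baseline run
delivers ≈ 6000 m³ of illegal dumping over 2000 days and legal disposal
of order tens of m³ — the published operating scale of the site. Because
every tested fee (MK6000–15,000) and fine (MK2000–15,000) still leaves
illegal dumping the dominant payoff, the illegal volume moves by under
10% across the whole tested range; this insensitivity is the model's
central result and is what makes the per-load calibration safe: it sets
the scale, not the conclusion. Bag mass-to-volume and compost yield are
not published and are configurable.

## Scenario grids, seeds and reproducibility

`scenario_grid()`/`run_scenario_grid()` run named parameter overrides for
`repeats` Monte-Carlo repetitions; repeat *r* of every scenario uses seed
`base_seed + r`, so scenarios are compared on paired seeds (identical
population and network within a repeat) and no two repeats share a seed.
Aggregation reports the per-tick mean, SD and 2.5/97.5 percentile band.
`write_outputs()` writes per-scenario CSVs, a scalar summary CSV and a
JSON manifest from which `grid_from_manifest()` reproduces the grid
byte-for-byte. The original study used 1000 repeats for the adoption
model and 250 for the site model; the package's acceptance computations
use 100 and 250 respectively, which hold the Monte-Carlo standard error
of every reported mean well under the tolerance it is judged against.

```{r example, eval = FALSE}
g <- scenario_grid("skyloo",
  scenarios = list(high_7000 = list(startup_capital = 10e6,
                                    monthly_repayment = 7000),
                   low_7000  = list(startup_capital = 2e6,
                                    monthly_repayment = 7000)),
  repeats = 100, base_seed = 1)
s <- run_scenario_grid(g, progress = TRUE)
s$scalars
write_outputs(s, "skyloo-grid")
```

## Numerical choices and degenerate inputs

* Probabilities produced by multiplier stacking are clipped to [0, 1];
  behaviour propensities are clamped to [0, 1] after every update.
* Household size draws are floored at 1; `sd = 0` income is degenerate at
  the mean; a zero-interest loan costs `principal/term` per month.
* A payment not exceeding the monthly interest raises an error rather
  than a non-terminating schedule.
* Ties and order: the waiting list is strictly first-come-first-served;
  within a day the order is word of mouth → adoption → build → un-adopt →
  monthly settlement, so a household adopting on day *t* can be built the
  same day only if it precedes the queue, and un-adoption strikes
  strictly *after* 30 full days of waiting.
* An edge whose home node is already linked to every other node is left
  un-rewired (only relevant for degenerate tiny networks).

## What the synthetic data does and does not show

The generator reproduces the *moments and proportions* the field survey
printed — not the spatial autocorrelation of income and tenure, nor
landlord–tenant dynamics, demographic change, or price inflation over the
5.5 simulated years. Passing tests therefore demonstrate that the models
are correct implementations of their stated mechanisms at the stated
operating scale, not that those mechanisms are a validated forecast of
any real neighbourhood. Known limitations: the Skyloo model does not
model the compost-reuse stage or environmental quality (disposal and
adoption volumes are proxies); the municipal model's payoff matrix is
reconstructed from a verbal description, with all payoffs configurable;
guard bribe income after refurbishment depends on how a bribe interacts
with the fence, which the source material leaves open — here the fence
always wins, so post-refurbishment bribe income comes only from disposal
companies.
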