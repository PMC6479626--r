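# fsabm

Agent-based simulation of faecal sludge (FS) reuse economics in a
peri-urban African city, for WASH researchers and sanitation planners who
want to stress-test financing and enforcement designs before piloting
them. The package contains two daily-step models:

* **Skyloo adoption** (`run_skyloo()`): a business markets raised
  twin-vault composting toilets ("Skyloos") to 3026 synthetic households
  on a Watts–Strogatz contact network, builds at most one per day with
  available cash, and finances each MK200,000 build with a fixed-payment
  loan; households become aware through marketing and word of mouth,
  adopt if open to FS reuse and able to afford the repayment, and abandon
  the decision after 30 days on the waiting list.
* **Municipal FS site** (`run_municipal()`): disposal companies choose
  between paying to dump at the site and dumping illegally, a guard
  either enforces fees and fines or takes bribes, and farmers either buy
  compost or steal sludge. Each agent adapts its propensity by the
  payoff-learning rule
  `p ← clamp(p + 10⁻⁶ · (actual payoff − counterfactual payoff))`.

Loan arithmetic is exact annuity mathematics: the level payment for
principal *P* at monthly rate *r* over *n* months (payments in advance) is
`P·r / ((1+r)(1 − (1+r)^−n))` — MK9320 (to MK10) for the two-year
MK200,000 Skyloo loan at 1%/month.

The synthetic household generator (`generate_households()`), small-world
builder (`build_small_world()`), Monte-Carlo scenario-grid runner
(`run_scenario_grid()`) and a command-line entry point
(`inst/cli/fs_abm.R`) round out the toolkit. See
`vignettes/fsabm-methods.Rmd` for the models, assumptions and
calibration.

## Worked example

```r
library(fsabm)

set.seed(1)
env <- generate_households(environment_config())   # 3026 households
net <- build_small_world(3026, k = 4, p_rewire = 0.2)
r <- run_skyloo(env, net,
                skyloo_config(startup_capital = 10e6,
                              monthly_repayment = 7000))
r
#> Skyloo adoption run: 3026 households, 2000 ticks
#>   installed 179 | waiting 0 | unadopted 71 | aware 2257 | naive 519
#>   business cash MK15,055 (startup MK1e+07)
summary(r)$final_capital
#> [1] 9499144
```

One run of the most favourable financing scenario: 179 households have an
installed Skyloo after 5.5 years, 71 adopted but abandoned the wait, and
the business has converted nearly all of its MK10M start-up cash into an
outstanding loan book (capital ≈ MK9.5M — cash plus receivables).

```r
m <- run_municipal(municipal_config(), seed = 1)
m
#> Municipal FS-site run: 2000 ticks (per_visit, unrefurbished site)
#>   volumes (m3): legal 0.0 | illegal 6129.0 | stolen 0.00
#>   council cash MK1,230,000 | guard bribes MK1,182,000
```

Under the observed per-visit tariff essentially everything — about
6000 m³ over 5.5 years — is dumped illegally: every tested fee and fine
leaves illegal dumping the better payoff, so the volume barely moves
across the tested ranges. Refurbishing the site (fence, full-time guard)
eliminates theft, and a monthly permit collects far more council revenue
than per-visit charging.

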