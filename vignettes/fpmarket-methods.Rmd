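---
title: "Modeling a segmented family-planning market: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a segmented family-planning market: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmarket)
```

## The model

`fpmarket` simulates a stylized market for short-acting modern
contraception in a low- or middle-income setting. Two venues serve a
population of women who all need family planning (FP) but differ in
income, in how much they care about service quality, and in where they
live on a square grid:

* a **public** venue that is always free but, in the urban geometry, has a
  long wait;
* a **private** venue that charges a price per unit of protection, has a
  short wait, and whose quality is initially unknown to consumers.

Service quality is a single 0–5 index. A policymaker holds a fixed
monthly budget `B` and splits it among three instruments: *truthful
advertising* (informing a fraction of uninformed consumers of the funded
venue's true quality each month), *true quality improvement*, and
*price support* at the private venue. The package's experiments run a
60-month burn-in with the whole budget sustaining public-sector quality,
reallocate the budget at month 61 according to a named policy, and
measure the modern contraceptive prevalence rate (mCPR) — the fraction of
women currently protected — every month for 120 months.

### Demand

Each woman receives a weekly cash transfer of 1/52 of her annual
earnings, which she cannot save. Every week she checks her protection
stock; only a woman with zero months of protection shops. She compares
the no-purchase option against every affordable plan (venue `v`,
quantity `n` up to `n_max`) and picks the plan maximizing

$$U(v, n) = \alpha \,\ln(1 + c - n p_v - t_v)
          + n\, A\, \beta\, p_0\, e(\hat q_v)\,(1 + \sigma \hat q_v / 5)
          - \omega\, w\, h_v,$$

where `c` is this week's cash, `p_v` the venue's current price, `t_v`
the travel cost (rural only: Euclidean distance times
`travel_cost_per_mile`), `\hat q_v` her *believed* quality of the venue,
`\sigma` her quality-sensitivity weight, `w = c_{weekly}/40` her implied
hourly wage, and `h_v` the venue's wait in hours (urban only). The
no-purchase option yields `\alpha \ln(1 + c)`. The protective term is
the expected disutility of unintended pregnancy averted per unit:
acceptance `A`, disutility weight `\beta` per expected unintended
pregnancy, baseline monthly risk `p_0` when unprotected, and a service
effectiveness

$$e(q) = \mathrm{clip}\big(e_{base}(0.5 + 0.1\,q),\ 0,\ 1\big),$$

so even the worst venue has half the best venue's effectiveness and
effectiveness rises linearly in quality. Expected pregnancies enter the
utility directly rather than being randomly realized: the outcome of
interest is protection coverage, and realizing the events would only add
noise.

A purchase adds `n` months to the woman's stock, reveals the visited
venue's true current quality, and consumes her cash; whatever is unspent
is forfeited at the end of the week. At the end of each month every
positive stock is decremented by one month and each woman's protected
flag (stock > 0) is recorded.

### Information

Women know both prices but not qualities. An unvisited, unadvertised
venue is valued at the prior `prior_quality`; a visit or an advertising
impression replaces the belief with the venue's true *current* quality,
after which the belief goes stale until refreshed — consumers do not
automatically observe quality changes at venues they stopped visiting.
This staleness is the information friction that the advertising
instrument relieves.

### Supply and the budget

Quality bought with public funds is a *flow-sustained* level, not a
stock: each month the active allocation's spending is converted anew from
the venue's base values, so redirecting the budget lets the previously
funded venue fall back to its base. Conversions are linear:
`kappa_quality` money per quality point (default 40, so the 80% benchmark
share raises quality by 2 points), `kappa_adv` money for full monthly
advertising reach (default `B`), and `kappa_price` money per unit of
price reduction. `kappa_price` is not free: it is pinned by the design
requirement that a 40% budget share drives the private price exactly to
zero (`calibrate_price_support()`), which also makes a 20% share halve
the price.

### Geometries

*Urban*: both venues sit at the grid center; travel is free and drops
out, and wait time is the non-monetary access cost, priced at each
woman's wage times `omega`. *Rural*: the venues occupy opposite corners;
each transaction pays `travel_cost_per_mile` times the Euclidean
distance, and wait time is negligible. Movement is abstracted: rather
than walking agents around the grid, travel is charged at transaction
time and a visit reveals quality, which is all the kinematics contribute
to the economics.

## Parameters and defaults

| Parameter | Default | Units / meaning |
|---|---|---|
| `earnings_low`, `earnings_high` | 520, 2080 | annual earnings class means (weekly cash 10, 40) |
| `income_spread` | 0.5 | half-width of the within-class uniform earnings band |
| `sigma_low`, `sigma_high` | 0, 1 | quality-sensitivity weights |
| `public_quality`, `private_quality` | 1.0, 2.5 | *base* (unfunded) qualities, 0–5 |
| `private_price` | 5 | money per unit (month of protection) |
| `public_wait`, `private_wait` | 4, 1 | hours per visit (urban) |
| `alpha` | 1 | weight on log residual consumption |
| `beta_uip` | 5.5 | disutility per expected unintended pregnancy |
| `acceptance` (A) | 1 | FP acceptance multiplier |
| `p0` | 0.08 | monthly pregnancy risk when unprotected |
| `e_base` | 0.95 | maximum service effectiveness |
| `omega` | 2.0 | wage multiple valuing an hour of waiting |
| `n_max` | 3 | units per transaction |
| `prior_quality` | 2.5 | believed quality of an unknown venue |
| `budget` (B) | 100 | policy money per month |
| `kappa_quality`, `kappa_adv` | 40, 100 | conversion constants |
| `travel_cost_per_mile` | 0.5 | money per mile (rural) |
| grid | 33 × 33 | continuous coordinates, origin lower-left |

Three default choices deserve explanation, because they were genuinely
open and the package's behavior depends on them.

**Unique incomes (`income_spread = 0.5`).** Each woman draws her own
earnings uniformly within her class band. With point-mass incomes every
urban woman in a subgroup is an exact clone — subgroup prevalence
collapses to 0 or 1 and regression standard errors vanish. A within-class
spread restores the heterogeneity that makes demand curves smooth and
Monte-Carlo variation meaningful.

**A low public base quality (1.0) with the prior at the private base
(2.5).** The unfunded public clinic is poor; the pre-switch budget
sustains it at `1.0 + 100/40 = 3.5`, above the private venue's 2.5 —
"slightly higher quality due to government funding". When the budget
moves to the private sector the public venue falls back to 1.0, *below*
what an uninformed consumer expects of a venue (2.5). This ordering is
substantive: women who entered the public market on the strength of its
funded quality discover the decline at their next visit and the marginal
ones rationally exit. If the public base sat above the prior, no consumer
could ever be disappointed by the public venue and the rural low-income
decline under reallocation — one of the model's headline findings — would
be structurally impossible.

**Random resolution of exact vendor ties.** The exported
`choose_plan()` breaks ties deterministically (lower spend, public before
private, smaller quantity), which is what the brute-force decision oracle
verifies. The *engine* resolves the one remaining knife-edge — two
venues identical in price, believed quality, and access cost — with a
seeded fair coin. With a deterministic public-first rule, two literally
indistinguishable venues would split the market 100/0, an artifact of
candidate ordering rather than economics; consumers indifferent between
identical venues should split between them, and the coin preserves both
reproducibility (it draws from the iteration's seeded RNG stream) and the
symmetric limit.

**Calibration.** The paper-level qualitative findings constrain but do
not identify the behavioral constants, so `beta_uip`, `omega`, and
`travel_cost_per_mile` were calibrated once, by grid search at small
Monte-Carlo size, to the four directional policy findings the acceptance
suite checks (urban benchmark positive; urban price support beating the
benchmark with the low-income gain exceeding the overall gain; rural
benchmark negative for low-income women; rural full price support
positive everywhere), and then frozen. They are not re-tuned at run time,
and all remaining constants keep their a-priori values.

## Experiments and analysis

An `experiment_spec()` fixes the geometry, the pre- and post-switch
allocations (`named_policy()` provides `public_baseline`,
`urban_benchmark` 20/80/0, `urban_price_support` 20/60/20,
`rural_benchmark` 20/60/20, and `rural_full_price_support` 20/40/40), an
optional sensitivity modifier, the scale, and the master seed. Iteration
`i` seeds R's RNG with `seed + i` and draws a fresh population, so
iterations are independent and reproducible, and two experiments sharing
a seed are bit-identical through the burn-in — policy effects are
differences in outcomes, not in random draws.

Sensitivity modifiers scale exactly one structural parameter by ±25% for
the whole horizon: wait times (urban only), travel cost (rural only),
acceptance (`fp_resistant`, ×0.75 only), `e_base`, `alpha`, or
`beta_uip`. `run_suite()` runs the benchmark, the alternative, and every
valid modifier from one seed and assembles the comparison table.

Analysis follows the pre/post design: iteration-month mCPR is sampled
from the equilibrium windows, months 51–60 (`policy = 0`) and 111–120
(`policy = 1`), within a segment (overall, an income class, or one of the
four income × sensitivity subgroups), and

$$\mathrm{mCPR}_i = \beta_0 + \beta_1\, \mathrm{Policy}_i + \varepsilon_i$$

is fit by OLS with classical standard errors; `beta1` is identically the
post-minus-pre difference in mean mCPR. The unit of analysis is the
iteration-month, matching the regression's index. Alternatives are
compared to the benchmark coefficient-by-coefficient with
`z = (\beta_1^a - \beta_1^b)/\sqrt{se_a^2 + se_b^2}` and a two-sided
normal p-value; a cell is marked **bold** only for a significant
*improvement* (`p < 0.01` and `\beta_1^a > \beta_1^b`). Stars follow the
usual `***`/`**`/`*` codes at 1/5/10%.

## Numerical choices

* A month is exactly four weeks (480 weeks over the 120-month horizon).
* Utility ties are detected with an absolute tolerance of 1e-9; spend
  ties likewise. Feasibility allows a 1e-12 slack so a plan that exactly
  exhausts the week's cash is affordable.
* Stratification is exact: population cells differ by at most one, with
  the remainder assigned in the fixed order LI-LQ, HI-HQ, LI-HQ, HI-LQ so
  both margins split 50/50 for every even population size.
* Advertising draws one uniform per currently uninformed woman per
  month; because the pre-switch regime buys no advertising, RNG streams
  are identical across policies until the switch.
* Degenerate inputs: an empty record set has no mCPR (error); a
  single-level policy dummy cannot be fit (error); a zero-residual fit
  (a saturated segment) yields a zero standard error and is handled
  explicitly in the benchmark comparison (equal effects: z = 0, p = 1;
  unequal: an infinite-precision difference).

## What the generator emulates — and what it does not

The synthetic population reproduces the study conditions: a 2 × 2
stratification of income and quality sensitivity, unique incomes,
uniform random locations, everyone starting unprotected and uninformed.
It does **not** emulate age or parity structure, method switching,
couples' decisions, savings or income growth, multidimensional quality,
vendor capacity, or stochastic pregnancy realization. Passing tests
therefore demonstrate that the *mechanisms* — price, quality, information,
and access-cost tradeoffs under a budget reallocation — behave coherently
and reproducibly, not that the model forecasts any real market's
prevalence levels. Simulated equilibrium mCPR levels are artifacts of the
calibration and should be read only through within-run contrasts
(pre/post differences and policy comparisons).

## Problem sizes

The full study scale is 100 iterations × 100 women × 120 months per
experiment (10,000 simulated users), which runs in well under a minute
per experiment on a single core. The packaged acceptance analyses and the
directional checks in the test suite use 30 iterations × 100 women —
3,000 users per experiment — which keeps the whole suite fast while
leaving the four directional findings highly significant; the structural
count check runs once at the full 100 × 100 scale.

## Limitations

Beyond the generator's scope above: quality is one-dimensional; only
short-acting methods are represented (each unit is one month of
protection, repurchased frequently); consumers are myopic
utility-maximizers with no forward-looking stocking strategy beyond the
per-transaction cap; and the two-venue market has no entry, exit, or
capacity constraints. The calibration delivers the directional findings
under the default conditions; magnitudes are not calibrated to any
empirical dataset.
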