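# fpmarket

Agent-based simulation of a segmented family-planning (FP) market, for
health-policy modelers studying how a fixed public budget is best spent
when one free public venue and one priced private venue compete for
heterogeneous consumers.

## The problem

In many low- and middle-income settings, public FP services are free but
slow or distant, while private services are quicker and closer but cost
money and have uncertain quality. A policymaker with a fixed monthly
budget `B` can sustain public-sector quality, or reallocate toward the
private sector through three instruments: truthful **advertising** of
quality, **true quality** improvement, and **price support**. Which split
raises modern contraceptive prevalence (mCPR) most — and for whom —
depends on the market's geography and on who is marginal.

`fpmarket` simulates this market. Women differ in income (low/high, with
unique earnings within class), quality sensitivity `σ ∈ {0, 1}`, and
grid location. Each week a woman with no remaining protection chooses
the venue `v` and quantity `n` maximizing

```
U(v, n) = α·ln(1 + c − n·p_v − t_v)
        + n·A·β·p0·e(q̂_v)·(1 + σ·q̂_v/5)
        − ω·w·h_v,          e(q) = clip(e_base·(0.5 + 0.1·q), 0, 1)
```

with `c` her weekly cash, `t_v` travel cost (rural geometry), `h_v` wait
hours priced at her wage `w` (urban geometry), and `q̂_v` her *believed*
quality — venues must be visited or advertised to be known. Experiments
run a 60-month burn-in with the budget on public quality, switch the
allocation at month 61, and compare mCPR between months 51–60 and
111–120 with the pre/post regression

```
mCPR_i = β0 + β1·Policy_i + ε_i
```

per iteration-month `i`; `β1` is the policy effect in prevalence points,
and alternatives are compared to the benchmark with a two-coefficient
z-test (bold cells: significant improvement at p < 0.01).

## Worked example

Run the urban benchmark (20% advertising / 80% private quality) and its
price-support alternative (20/60/20) from the same seed, then compare:

```r
library(fpmarket)

bench <- run_experiment(experiment_spec("urban", "urban_benchmark",
                                        n_iterations = 30, seed = 1))
alt   <- run_experiment(experiment_spec("urban", "urban_price_support",
                                        n_iterations = 30, seed = 1))
alt
#> Simulation panel: 360000 records (30 iterations x 120 months x 100 women)
#>   urban market, modifier 'none', switch at month 61, seed 1
#>   overall mCPR: 0.166

fits_b <- analyze_experiment(bench, c("overall", "low_income"))
fits_a <- analyze_experiment(alt,   c("overall", "low_income"))
fits_a$overall
#> Pre/post mCPR regression (overall segment, n = 600):
#>   beta0 (pre-policy mCPR):      0.0463
#>   beta1 (policy effect):        0.2583 (25.8 pp) se = 0.0023, p = <2e-16

compare_to_benchmark(fits_a$overall, fits_b$overall)
#> Benchmark comparison: delta beta1 = 0.2200 (22.0 pp), z = 74.47, p = <2e-16 [significant improvement]

results_table(list(benchmark = fits_b, price_support = fits_a))
#> Policy effects on mCPR (percentage points; benchmark: benchmark)
#>
#>               overall             low_income
#> benchmark     3.83*** (0.19)      -9.27*** (0.27)
#> price_support **25.83*** (0.23)** **32.27*** (0.37)**
```

Reading the output: under the benchmark reallocation, urban mCPR rises
3.8 points overall; adding price support lifts the gain to 25.8 points,
a significant improvement over the benchmark, and low-income women gain
more (32.3 points) than the population overall — prices, not quality,
are what exclude them. `plot(alt)` draws the monthly mCPR trajectories
with the switch month marked, and `summary(alt)` tabulates pre/post
prevalence by segment.

The full sensitivity suite for one geometry (benchmark, alternative, and
every ±25% one-parameter perturbation, from one seed) is

```r
suite <- run_suite("rural", seed = 1)   # or the command line below
suite$table
```

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/fpmarket.R run      --config myrun.yaml --out-dir out/
Rscript inst/cli/fpmarket.R suite    --setting urban --seed 7 --out-dir out/
Rscript inst/cli/fpmarket.R analyze  --panel out/panel.csv
Rscript inst/cli/fpmarket.R fixtures --out-dir out/
```

Configs are YAML; every omitted key takes the documented default
(`default_config()`), validation names offending keys, and each run
writes a `manifest.yaml` sufficient to reproduce it exactly.

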