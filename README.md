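# tevtrade

Spatially explicit trade-off analysis between the economic benefits of
converting tropical forest to agriculture and the externalities of that
conversion — lost ecosystem services (ES) and carbon emissions — for
researchers in ecosystem-service valuation, land-use economics, and
REDD+ opportunity-cost analysis.

## What it computes

The package integrates four estimates on a common grid of cells:

1. **ES value surface.** A meta-analytic benefit-transfer model of ES
   valuation observations,

   log(value_i) = α + Σ_j β_j X_ji + a_c + ε_i,
   a_c ~ N(0, σ₁²), ε_i ~ N(0, σ²),

   a country random-intercept mixed model fitted by maximum likelihood,
   exhaustively enumerated over fixed-effect subsets (2^8 = 256 models
   by default), selected by ΔAICc ≤ 2, and combined by Akaike weights.
   Per-cell total ES value (TEV) sums class predictions weighted by the
   number of service types per class (cultural 5, provisioning 5,
   regulating 6 — one regulating service excluded to avoid double
   counting carbon). Accuracy is benchmarked by leave-one-out
   cross-validation (MAPE, through-origin predicted-vs-observed slope)
   against direct benefit transfer.

2. **Carbon value.** Per-hectare emissions
   (AGB + BGB + DOM + peat depth × peat density) × 44/12 tCO2e, valued
   under a market or social carbon-price regime and annualized with the
   annuity factor r/(1−(1+r)^−T) (defaults 5%, 100 years).

3. **Agricultural rents.** AR_i = y_ui p_u − c_ui under four
   crop-replacement scenarios: national crop composition with (A) and
   without (B) production costs, and per-cell maximum-potential-rent
   crops with (C) and without (D) costs, including von Thünen transport
   costs, labour, fertilizer, cattle rents and an annualized timber
   windfall.

4. **Net impact.** I = Σ_i (TEV_i − AR_i) A_i, integrated per cell and
   aggregated to country and global totals, with joint Monte Carlo
   propagation of every uncertainty source (ES model bootstrap,
   loss-map classification error, carbon- and crop-price draws, crop
   assignment) reduced to 2.5th/50th/97.5th percentile maps and tables.

A seeded synthetic-data generator supplies landscapes, valuation
records and economic tables with known ground truth, so the whole
pipeline is testable without any external data.

## Worked example

```r
library(tevtrade)

cfg     <- synth_config(grid_nx = 20, grid_ny = 20, n_countries = 3, rng_seed = 42)
grid    <- generate_landscape(cfg)
records <- generate_valuation_dataset(cfg, grid)
econ    <- generate_econ_tables(cfg)

# ES meta-analysis: enumerate 256 models, keep the high-support set
top <- select_top(enumerate_models(records, es_candidate_terms()))
length(top$models)
#> [1] 5
top$terms_list[[which.min(top$delta_aicc)]]
#> [1] "es_class" "method_class" "temperature" "richness_birds"

# predictive accuracy vs the direct benefit-transfer baseline
cv  <- loo_cv(records, es_candidate_terms(), procedure = "top")
dbt <- direct_benefit_transfer(records, "global")
c(slope = cv$slope, mape = cv$mape, dbt_mape = dbt$mape)
#>     slope      mape  dbt_mape
#> 0.9940614 0.2492000 0.3347354

# bootstrap the TEV surface and propagate all uncertainty sources
es  <- bootstrap_es_maps(records, grid, B = 50, top_set = top, seed = 1)
ens <- run_monte_carlo(grid, es, econ, "A",
                       uncertainty_spec(n_reps = 50, seed = 1))
glob <- ens$aggregates[ens$aggregates$level == "global", ]
quantile(glob$impact_total, c(0.025, 0.5, 0.975))
#>      2.5%       50%     97.5%
#> 278186616 359423166 591154828
```

The slope near 1 says the held-out log-value predictions are close to
unbiased; the meta-analytic MAPE of 0.25 beats the 0.33 of direct
benefit transfer. The final line is the global net impact of
deforestation under scenario A in currency/yr with its 95% uncertainty
range: positive, so on this synthetic landscape the externalities of
conversion exceed the agricultural rents gained.

One call runs everything (screening, selection, bootstrap, rents,
impact, Monte Carlo, percentile reduction) and writes all artifacts
plus a checksummed manifest:

```r
pc <- pipeline_config(outdir = "out", scenario = c("A", "B", "C", "D"),
                      synth = cfg, B = 50, 
                      uncertainty = uncertainty_spec(n_reps = 50), seed = 7)
run_pipeline(pc)
```

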