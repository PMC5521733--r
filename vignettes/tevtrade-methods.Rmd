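---
title: "Methods: valuing forest loss against agricultural rents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valuing forest loss against agricultural rents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tevtrade)
```

# The problem

Converting tropical forest to agriculture creates private benefits
(crop and cattle rents, a one-off timber windfall) and destroys public
value (carbon storage and a bundle of other ecosystem services, ES).
`tevtrade` estimates both sides on a common grid and integrates them
into a per-cell and aggregate net impact,

$$ I = \sum_i \left[(\mathrm{TEV}_i - \mathrm{AR}_i)\, A_i\right], $$

where $\mathrm{TEV}_i$ is the externality value per hectare and year of
the services lost in cell $i$ (including the annualized value of the
carbon emitted, and net of the cost of operationalizing an ES payment
program), $\mathrm{AR}_i$ the annual agricultural rent gained per
hectare, and $A_i$ the deforested area of the cell. Positive $I$ means
conversion destroys more value than it creates. The framing treats
marginal deforestation against marginal land-use benefits and assumes
the remaining forest stays far from any scarcity threshold at which ES
values would spike; that is an assumption of the method, not a testable
property.

Because global valuation and land-use rasters are large, proprietary,
or both, the package ships a seeded synthetic-data generator that
emulates all three inputs — a gridded landscape, a table of ES
valuation observations, and economic parameter tables — from a known
generative model, so every stage can be tested against ground truth.

# The ES meta-analytic model

ES valuation observations are scarce and heterogeneous; transferring
them to unstudied sites requires controlling for the valuation method,
the service type, and the environmental and socioeconomic context. The
package models the log value of an observation $i$ in country $c$ as

$$ \log(\mathrm{value}_i) = \alpha + \sum_j \beta_j X_{ji} + a_c +
\varepsilon_i, \qquad a_c \sim N(0, \sigma_1^2), \quad
\varepsilon_i \sim N(0, \sigma^2), $$

a linear mixed model with a country random intercept capturing
country-level sources of non-independence (institutions, corruption,
price levels). The service type enters as a three-level factor
(cultural, provisioning, regulating; supporting services are excluded
to avoid double counting) and the valuation method as a second
three-level factor (cost-based, stated preference, revealed
preference); both are the clustered forms that keep the design
full-rank at small sample sizes. The continuous candidate predictors
are publication year, temperature, precipitation, accessibility, and
bird species richness and carbon density as surrogates for ecosystem
function and forest type.

Model uncertainty is handled information-theoretically rather than by a
single fit:

* every subset of the candidate terms is fitted (`enumerate_models()`;
  8 candidates give $2^8 = 256$ models, intercept-only included);
* models are ranked by AICc, the small-sample corrected AIC
  $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$;
* the high-support set is $\Delta\mathrm{AICc} \le 2$ (boundary
  inclusive);
* predictions of the retained models are combined by renormalized
  Akaike weights $w_m \propto \exp(-\Delta_m/2)$.

All likelihoods are maximum likelihood, not REML, because AICc
comparisons span different fixed-effect sets; REML likelihoods are not
comparable across them. Averaging happens at the prediction level with
weights applied to each model's conditional prediction; for linear
predictors this is equivalent to conditional (not full) coefficient
averaging, i.e. coefficients are averaged only over models that contain
them.

Spatial prediction fills the two predictors with no spatial layer
(publication year, valued forest area) with their training means, uses
the estimated country intercept where the country was observed, and
falls back to the fixed effects alone for countries absent from the
training set. Per cell, one prediction is made for each ES class at
each of the three method levels; the three method-level predictions are
averaged on the log scale and exponentiated (a geometric mean across
methods), and the class values are combined as

$$ \mathrm{TEV} = 5\,V_{\mathrm{cultural}} + 5\,V_{\mathrm{provisioning}}
 + 6\,V_{\mathrm{regulating}}, $$

the counts of service types aggregated per class, with one regulating
service excluded because carbon is valued separately. Whether the
regulating multiplier should be 6 or 7 is genuinely ambiguous in the
source material; 6 (excluding the overlap) is the default and the
multiplier vector is configurable. Back-transformation is naive
exponentiation; no smearing correction is applied, which understates
the arithmetic-mean value when residual variance is large — a
documented, deliberate simplicity (the model's response is the log
value throughout, including in the accuracy metrics).

## Validation machinery

`loo_cv()` runs leave-one-out cross-validation of the entire
select-and-average procedure (or, faster, refits the structures
selected once on the full data; `procedure = "top"`), reporting the
mean absolute percentage error on the log scale and the slope of a
through-origin regression of observed on predicted values
($\hat\beta = \sum p_i o_i / \sum p_i^2$; 1 means unbiased). The MAPE
scale is a choice — the source material does not state one — and the
log scale is used because it is the model's response scale; percentage
errors on the raw scale are dominated by the heaviest tail.
`direct_benefit_transfer()` is the baseline every meta-analytic
transfer must beat: leave-one-out stratum means per ES class (global)
or class × region (regional), with singleton strata falling back to the
global mean. `diagnostics()` provides VIF on the fixed-effects linear
analogue, a Breusch–Pagan test with country as a fixed effect, and a
binned residual semivariogram whose slope against distance should be
indistinguishable from zero when residuals are spatially independent.

Prediction uncertainty uses a nonparametric bootstrap
(`bootstrap_es_maps()`): records are resampled with replacement at the
record (row) level, the selected top-model structures are refitted on
each resample, their weights recomputed from the refitted AICc values,
and the TEV surface re-predicted, giving $B$ maps. Resampling rows
rather than studies is the default because the study identifier is not
part of the minimal record schema; a full re-enumeration per resample
is available (`re_enumerate = TRUE`) but refitting fixed structures is
the default, matching the practice of bootstrapping the already
selected models. A subtlety worth knowing: even noise-free data do not
collapse the ensemble when the model contains publication year or
forest area, because each resample carries its own training mean used
to fill those predictors at prediction time. That is a real component
of bootstrap spread, not a bug.

# Carbon accounting and valuation

Emissions from converting one hectare are
$(\mathrm{AGB} + \mathrm{BGB} + \mathrm{DOM} + d_{\mathrm{peat}}
\rho_{\mathrm{peat}}) \times 44/12$ tCO2e, where the pools are
above-ground, below-ground and dead-organic-matter carbon (tC/ha), and
peat contributes its depth (m) times a carbon density
$\rho_{\mathrm{peat}}$, default 500 tC/ha per metre — a stated free
parameter, since no pantropical peat-depth product exists and depth
distributions are borrowed from Indonesian peatlands in the source
analysis. Mineral soil carbon is conservatively assumed unchanged. The
dead-organic-matter pool is a constant per-hectare layer (IPCC-table
style), configurable. The peat correction is applied once as a stock
release and then annualized; whether it should instead be an ongoing
annual oxidation flux is an open interpretive question, and the one-off
reading is the implemented one.

Two price regimes are supported: a market price (reference level
13.6 currency/t, the multi-year average of an allowance market) drawn
from a daily price series, and a social cost of carbon (reference mean
30 currency/t) drawn from a pool of integrated-assessment draws, five
scenario strata of 1,000 draws each. Quoted carbon prices are
convention-dependent — per tonne of carbon or per tonne of CO2e
(12/44 apart) — and the source usage is internally contradictory, so
the basis is an explicit configuration switch (`carbon_price_model()`,
default `per_tCO2`) rather than a silent assumption. One-off stock
values are annualized with the annuity factor $r/(1-(1+r)^{-T})$ at the
default 5% over 100 years, with the $r \to 0$ limit $pv/T$ handled by
continuity.

# Agricultural rents

Per-cell rents follow $AR_i = y_{ui} p_u - c_{ui}$: yield times
farm-gate price minus production costs, negative rents preserved. Four
scenarios bracket the land-use response:

| scenario | crop choice | yields | costs |
|---|---|---|---|
| A | drawn from the national crop composition | current | labour + fertilizer |
| B | as A (same seeded draw) | current | none (gross) |
| C | per-cell maximum-rent crop | potential | labour + fertilizer + transport |
| D | per-cell argmax of gross rent | potential | none (gross) |

A and B represent the contemporary pattern — replacement by crops
already grown in the country, sampled per deforested cell from the
national area-weighted crop composition (the 18 major tropical crops
plus cattle; a uniform-over-crops option exists). C and D are the
hypothetical intensification bound: every cell adopts the crop with the
highest potential rent, ties broken deterministically by crop-set
order, cattle included in the candidate set. Transport costs apply only
to the C/D cash-crop scenarios, per the cost lists that define the
scenarios; the von Thünen transport model is one truck (18 m³,
45 km/h, 0.3 L/km, returning empty, one driver paid the national wage),
with a default load density of 1 t/m³ converting the volumetric
capacity to mass — the conversion is unstated in the source and
explicit here. Labour uses crop-specific person-days per hectare and
the national agricultural wage, falling back to the manufacturing wage;
fertilizer is usage times national price; a missing crop–country price
falls back to a configured donor country, then to zero with a warning.
All scenarios add the annualized one-off timber windfall
(stock × commercial fraction × export price), switchable off.

Two dominance facts are useful for testing and interpretation: B ≥ A
cell-wise under a shared seed (same crops, costs only subtracted), and
D ≥ C cell-wise (the gross argmax dominates any net rent).

# Uncertainty propagation

`run_monte_carlo()` samples jointly, per replicate, from every active
source: one of the $B$ bootstrap TEV maps chosen uniformly; the
forest-loss map perturbed to emulate classification error (each loss
cell kept with probability 0.87, each no-loss cell kept with 0.997,
flipped no-loss cells receiving the national mean loss area — the area
assigned to a flipped cell is unspecified in the source and the
national mean is the package's choice); the market carbon price drawn
from the daily series and the social price from the SCC pool; each
crop–country price drawn from $N(\mu, \sigma)$ clamped at zero
(clamping, not rejection — the mass at zero is negligible at realistic
coefficients of variation); and, for scenarios A/B, the crop assignment
redrawn (the crop distribution is itself listed among the uncertainty
sources, so redraw-per-replicate is the default). Scenario C/D
assignments are deterministic at mean prices and held fixed.

One master seed derives an independent sub-stream per source and
replicate (`derive_seed()`), so switching one source off leaves every
other draw unchanged — the property that makes variance-ablation tests
meaningful. The ensemble is reduced to empirical 2.5th, 50th and 97.5th
percentiles per cell and per aggregate, using the linear-interpolation
quantile definition (R type 7). Cross-country contrasts on the cube-root
scale use a sign-preserving root, $\mathrm{sign}(x)|x|^{1/3}$, and are
transformed per replicate before percentiles are taken.

Reference replicate counts are $B = 500$ bootstrap maps and $M = 200$
Monte Carlo replicates; the test suite and the shipped examples use
$B = M = 50$, which the package treats as its reduced test default.

# The synthetic generator

`synth_config()` fixes the study conditions: grid size and cell area
(default 10,000 ha, the order of a 0.1° tropical cell), countries as
contiguous column strips (contiguity is all the method uses; real
country shapes are out of scope), forest loss as a Bernoulli draw per
cell with a uniform loss fraction, carbon pools and peat
(exponentially distributed depth, truncated at a maximum), independent
uniform covariates with an optional near-duplicate covariate to
exercise the collinearity diagnostics, per-crop current yields with
potential yields a 1.2–2.5× multiple, and a Dirichlet national crop
composition with the cattle share tied to the mean pasture fraction.
The valuation generator uses the mixed model above with the
three-level class and method factors exactly as fitted, defaults
$\sigma_1 = 0.5$, $\sigma = 1$ on the log scale (valuation datasets
span orders of magnitude), and a default size of 78 records matching
the reference dataset; the realized country intercepts and noise-free
linear predictor are returned as test oracles. The default generative
coefficients follow the empirically observed signs (value rising with
temperature, falling with publication year and bird richness), with
the intercept offset so a typical service is worth about
$e^4 \approx 55$ currency units/ha/yr.

What the generator does *not* emulate: spatial autocorrelation of loss
patches and covariates, real country geometries, study-level clustering
of valuation records, currency conversion, and market feedbacks.
Passing tests therefore demonstrate the correctness and calibration of
the machinery under the stated generative model, not the accuracy of
any real-world valuation.

# Numerical and testing choices

* Singular mixed-model fits (country variance at the boundary) are
  accepted and flagged, with `sigma_country = 0`; one-country data
  degenerate to a fixed-effects regression, flagged. Rank-deficient
  designs are errors naming the collinear columns, and bootstrap
  resamples that lose a factor level are redrawn and counted.
* AICc requires $n > k + 1$ and errors otherwise.
* Determinism: every generator and every Monte Carlo stage is
  reproducible bit-for-bit from its seed; the pipeline manifest records
  MD5 checksums, and re-running an identical configuration reproduces
  them.
* Statistical tests in the suite use pre-chosen bands: 3-sigma binomial
  bands for count checks, a 0.0005–0.9995 chi-square band for the
  country-variance decomposition, four standard errors for the
  closed-form variance-propagation check at $M = 2000$, and the
  interval-coverage check (50 meta-replicates on a 12×12 grid with
  $B = M = 50$) accepts at the 80% threshold.
* Problem sizes in the suite (coverage at 12×12 × 4 countries, smoke
  pipeline at 50×50 × 5 countries, all four scenarios) are the
  package's chosen test scales for single-CPU runs.

# Known limitations

Capital costs, market feedbacks on prices, land degradation and
abandonment, biodiversity trade-offs, time-varying carbon prices, and
per-service individual models are out of scope, as is any spatial
random-slope autocorrelation structure (attempted and rejected in the
source analysis). The internalization cost is deducted only in
ES-based comparisons, not in carbon-only mode. The grid dialect is a
plain long-format CSV with a JSON sidecar; GeoTIFF export is not
required by any stage and is not implemented.
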