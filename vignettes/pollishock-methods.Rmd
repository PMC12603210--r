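---
title: "Modelling a wild-pollinator collapse: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a wild-pollinator collapse: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollishock)
library(dplyr)
```

pollishock studies a counterfactual: what happens to agricultural markets,
welfare and food security if the wild pollinators of one world region
(Europe) collapse while the rest of the world is untouched? The package
implements the full chain from biological dependence data to economic
indicators: a shock engine, a stylized multi-region partial-equilibrium
market model with Armington trade, welfare and nutrition accounting, and
the scenario/sensitivity designs that wrap them. A seeded synthetic-data
generator stands in for the large proprietary market databases such
analyses are usually calibrated to, so the whole pipeline runs and is
tested offline.

## From dependence ratios to productivity shocks

A crop's *dependence ratio* $D_i \in [0,1]$ is the fraction of its yield
attributable to animal-mediated pollination; the *wild contribution*
$\varphi_c \in [0,1]$ is the share of that service delivered by wild (as
opposed to managed) pollinators for commodity $c$. Commodities aggregate
several crops, weighted by region-specific production value shares
$\mathrm{shr}_{c,i,n}$. A collapse of wild pollinators then cuts commodity
yields by

$$ s_{c,n} \;=\; \min\Big(0.999,\; \sum_i \mathrm{shr}_{c,i,n}\,
   \varphi_c\, D_i\Big), $$

and the yield multiplier applied to the market model is $1-s_{c,n}$. The
cap keeps output strictly positive for fully dependent crops
(quinces-and-pumpkins-style $D=1$ records). We store shocks as fractions
and format percentages only at the reporting edge, rounding half-up to one
decimal so a shock of 7.95% prints as 8.0 — the convention the published
commodity table uses. Note the sign convention: some sources write the
displayed equation for the *multiplier* $1-\sum \mathrm{shr}\,\varphi\,D$;
this package names both fields (`s_*` and `multiplier_*`) explicitly so
the semantics are never ambiguous.

Confidence bounds come from treating each crop's dependence ratio as
triangular with support $[D_{\min}, D_{\max}]$ and mode $D_{\text{mean}}$
— the simplest distribution consistent with the three reported statistics
— and replacing $D_i$ by the closed-form quantiles at $(1 \pm 0.95)/2$.
Aggregation across crops is *comonotone* (every crop sits at the same
quantile), which yields a single low/mean/high scenario triple rather than
a convolution; that matches how such studies report one bounded scenario
set. Two edge cases are handled explicitly:

* crops without usable min/max information fall back to a proportional
  $\pm 50\%$ band around their mean contribution (the convention used for
  buckwheat, the single dependent crop of the Other Cereals account);
* the interval is clipped to contain the point estimate, because a mode
  sitting at the edge of its support (e.g. $D_{\text{mean}} = 1$) would
  otherwise put the 97.5% quantile *below* the mean.

A related subtlety: at `coverage = 0` both quantiles collapse onto the
triangular *median*, which equals the mean shock only for symmetric
triangles. The quantile semantics are kept faithfully rather than forcing
the degenerate interval onto the mean.

Shocks are confined to Europe: `build_shock_table()` requires every region
to be classified and assigns $s = 0$ to all non-European regions
(Turkey-style cases are handled simply by classifying the region as
non-European). A collapse defined as a 90% population decline over the
2017–2030 horizon (14 annual periods) corresponds to
$1 - 0.1^{1/14} = 15.2\%$ per year, available as `annual_decline_rate()`.

## The stylized market model

Large partial-equilibrium systems in this field (multi-region agricultural
sector models with a market module and a regional supply module solved
sequentially) publish their mechanisms but not closed functional forms.
This package deliberately implements the *simplest* forms that deliver
every reported mechanism — price overshoot under inelastic demand, trade
buffering, cropland expansion, endogenous intensification — and declares
all elasticities as data, not code:

* **Supply.** $Q_{r,c} = Q^0_{r,c}\,(1-s_{r,c})\,
  \tilde p_{r,c}^{\,\varepsilon_s}\, \bar P_r^{\,\lambda_r}$, where
  $\tilde p$ is the producer price relative to base, $\bar P_r$ is the
  region's area-weighted (geometric) crop price index, $\varepsilon_s > 0$
  the supply elasticity and $\lambda_r \ge 0$ the aggregate cropland
  response. Realized yield is $y^0 (1-s)\, \tilde p^{\,\eta}$ with
  $\eta \ge 0$ the price-responsive intensification term (the collapsed
  stand-in for low/high-intensity technology variants); land is the
  quantity/yield quotient. The design was genuinely open here: a pure
  relative-allocation (share-preserving) area response would make
  own-price supply response vanish in a one-commodity market and break the
  closed-form benchmark $p^* = (1/m)^{1/(\varepsilon_s + |\varepsilon_d|)}$
  that anchors the solver tests, so the own-price constant-elasticity form
  with a separate land-index term was chosen.
* **Demand.** Constant own-price elasticity $\varepsilon_d < 0$ on the
  composite consumer price; no cross-price demand terms and no income
  feedback (partial equilibrium). Inelastic demand
  ($|\varepsilon_d| < 1$) is the empirically relevant default and what
  produces the King-Davenant revenue gain for producers after a negative
  supply shock.
* **Trade.** Two-level CES (Armington): domestic variety versus an import
  composite with elasticity $\sigma_1$, and origins within the composite
  with $\sigma_2$. Everything is calibrated in *share form*: base-year
  value shares are the CES share parameters, so the observed baseline is
  an exact equilibrium by construction and the zero-shock solve reproduces
  it identically. $\sigma = 1$ is handled by the log-form limit.
* **Price transmission.** Ad-valorem wedges $\tau \ge 0$ between origin
  and landed prices; wedge revenue accrues to the importing government.
  Because wedges are constant across scenarios they cancel from the ratio
  dynamics and matter only for levels (tariff revenue, baseline shares).

The solver alternates the supply block and the Armington demand/clearing
block with damped log-price updates,
$\ln p \mathrel{+}= \gamma \ln(\text{demand}/\text{supply})$, with a
per-market step $\gamma$ scaled by an upper bound on the local
excess-demand elasticity ($\varepsilon_s + \eta + \lambda +
\max(\sigma_1, \sigma_2, |\varepsilon_d|)$, damped by 0.5). Convergence is
declared when the worst relative market-clearing residual falls below
`tolerance` (default `1e-6`, cap 500 iterations); non-convergence is an
error carrying the residual trajectory, never a silent partial result.
The defaults are documented package choices — reference systems do not
publish theirs.

## Welfare and nutrition accounting

Consumer surplus uses the Marshallian integral under the calibrated
constant-elasticity demand curve,
$\Delta CS = -\int_{p_0}^{p_1} D(p)\,dp$, in closed form (log form at
$\varepsilon_d = -1$); with no income effects this coincides with the
compensating income change. Producer surplus is profit over variable cost
under the constant-elasticity supply curve, $pq/(1+\varepsilon_s)$ per
market, conditional on the land index. Government revenue is the
ad-valorem wedge take on import values. The decomposition adds up exactly
by construction, and blocs (EU ⊂ Europe ⊂ world) aggregate component-wise
over partitions; nested blocs are produced by separate calls rather than
one overlapping partition. One denominator choice deserves note: the
Marshallian consumer surplus *level* is unbounded for inelastic
constant-elasticity demand, so relative welfare changes are reported
against baseline consumption expenditure plus baseline producer surplus
plus baseline tariff revenue — a finite, interpretable proxy for the
sector's baseline welfare contribution. Processing and dairy margins have
no separate sector in the stylized model and are implicitly part of
producer surplus.

Two back-of-envelope valuation calculators complement the model:
willingness-to-pay extrapolation (per-household annual value times
household count; €113.5 across 193 million households gives €21.9 billion
per year) and the honeybee replacement-cost range (colonies times unit
cost, optionally per hectare of dependent cropland). Both are pure
arithmetic and bit-reproducible.

Nutrition indicators convert demanded quantities into per-capita daily
availability, $\sum_c q_c \kappa_c / (\text{population} \cdot 365)$, for
kilocalories, vitamin A and folate, reported as percent changes per bloc
for the vegetables-and-fruits group and for all food. Availability — not
waste-adjusted intake — is the deliberate concept. Nutrient units are
carried opaquely (per product ton) because source accounting conventions
(e.g. retinol equivalents) vary; only ratios are ever reported.

## Scenario designs

`run_ci_scenarios()` solves the low/mean/high shock levels independently
and reports per-indicator envelopes. `run_sensitivity_grid()` runs the
full factorial of four factors — wild contribution, dependence ratio,
supply elasticity, Armington trade elasticities (both nests scaled
jointly, since they act as one block) — at three multiplicative levels
each: $3^4 = 81$ deterministic runs whose all-central cell is exactly the
core scenario. The level set $\{0.5, 1, 1.5\}$ is a package default,
symmetric and overridable; the exact levels used by the source analyses
live in unpublished supplementary material, so ours are declared rather
than inferred. Dependence and contribution multipliers are clamped to
$[0,1]$ after scaling.

`vote_association()` is a purely descriptive population-weighted least
squares of parliamentary rejection shares on consumer welfare exposure; it
reports slope, intercept, weighted $R^2$ and the slope p-value per
proposal and for their average, and implies no causality.

## The synthetic generator

`generate_market_dataset()` emulates the statistical shape of the real
input databases, not their values: log-normal (right-skewed) production,
prices around a few hundred €/t, bilateral trade built origin-by-origin
(an exported fraction of production allocated by size-weighted gravity),
so world trade balances *by construction*; demand elasticities drawn in
$(-0.9, -0.2)$ (inelastic throughout, so King-Davenant holds
market-by-market); Armington $\sigma_1 \in (1.5, 3)$,
$\sigma_2 \in (2, 5)$; wedges up to 30%. European production of dependent
commodities is rescaled so Europe holds exactly 10% of their world value,
the order of magnitude relevant for trade-buffering behaviour. The default
size — six regions (three European, two of them EU) by six commodities
(three pollination-dependent), with one-to-three crops per dependent
commodity and one full-dependence crop to exercise the 99.9% cap — keeps
the complete pipeline (shocks → equilibrium → welfare → nutrition →
81-run grid) under a minute on one CPU; tests and the acceptance script
use exactly these sizes. All draws are `set.seed()`-deterministic.

What the generator does *not* emulate matters for interpreting green
tests: there is no sub-national resolution (the real analyses resolve
~273 European regions), no feed/processing demand layers, no quota or
subsidy instruments, no multi-year projection baseline, and no attempt to
match real country totals. Passing tests therefore demonstrate the
*mechanisms* (directions, identities, invariants, closed-form agreement),
not the published magnitudes — reproducing, say, a specific −7.8%
European yield change would require the proprietary-scale database the
stylized model deliberately does not depend on. The quantities that *are*
desk-reproducible — the commodity shock table, the 15.2% annual decline
rate, the valuation arithmetic — are reproduced exactly.

## Numerical conventions and limitations

* Quantities in kt, prices in €/t, so value cells are thousand EUR;
  percentages are serialised as percents only in report columns suffixed
  `_pct`, fractions everywhere else.
* Zero denominators yield `NA` indicators (flagged undefined), never 0.
* Equilibria are bit-identical for identical inputs; there is no
  randomness outside the generator.
* Managed pollinators are held fixed (zero substitution elasticity); crop
  quality and seed-production channels are excluded; welfare is averaged
  over national households, so within-country distribution is out of
  reach.
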