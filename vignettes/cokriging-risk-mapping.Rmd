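---
title: "Probability co-kriging for invasion risk mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability co-kriging for invasion risk mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiskrige)
```

## The problem

Zebra mussels and Eurasian watermilfoil spread between waterbodies through
surface-water connections and, above all, through trailered boats. Where
surveillance relies on public reporting, confirmed infestations are a
biased sample of the true ones: accessible, heavily visited lakes get
reported; remote ones do not. The mapping question is therefore not "where
has an invasion been reported" but "where would we expect one, given where
reports sit in space and how waterbodies are used".

`aiskrige` answers this with probability (indicator) co-kriging. The
primary variable is the 0/1 reported-presence indicator of one species;
secondary variables are waterbody-specific risk factors that are observed
everywhere (or nearly so) and correlate with presence. Because co-kriging
weights decay with distance through the fitted variogram, proximity to a
reported infestation is part of the predictor by construction; the
secondaries let a never-reported but high-traffic, road-adjacent waterbody
inherit risk from its profile rather than only from its neighbours — which
is precisely the correction for underreporting.

## The model

For variables $Z_1$ (primary indicator) and $Z_2, Z_3$ (secondaries), the
ordinary co-kriging predictor at location $s_0$ is

$$\hat Z_1(s_0) = \sum_i \lambda_i Z_1(s_i) + \sum_j \mu_j Z_2(s_j)
  + \sum_k \nu_k Z_3(s_k),$$

with $\sum_i \lambda_i = 1$, $\sum_j \mu_j = 0$, $\sum_k \nu_k = 0$, and
weights solving the linear system that minimises the error variance under
a joint spatial-dependence model. Predictions of the indicator are clamped
to $[0,1]$ and read as introduction probabilities.

The joint model is a linear model of coregionalization (LMC) with two
structures — a nugget and one `family` structure (spherical by default)
with a single shared range:

$$\gamma_{uv}(h) = B^{(0)}_{uv}\,\mathbf 1(h>0) + B^{(1)}_{uv}\, g(h/a).$$

Each direct and cross semivariogram is estimated by the Matheron estimator
on lag bins of width `lag_size` (12 lags by default), fitted by weighted
least squares (Cressie weights, pair counts over squared model values) at
a shared range taken from a free fit to the primary's direct variogram.
The coefficient matrices $B^{(0)}, B^{(1)}$ are then projected to the
nearest positive semidefinite matrix by eigenvalue clipping. PSD
coefficient matrices are what make the co-kriging system solvable for any
target; without the projection a WLS fit can easily produce an invalid
joint model when cross-variograms are noisy, which is the typical case for
sparse indicators.

### Treatment of unreported waterbodies

The estimator needs data at uninfested locations. Waterbodies without a
report enter as indicator 0 — a deliberate convention, since some of those
zeros are false negatives (that is what underreporting means). The
secondaries are what correct for this; a `zeros = "subsample"` switch in
`kriging_params()` keeps all 1s and a seeded fraction of 0s for users who
prefer to down-weight the uncertain zeros.

### Anisotropy

Geometric anisotropy is supported end to end (an `aniso_factor`/
`aniso_angle` pair stretches separations before both variogram binning and
covariance evaluation) but is off by default (`factor = 1`): the synthetic
landscapes are isotropic by construction, so a directional fit would only
add variance. Users mapping real data with a known directional trend can
switch it on in `kriging_params()`.

## The covariates

Six waterbody-specific variables, assembled per census year:

1. `v1_zm`, 2. `v2_ewm` — reported presence per species (the primary
   variable of the respective model, and an eligible secondary for the
   other species);
3. `v3_conn_zm`, 4. `v4_conn_ewm` — connectivity to a reported
   infestation through shared stream route ids ("kittle numbers"): a
   waterbody is flagged when any stream it lies on (invaded waterbodies
   get a 100 m buffer to the nearest stream) also carries an invaded
   waterbody, ignoring flow direction;
5. `v5_eig` — eigenvector centrality of the boater-traffic network built
   from watercraft-inspection surveys (each eligible record adds the
   edges previous–station and station–next); computed on the largest
   connected component, unit Euclidean norm, zero elsewhere. Unsurveyed
   waterbodies carry 0 — the centrality of an isolated node — rather than
   a missing value, so the variable is defined everywhere;
6. `v6_invroad` — inverse Euclidean distance to the nearest major road,
   floored at 10 m so a waterbody touching a road maps to 100 /km rather
   than infinity.

Centrality choice (eigenvector vs betweenness vs degree) is made by
Pearson correlation against the two species' statuses, ties broken in the
fixed order eigenvector > betweenness > degree. Secondary variables
screen in at Pearson $r \ge 0.1$ against the primary; all unordered pairs
of screened candidates are then compared by temporal-validation AUC and
the argmax pair is kept.

## Validation

*Temporal validation* fits on first-census statuses and scores every
waterbody not reported infested then; positives are waterbodies newly
reported by the second census, negatives those never reported. Negatives
necessarily include unreported true infestations — no computable
alternative exists under passive surveillance, and the convention is
stated wherever metrics are reported. Each scored waterbody is predicted
by leave-one-out co-kriging: its own primary indicator datum (always 0 in
the test set) is excluded from the neighborhood, while its secondary data
are kept. Without the exclusion, the co-located zero dominates every
solve and the test degenerates; this is the standard kriging
cross-validation convention.

*k-fold cross-validation* (k = 5, i.e. 80/20 splits) partitions infested
waterbodies into seeded folds — and uninfested ones likewise — withholds
each fold's infested set from the fitting data, and scores that fold's
waterbodies with the variogram parameters held at the full-data fit.
Pooled scores give the AUC (Mann–Whitney concordance, ties counted one
half) and sensitivity/specificity at the threshold risk rank 3. An AUC
above 0.7 is treated as the accuracy bar.

Ranked outputs use quintile classes of the extracted per-waterbody
probabilities (rank 5 = very high … 1 = negligible), with the
linear-interpolation percentile definition and boundary ties sent to the
lower class. Reported percentages follow the truncation-at-2-decimals
convention of the results this package mirrors. Quantiles are computed
over waterbody-extracted values, not grid cells, since waterbodies are
the decision units.

## The synthetic landscape

No public deposit of the state-wide waterbody, survey, and infestation
databases exists, so the package ships a generator whose defaults define
the study conditions for every test:

* 600 waterbodies on a 30 × 30 km plane from a Thomas cluster process
  (40 parents, 1.2 km offspring spread) — lakes cluster, and clustering
  is what gives the variogram its short-range structure;
* first-census prevalence 5% (zm) and 8% (ewm). The real system's 0.67%
  would leave four positives at n = 600 — no variogram or ROC analysis
  survives that; the chosen prevalences keep the positive counts
  (~30/~48) in a regime where the method is actually exercised.
  Census-to-census growth factors 2.2 (zm) and 1.2 (ewm) mirror the
  57→125 and 251→304 growth patterns of the real system;
* a latent logistic risk score with effects traffic 1.2, road access 0.8,
  spatially autocorrelated Gaussian field 1.0 (exponential covariance,
  4 km range); second-census infestations add a proximity effect
  (2 km decay scale, coefficient 2.0) and a stream-connectivity effect
  (1.0). Intercepts are calibrated by root-finding so expected prevalence
  and growth hit their targets exactly in expectation;
* reporting: each true infestation is detected with probability
  `plogis(1.5 + 1.0 * (road z + traffic z))` per census — about 80%
  on average, biased toward accessible waterbodies; never a false
  positive, never a retraction. The underreporting rate is deliberately a
  free parameter: no published estimate exists to pin it;
* 5,000 survey records, 79% ineligible (mirroring the reported 21%
  eligibility), station/trip-end draws proportional to a gravity-style
  propensity (lognormal size over distance).

All randomness derives from one seed through named substreams, so adding
a generator never perturbs another and every output is byte-reproducible.

What the generator does **not** emulate: real hydrological routing (streams
are polylines threading nearby waterbodies, not a flow network), lake
polygons (points only), seasonal survey dynamics, and spatial gaps in
road coverage. Passing tests therefore show that the pipeline recovers
risk structure of the kind it assumes — covariate-driven, spatially
autocorrelated, under biased observation — not that it would achieve any
particular AUC on the real databases.

## Numerical choices

* Variogram fitting bounds the range to `[lag_size, 4 × max lag]` and
  clamps nugget and partial sill non-negative (boundary solutions are
  compared by weighted SSE). The desk-scale pipeline uses lag 0.5 km ×
  12 lags — the published 0.04 km lag scaled to the 30 km synthetic
  extent; the function defaults keep 0.04 km for data on that scale.
* The kriging neighborhood takes the 16 nearest data per variable
  (search radius unlimited by default). Sixteen nearest points already
  reproduce global solves to well within the indicator's noise at desk
  scale, at a quarter of the cost of 32; the parameter is in
  `kriging_params()` for users who want larger neighborhoods.
* Singular co-kriging systems are retried once with a 1e-10 diagonal
  jitter, then raised as errors.
* The grid cell defaults to the lag size; cells without a waterbody are
  fixed at probability 0 (introductions need a waterbody), cells with one
  are predicted at their centre and clamped to [0, 1].
* Replicate studies (the 20-seed signal and null runs) use n = 600
  landscapes; that size keeps a full 20-replicate pipeline study in the
  minutes range while leaving every stage non-trivial.
* Provenance for a pipeline run is centralised in `provenance.json`
  (full generator config and kriging parameters) next to the stage
  outputs, which are all plain CSV/GeoJSON/ASCII-grid/JSON files.

## Known limitations

* Negatives in every validation contain unreported true infestations;
  AUCs are computed against an imperfect reference and are best read
  comparatively (model vs model, signal vs null).
* The LMC uses a single shared-range structure plus nugget; strongly
  multi-scale cross-dependence would need more structures.
* Indicator kriging's probabilities are method-consistent, not
  calibrated posteriors; the quantile ranking (which is invariant to
  monotone distortion) is the intended consumption format.
* With very few positives (a handful of new reports between censuses)
  per-seed AUCs are noisy; conclusions should rest on replicate means,
  as in `analysis/05_replicates.R`.
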