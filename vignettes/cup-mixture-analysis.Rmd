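---
title: "Analysing current-use pesticide mixtures in soil and vegetation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing current-use pesticide mixtures in soil and vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupmix)
```

## The problem

Agricultural fields receive a sequence of current-use pesticides (CUPs)
over the year, so soil-dwelling and plant-associated insects are exposed
not to single substances but to residue mixtures that change with the
season and fade with distance into adjacent non-target meadows. `cupmix`
implements the analysis chain for monitoring campaigns of this kind: a
long-format residue table (one row per site x matrix x distance class x
month x compound) feeds four largely independent analyses — mixture
summarisation, seasonal curve comparison, distance decay, and additive
mixture risk — plus a synthetic campaign generator that provides ground
truth for every estimator.

The emulated design is nine sites (three per management system: arable,
vegetable, viticulture), four distance classes (in-field, mapped to 0 m at
the field margin, and 1, 5, 20 m into the meadow), thirteen monthly
campaigns, and two matrices (topsoil and vegetation), with concentrations
in µg/kg dry weight (= ng/g).

## Censoring semantics

Residue measurements are left-censored twice: below the limit of detection
(LOD) nothing is seen; between LOD and the limit of quantification (LOQ)
a compound is detected but cannot be quantified. The package encodes the
convention used throughout the analysis:

* a `below_loq` detection **counts** towards the number of CUPs in a
  sample, mixture membership, and detection frequency;
* it contributes **zero** to every concentration sum (total
  concentrations, means, risk quotients);
* `quantified` holds if and only if the concentration is at or above the
  LOQ, and this is validated at table construction, not assumed.

The distinction matters: a sample full of traces has a high CUP count and
a zero total concentration, and both facts are informative.

## The synthetic campaign generator

`generate_campaign()` simulates the mechanisms the estimators assume, with
known ground truth:

* **Soil**: each application pulse adds its dose to the in-field soil
  concentration, which then dissipates first-order with a per-compound
  half-life `dt50` (months).
* **Drift**: off-field concentrations at distance $x$ equal the in-field
  level times $e^{b x}$ with a per-system $b < 0$ (1/m). The defaults
  (−0.47 arable, −0.52 vegetable, −0.11 viticulture) encode the expected
  contrast between ground-level (2D) spraying and canopy-directed (3D)
  spraying in vineyards, which drifts much further.
* **Vegetation**: an application deposits
  `dose x interception x mass_ratio` on plants — the mass ratio (default
  20) converts a soil-referenced dose to the much smaller intercepting
  plant biomass, which is why vegetation concentrations exceed soil
  concentrations. Between months plant residues retain a fraction
  `vegetation_dilution` (default 0.25, representing growth dilution and
  wash-off, chosen so that vegetation counts rise to summer maxima and
  decline afterwards rather than accumulating like soil); off-field
  vegetation is reset by mowing (defaults: months 4 and 8 of the
  Feb-to-Feb grid).
* **Measurement**: observed = noiseless x lognormal(mean 1, CV
  `noise_cv`, default 0.3), then censored against LOD/LOQ.

What the generator does **not** emulate: leaching, volatilisation,
metabolite formation, weather-driven drift episodes, plant uptake of
systemic compounds, site-to-site heterogeneity of application calendars
(replicate sites are exchangeable draws around one system-level truth),
and missing vegetation samples. Passing tests on synthetic campaigns
therefore demonstrate correctness of the estimators under the stated
mechanisms, not robustness to every feature of real field data.

Default application calendars mirror regional practice qualitatively:
arable fields get spring and autumn pulses, vegetable fields repeated
pulses across the season, viticulture a fungicide-heavy May–August
programme. `synthetic_endpoints()` provides deterministic, clearly
labelled synthetic toxicity values (not literature values) so that risk
examples are reproducible offline.

## Mixture summaries

`summarize_samples()`, `detection_frequency()`, `concentration_stats()`
and `enumerate_mixtures()` produce the sample-level overview. One design
point deserves a note: a "total mean concentration" per compound is
ambiguous — the mean over quantified records only, or over all samples of
the matrix? Both are reported (`mean_quantified`, `mean_all`), with the
quantified-only variant as the headline because it does not shrink with
the number of uncontaminated samples. Samples with no detection are
excluded from mixture enumeration and reported separately
(`n_empty_samples`).

## Seasonal curves: loess + KL divergence

Monthly means of a per-sample statistic (default: CUP count) over the
pooled replicate sites of a system are smoothed with loess — tricube
weights, local quadratic (`degree = 2`), no robustness iterations, exact
local regression (`surface = "direct"`, which also allows the
extrapolation needed at the grid ends during cross-validation). The span
is either fixed or selected by leave-one-out cross-validation over the
grid 0.3–1.0 (step 0.1); ties are broken towards the larger, smoother
span.

To compare two annual courses the smoothed curves are turned into
probability distributions: values are floored at `epsilon = 1e-6`
(clipping any negative loess excursions) and L1-normalised over the month
grid. The Kullback–Leibler divergence
$KL(P \| Q) = \sum_i P_i \log_2 (P_i / Q_i)$ (bits) then quantifies how
much one system's seasonal pattern diverges from another's; it is
asymmetric and zero only for identical curves. The floor guarantees a
finite divergence; its value is recorded in the run settings because the
normalisation is a modelling choice, not a mathematical necessity.

Seasonal extrema are located on *detrended* series: an OLS line over the
year is subtracted, and a single forward pass emits an extremum whenever
the residual series moves more than `delta = 0.3` (in units of the
statistic) away from the running candidate. The pass starts in
maximum-seeking state, so a series whose first crossing is downward emits
its running maximum first; kinds then alternate, and a trailing candidate
never confirmed by a crossing is not emitted. This initial-direction
convention is ours; the algorithm family does not fix it.

## Distance decay

The transect response $y$ (per-sample CUP count, or total concentration)
is fitted against distance $x$ with

$$y = a \, e^{b x} + c$$

by Levenberg–Marquardt damped least squares (`minpack.lm::nlsLM`;
start $a_0 = \max(\bar y_{x=0} - c, 10^{-3})$, $b_0 = -0.1$, max 200
iterations). $a$ is the excess at the field margin over the background,
$b$ the decay rate (more negative = faster), and $c$ is **fixed, never
estimated**.

Where to anchor $c$ is the one genuinely open design point. We anchor it
at the mean response of the *farthest* sampled distance: $c$ is the
background the decaying curve relaxes to, and a decaying exponential with
$a > 0,\ b < 0$ can never fall below its own asymptote — anchoring $c$ at
the (highest) in-field mean would make the model structurally unable to
follow a decreasing transect and drives the optimiser into a singular
gradient. The in-field anchoring and an explicit numeric $c$ remain
available (`c_background = "in_field"` or a number) for sensitivity
checks. In-field observations are included in the residual sum by default
(`include_infield`), and fits with $\hat a \le 0$ or $\hat b > 0$ are
flagged rather than constrained.

Two caveats worth knowing. First, the decay rate of the *CUP count* is
not the decay rate of the underlying concentrations: counts fall when
individual compounds cross their LODs, so the count-based $b$ is a
different (design-dependent) quantity. Parameter-recovery checks against
the generator's `b_true` therefore use the total-concentration response,
which decays exactly as $e^{bx}$ when all compounds of a system share one
drift rate. Second, for shallow decays (e.g. $b = -0.11$) the farthest
distance still carries a substantial share of the in-field signal, the
background anchor absorbs it, and $\hat b$ is biased towards faster
decay; recovery checks use the steep-decay subsets where the anchor is
clean.

## Mixture risk and hazard

For soil organisms, each compound's risk quotient is
$RQ = \mathrm{MEC}/\mathrm{PNEC}$ with
$\mathrm{PNEC} = \mathrm{NOEC}/10$ (chronic NOEC preferred) or
$\mathrm{LC50}/1000$ as fallback, and the mixture risk quotient is the
additive sum $\mathrm{MRQ} = \sum RQ$ per sample (concentration
addition; synergy is out of scope). MECs are µg/kg, PNECs mg/kg, and the
unit conversion happens in exactly one place. Risk bands are left-closed:
negligible $[0, 0.01)$, low $[0.01, 0.1)$, medium $[0.1, 1)$, high at
exactly 1, very high above 1 — the source conventions disagree at the
edges, so the package picks one boundary convention and documents it;
"high" and "very high" collapse to "at/above threshold" in any practical
reading.

For a surrogate ground-nesting solitary bee, the acute contact hazard
quotient of a compound is

$$HQ = \frac{2.23\ \mathrm{g} \times \mathrm{MEC}\ [\mathrm{ng/g}]}
{\mathrm{LD50}_{\mathrm{honey\ bee}} / 10\ [\mathrm{ng/bee}]}$$

(2.23 g is the soil mass a female contacts during 48 h of burrowing; the
divisor 10 converts the honey-bee endpoint into a solitary-bee
surrogate), and $\mathrm{MHQ} = \sum HQ$ with a strict hazard flag at
$\mathrm{MHQ} > 1$. The LD50 is held internally in ng/bee so the quotient
is dimensionless without hidden factors; values declared in µg/bee are
converted at read time.

Compounds without a usable endpoint are excluded from the sums — never
imputed — and every result carries `coverage`, the fraction of detected
compounds that had an endpoint. Below-LOQ detections contribute zero but
stay in coverage's denominator. Single-compound attribution reports
`rq_max` (or `hq_max`), its compound, and its fraction of the mixture
total, computed per sample and then averaged where aggregation is
requested. Aggregation over the three replicate sites reports mean and
maximum per system x month x distance cell and flags incomplete cells.

## Numerical choices and degenerate inputs

* Loess needs ≥ 4 points and a window of ≥ `degree + 1` points; smaller
  spans are rejected, infeasible CV candidates dropped.
* `detrend_linear()` refuses fewer than 3 points or a degenerate grid.
* `detect_peaks()` requires `delta > 0`; an empty series yields an empty
  peak set.
* `fit_exponential()` requires observations at $x = 0$ and at two further
  distances, rejects an all-equal response (amplitude unidentifiable),
  reports `converged = FALSE` instead of erroring when the optimiser
  fails, and treats convergence as a relative RSS change below $10^{-10}$.
* Probability normalisation rejects all-non-positive curves; KL refuses
  mismatched grids and non-distributions.
* Campaign generation draws records in a fixed deterministic order, so a
  fixed seed reproduces tables byte-identically.

## Problem sizes used in the tests

The test suite runs entirely on generated data: default campaigns of
9 sites x 4 distances x 13 months x 14 compounds x 2 matrices (13,104
records, under a second to generate), 100 random ≤ 15-compound samples for
the risk-engine oracle equivalence, 1000 random curve pairs for KL
non-negativity, and transects of n = 156 samples per system for drift
recovery. These sizes keep the full suite in the tens of seconds while
leaving every estimator's sampling noise far below the tested tolerances.

## Known limitations

* Additive risk assumes concentration addition; synergistic mixtures are
  outside the model.
* Oral/vegetation exposure routes are not assessed (no endpoints exist
  for them); the bee scenario is acute contact with soil only.
* The count-based drift rate is design-dependent (see above).
* Loess provides no inferential p-values; the KL comparison is
  descriptive.
* The generator's replicate sites share one truth per system, so
  between-site variance in real campaigns will exceed what the defaults
  emulate.
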