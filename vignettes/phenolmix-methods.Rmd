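---
title: "Methods: quantifying antioxidant interactions in phenolic-acid mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying antioxidant interactions in phenolic-acid mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolmix)
library(dplyr)
```

## The problem

The antioxidant capacity of a mixture is rarely the sum of its parts.
When phenolic acids — the most widespread class of plant phenolics — are
combined, their joint activity in a given assay can exceed the additive
expectation (synergy), fall short of it (antagonism), or match it
(additivity, i.e. no interaction). `phenolmix` implements the
expected-additivity analysis of such mixtures for two canonical assays:

* **FRAP** (ferric reducing antioxidant power), an electron-transfer
  assay whose results are expressed as the concentration of Fe²⁺ giving
  equivalent reduction (µM Fe²⁺);
* **ORAC** (oxygen radical absorbance capacity), a hydrogen-atom-transfer
  assay in which the decay of a fluorescent probe under peroxyl-radical
  attack is integrated over time and expressed relative to Trolox
  (µM Trolox Equivalents, TE).

The packaged study panel comprises ten phenolic acids — five
hydroxybenzoic (protocatechuic `P`, gentisic `Ge`, gallic `G`, vanillic
`V`, syringic `Sy`) and five in the hydroxycinnamic set (*p*-coumaric
`pC`, caffeic `C`, ferulic `F`, sinapic `Si`, plus rosmarinic acid `R`,
a caffeic-acid ester) — measured individually and in every binary,
ternary, quaternary and quinary equimolar combination within each class.

## The interaction index

For a k-component equimolar mixture at total concentration $C$, each
component is present at $C/k$. Assuming each compound's activity is
linear in its concentration (the package checks this premise on the
individual dose–response data; see `linearity_check()`), component $i$
contributes $1/k$ of the activity $A_i(C)$ it shows alone at the full
concentration $C$. The expected additive ("theoretical") activity is
therefore the arithmetic mean

$$ T = \frac{1}{k}\sum_{i=1}^{k} A_i(C), $$

and the interaction index is the relative departure of the observed
mixture activity $E$ from it:

$$ d = 100\,\frac{E}{T} - 100 \quad (\%). $$

`theoretical_mixture_value()` and `difference_percent()` implement these
two steps; their composition is algebraically identical to dividing the
observed combination value by the sum of the per-component contributions
$A_i/k$, and the test suite verifies that equivalence to $10^{-9}$ on
randomly drawn instances for $k = 2..5$.

Classification (`classify_interaction()`) uses a band of ±5 percentage
points around zero: $|d| \le 5$ is **additive**, $d > 5$ **synergistic**,
$d < -5$ **antagonistic**. Two conventions deserve a note:

* **Inclusive boundary.** The source tables describe both "difference
  > 0 ⇒ synergistic" and "difference ≅ 0 ± 5 % ⇒ additive". We resolve
  the overlap in favour of the more specific band rule: exactly +5 is
  additive. The band half-width is configurable
  (`interaction_config(additive_band_pct = …)`).
* **Reporting precision.** Printed differences mix one-decimal values
  (|d| < 10) with integers, rounded half away from zero;
  `format_difference()` reproduces that convention while all underlying
  values are kept at full precision.

### Uncertainty

The study tables report replicate SDs on activities but not on
differences. `difference_uncertainty()` propagates replicate noise into
$d$ by the first-order delta method, treating the mixture mean and the k
individual means as independent:

$$ \operatorname{sd}(d) \approx 100\,\frac{E}{T}
   \sqrt{\frac{s_E^2/n_E}{E^2} + \frac{\sum_i s_i^2/n_i}{k^2 T^2}}. $$

Being a ratio statistic, $d$ (and its delta-method SD) is invariant under
a common rescaling of all activities — a property the tests exercise —
and the approximation is validated against a Monte-Carlo resampling
oracle (10⁵ Gaussian draws) to 5 % relative accuracy. For the small
relative errors typical of these assays (a few percent) the first-order
approximation is comfortably adequate; it degrades when
$\operatorname{sd}(T)/T$ grows large, where the ratio's distribution
becomes skewed.

## Assay reduction

The upstream reductions from raw plate-reader signals to activity units
follow the community-standard formulations (the interaction analysis is
agnostic to how its activities were obtained):

* **FRAP**: endpoint absorbance is calibrated against an Fe²⁺ ladder by
  ordinary least squares (`fit_standard_curve()`, free intercept by
  default since blank-corrected instruments can still carry offsets;
  `through_origin = TRUE` forces the origin) and inverted
  (`frap_to_fe2()`).
* **ORAC**: each well's fluorescence trace is normalized to its initial
  reading ($f(0)=1$, for plate-to-plate comparability of gains — raw-AUC
  integration is available via `normalize = FALSE`), integrated by the
  trapezoidal rule over the 80-minute observation window
  (`curve_auc()`), blank-corrected (`net_auc()`), and converted to µM TE
  against a Trolox-ladder net-AUC calibration (`orac_te()`,
  `reduce_orac_plate()`).

Numerical notes: the trapezoid is exact for piecewise-linear traces
(tested under grid refinement) and agrees with a 0.001-min Riemann
oracle within 0.1 % for exponential decays sampled at 1-min intervals,
the study's acquisition rate. Degenerate inputs (non-increasing time
stamps, $f(0)=0$, single calibration point, zero-slope curves) raise
errors rather than propagating nonsense.

## The packaged study tables

`load_fixtures()` returns the complete printed dataset: the ten-compound
panel with substituent features, individual activities (FRAP at
100/500/1000 µM, ORAC at 2.5/5 µM; mean ± SD over triplicates), and the
four mixture tables (26 hydroxybenzoic and 26 hydroxycinnamic mixtures)
with experimental means and the printed theoretical/difference cells
stored **verbatim as strings at printed precision** — `"4.0"` is not
`"4"`, and nothing is re-rounded on ingest. Replicate-level data were
never published, so fixture measurements are summary-only
(`summary_only = TRUE`, n = 3).

`reproduce_tables()` recomputes every theoretical and difference cell
from the individual activities and the experimental means, rounds to the
printed precision (half away from zero) and compares, passing a cell when
the gap is at most one unit of the printed final digit. The tolerance
exists because the source tables were rounded from unrounded raw
replicate means: recomputing from printed inputs cannot reproduce every
cell to the last digit. Cells that disagree beyond that are *flagged*,
never silently accepted, and two groups of flags are distinguished:

* **Known typos** (`known_typo`): order-of-magnitude inconsistencies in
  the source. The entire 500 µM theoretical column of the hydroxycinnamic
  FRAP table is inconsistent with the printed individual activities for
  all fifteen ferulic-containing mixtures — the cells reproduce almost
  exactly if ferulic's 500 µM mean (885) is transcribed as 8885, and the
  printed differences are consistent with the inflated theoreticals, so
  the error propagated into that column's differences too. One further
  cell (C+Si at 100 µM, printed 3560 vs recomputed 355.5) has an extra
  digit.
* **Ordinary flags**: small drifts (1–4 final-digit units) in a handful
  of ORAC difference cells, the expected footprint of the authors'
  unrounded raw means.

`fixture_notes()` records source discrepancies that are not per-cell
arithmetic, e.g. the running text calls gentisic + syringic
ORAC-antagonistic (−24 %) while the table prints Ge+Sy at +236 % and
G+Sy at −24 %; the table is taken as authoritative and the discrepancy
is surfaced, not adjudicated. Likewise the duplicated "1440 ± 23"
experimental entry and a suspicious "± 0" replicate SD are stored as
printed and noted.

```{r}
rep <- reproduce_tables(load_fixtures())
rep
```

## Structure–activity features

Only features computable from the declared substituent maps are encoded
(`feature_table()`): hydroxyl and methoxy counts, a catechol indicator
(adjacent 3,4-dihydroxy pattern — gentisic acid's 2,5 arrangement does
*not* count, matching the structural distinction the assay literature
draws), and the acid-class indicator. Positional electronic effects,
intramolecular hydrogen bonding, bond-dissociation enthalpies and
dissociation equilibria are qualitative rationales, not computable from
the data, and are deliberately out of scope.
`feature_activity_correlation()` reports Spearman rank correlations
(average ranks under ties) as a descriptive check; with ten compounds
these are exploratory summaries, not inference.

## The synthetic-data generator

The generator emulates the study design so every stage can be tested
with known ground truth:

* individual replicates are `slope_i * C * (1 + ε)`, ε ~ N(0, `noise_cv`)
  — linear dose–response with multiplicative noise. Multiplicative
  (rather than additive) noise was chosen because the printed replicate
  SDs grow with the mean; the default CV of 0.03 matches their typical
  relative size (e.g. 2341 ± 32). Default slopes sit on the observed
  FRAP scale (≈0.1–5 µM Fe²⁺ per µM); defaults of 3 replicates and the
  100/500/1000 µM grid mirror the study;
* mixture means are the additive expectation inflated by an injected
  effect δ: `(Σ slope_i C / k) (1 + δ/100)`, with replicate noise on
  top. δ is injected on the mean, not per replicate, so it is exactly
  identifiable in the noiseless limit (`difference_pct == δ` to 1e−9, a
  test);
* ORAC plates are exponential decays whose rates are solved numerically
  (bisection to 1e−13) so each well's blank-relative net AUC is exactly
  linear in its programmed TE value; reduction therefore recovers the
  programmed values to 1e−6, and an end-to-end plate → reduction →
  interaction analysis recovers the injected δ.

Seeding: one master seed; per-table child seeds derive as
`(seed·7 + offset) mod (2³¹−1)` with offsets 1 (individuals), 2
(mixtures), 3 (plate noise), so each table regenerates independently and
identical specs give byte-identical output.

What the generator does **not** emulate: plate spatial effects,
inner-filter corrections, heteroscedasticity beyond a constant CV,
nonlinear dose–response, or mechanistic radical kinetics. Passing
recovery tests therefore demonstrates the pipeline's correctness under
the stated noise model, not robustness to real-plate artefacts.

The suite also quantifies a property the interaction literature rarely
reports: the false-positive behaviour of the ±5 % band. Under the
additive null with CV 0.03 triplicates, the proportion of binary
mixtures classified non-additive is checked against a direct Monte-Carlo
simulation of the index's null distribution (agreement within 2
percentage points over ~1000 simulated mixtures).

## Problem sizes and runtime choices

Validation experiments were sized to be decisive yet quick: 1000 random
instances for the formula-equivalence and invariance properties, 200
seeds for recovery of an injected δ = 30 (mean within ±2 points,
classification synergistic in >95 % of runs), ~1000 simulated binary
mixtures plus 4000-draw-per-pair oracles for the null-calibration check,
and 10⁵ resamples for the delta-method oracle. The full suite and the
table recomputation each run in well under a minute on a single core.

## Known limitations

* The theoretical value presumes linear individual dose–response;
  the package verifies Pearson r ≥ 0.99 on the packaged FRAP data, but
  where linearity fails the additive expectation (and hence d) is
  biased. Measuring individuals at C/k directly would remove the
  assumption at the cost of a different design; that alternative is not
  implemented because the index is defined at the full concentration.
* No hypothesis test is attached to the classification: the ±5 % band is
  a convention, not a confidence statement. `difference_uncertainty()`
  lets users judge whether a difference is resolvable against replicate
  noise, but the classification itself follows the band.
* Only the expected-additivity index is implemented; Loewe-, Bliss- or
  Chou–Talalay-style combination models are out of scope.
* Substituent features are declared, not perceived from structures; no
  SMILES/InChI parsing.
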