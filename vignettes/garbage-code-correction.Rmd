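---
title: "Correcting road traffic mortality for nonspecific ICD-10 codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting road traffic mortality for nonspecific ICD-10 codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmortality)
```

## The problem

Civil registration systems certify deaths with ICD-10 codes, but a
substantial share of certificates carry codes that are too vague to support
cause-specific analysis. For road traffic statistics the damage is layered:
a death coded R99 ("other ill-defined causes") could be anything; X59
("exposure to unspecified factor") is known to be an unintentional injury
but nothing more; V87.4 ("collision between car and heavy vehicle, user
unspecified") is known to be a road traffic death but not whether the
decedent walked, cycled, rode or drove. Left in place, these codes deflate
road traffic mortality rates, distort trends, and misclassify countries'
progress against the international target of halving road traffic deaths
between 2021 and 2030.

This package implements the full correction chain: classify nonspecific
codes into five categories, measure their prevalence, redistribute them to
specific causes by the proportionate method, and recompute age-standardized
rates, geometric-mean trends and 2021/2030 projections on the corrected
table.

## The five-level hierarchy

Each nonspecific category sits at one level of a nested hierarchy, and each
level defines three code sets held in a YAML registry
(`load_registry()`):

* the **garbage set** — the nonspecific codes themselves: R95/R96/R98/R99
  (ill-defined cause, level 1); Y34/Y87.2/Y89.9 (undetermined intent,
  level 2); X59 (unspecified unintentional injury, level 3); V99/Y85.9
  (unspecified transport crash, level 4); V87, V87.0–V87.8 and V89.2
  (unspecified road traffic, level 5);
* the **denominator** — the level's parent set, used for prevalence and for
  the temporal-window rule: all causes; injuries (V01–Y89); unintentional
  injuries (V01–X59); transport (V01–V99 and Y85.9); road traffic
  (V01–V89);
* the **target set** — where the garbage mass goes: the denominator minus
  every garbage code, except at level 5, where targets are occupant and
  motorcyclist codes only (V20–V79), because a crash specific enough to be
  coded V87.x almost always involved a vehicle occupant or rider whose
  group the certifier failed to record.

Road-user groups follow the standard transport blocks: pedestrians V01–V09,
pedal cyclists V10–V19, motorcyclists V20–V29, occupants V30–V79, other
road users V80–V89 (minus the level-5 garbage codes). "Road traffic" means
V01–V89 at the three-character level, so the level-5 garbage codes count
inside road traffic totals — they are road traffic deaths of unknown user —
while V90–V98 (water, air, other transport) and V99 sit outside.

Three classification conventions are worth spelling out. A bare V87 is
treated as nonspecific: without a fourth character it denotes a road
vehicle collision with the user unrecorded. A four-character code inherits
garbage status from a bare three-character member only when the registry
does not distinguish that root's children (X59.0 is garbage via X59, but
V87.9 — "other specified road vehicle accidents, noncollision" by our
reading of the listed children — stays specific, as do V89.0/.1/.3/.9).
And fourth-character traffic/non-traffic distinctions (e.g. V10.0) are
ignored: all V01–V89 deaths count as road traffic. The registry file makes
all three conventions user-configurable rather than baked in.

## Quality indicators

`assess_quality()` reports, per country-year and category, the percentage
of the level's deaths carrying the level's nonspecific codes. The
denominator includes the level's own garbage deaths by default — "what
share of this level is nonspecific" — with a flag to exclude them. A zero
denominator yields a missing value, never 0%: a country with no recorded
injury deaths has unknown, not perfect, injury coding. Percentages are
binned 0–20 / 21–40 / 41–60 / 61–80 / 81–100, with boundary values going to
the lower bin (the printed labels "0%–20%", "21%–40%" imply upper-inclusive
lower bins). `assess_availability()` counts years with any data in the
assessment window.

## Proportionate redistribution

The proportionate method assumes nonspecific deaths follow the same cause
distribution as the specific deaths of their target set, and allocates them
accordingly. For category $c$ in country-year $(i,t)$ with garbage mass $G$
in a (sex, age band) stratum, each target cause $k$ receives

$$ \Delta_k = G \cdot \frac{D_k}{\sum_{k'} D_{k'}} $$

where $D_k$ are the target-set specific deaths pooled over a temporal
window. Pooled counts act as weights only, so the allocation is scale-free.

**Windows.** The window width adapts to how bad the coding is: below 30%
nonspecific, the study year alone; 30–49%, the year ± 1; 50–69%, ± 2; 70%
and above, ± 3. Boundary proportions take the wider window (30% belongs to
"30–49%"). If *any* nominal window year is unavailable for the country, all
available years are used instead — a strict reading of the all-available-
data fallback, applied even when only one edge year is missing. The
proportion that drives the window is the category's own-level share, the
same quantity the quality indicator reports (as a fraction).

**Cascade.** Categories are processed top-down: ill-defined → undetermined
intent → unspecified unintentional → unspecified transport → unspecified
road traffic, each step's output feeding the next step's proportions and
pools. The ordering is the internally consistent one: level-$k$ garbage
must be placed before it can serve in (or inflate) level-$k{+}1$
denominators. After a step, the processed category's rows are removed; its
mass lives on in specific causes or in the unallocated ledger.

**Strata and fallbacks.** Allocation happens within (sex, age band) strata
to preserve the age structure that standardization needs. A stratum whose
target pool is empty falls back to sexes pooled within the age band, then
to the whole country-year pool, and finally to an explicit `unallocated`
ledger entry with a warning — mass is never silently dropped, and the
conservation identity *output = input specific + placed; placed +
unallocated = garbage* is enforced to 1e-9 by the tests. A `strata =
"none"` mode reproduces country-year-level redistribution for users who
want it.

**Level split.** The first four categories sit outside road traffic, so
redistributing them can only add road traffic deaths; level 5 moves mass
within road traffic. Overall, pedestrian and pedal-cyclist statistics
therefore use the levels-1–4 cascade (`include_level5 = FALSE`), and
occupant and motorcyclist statistics the full cascade — matching how each
group's counts are distorted.

## Rates, trends, projections

`age_standardize()` is the direct method against the new WHO world standard
population (bundled, collapsed to 18 five-year bands 0–4 … 85+; the
published percentages do not sum exactly to 100, so the shipped weights are
normalized to sum to 1). Rates are per 100 000 standard population — the
scale is conventional and cancels in every downstream ratio. Both sexes are
combined by default; deaths of unknown age are spread proportionally over
known bands (within cause where possible, else within the stratum) before
any rate is computed, and unknown-sex rows count in totals but not in
sex-specific outputs.

The average annual change is the geometric mean of year-over-year ratios,
which collapses to the endpoint form
$r = (D_{\text{last}}/D_{\text{first}})^{1/(y_{\text{last}}-y_{\text{first}})} - 1$.
Gaps in a series are annualized through the exponent, so an intermediate
zero cannot poison the product; a series *ending* at zero gives $r = -1$
(−100% per year), and a series starting at zero, or a single year, has no
defined trend. Projections chain from the last observed year,
$D_Y = D_{\text{last}}(1+r)^{Y-y_{\text{last}}}$, so countries whose data
end before 2020 still project; the 2021→2030 percent change
$100((1+r)^9-1)$ is independent of the base. On-track means that change is
at most −50, with a 1e-9 tolerance so the exactly-halving rate
$r = 0.5^{1/9}-1$ classifies on track despite floating-point rounding.
`classify_shift()` labels corrected-vs-uncorrected trend changes as sign
flips (zero counts as its own sign) or as moves of more than 10 percentage
points on the annual rate.

## The synthetic panel generator

`simulate_panel()` emulates a national vital-registration extract:
country-year panels of ICD-10-coded deaths by sex and five-year age band,
with known ground truth. The default cause mix spans roughly forty specific
codes across every hierarchy level — about 2% road traffic and 5% injuries,
in line with typical national profiles — so every redistribution step has a
non-empty target pool. Population tables are generated jointly with a fixed
age structure, giving standardized rates a closed-form expectation under
the configuration. A per-country multiplicative drift on road traffic
deaths creates known trends.

Garbage injection runs in reverse cascade order (level 5 first, level 1
last), the mirror image of redistribution. This makes deterministic
proportional injection the *exact inverse* of the cascade with same-year
windows: the test suite verifies truth recovery to 1e-9 per cell on a
20-country, 6-year panel with per-category fractions up to 0.9, and
equality of corrected and truth age-standardized rates at the same
tolerance. Stochastic mode draws multinomial truth tables and binomial
relabelling for realistic integer counts; biased mode scales each cause's
relabelling propensity, deliberately violating the proportionality
assumption to measure its failure mode.

Validation experiments use deliberately chosen problem sizes: 50 small
stochastic panels for the conservation ledger; 100 country-years at 100 000
deaths each for stochastic recovery (corrected overall rates within 2% of
truth in at least 95% of country-years, at garbage fractions of 2% for the
rare categories, 10% for unspecified unintentional injury and 20% for
unspecified road traffic — the profile of a typical mid-quality country);
and 20 seeds per direction for the bias sign test, where stealing garbage
preferentially from non-road-traffic causes makes corrected road traffic
rates overshoot truth and vice versa.

What the generator does **not** emulate: cohort demography, migration,
correlated certifier behaviour across years, underreporting, and cause
misclassification other than nonspecific coding. Passing tests therefore
show the algebra of the correction is right and its assumption's failure
mode has the expected sign — not that corrected numbers from any real
country are unbiased. If certifiers disproportionately assign garbage codes
to particular causes, corrected results inherit that bias; this is the
method's stated limitation, and the biased injection mode exists precisely
to demonstrate it.

## Numerical and interface choices

Fractional death counts are permitted everywhere (redistribution requires
them). Duplicate keys, negative counts and malformed codes are hard errors;
conservation checks in the WHO-dialect reader tolerate 0.5 deaths against
the per-row total before warning. The WHO reader supports the detail age
formats (Frmat 0/1/2), which only require aggregating fine bands up to the
canonical 18; coarser lumped formats are rejected (or dropped with a
warning under `frmat_policy = "drop"`) rather than split against an
external population structure the file itself does not carry. Undotted WHO
causes ("V873") are normalized to explicit decimals. All randomness flows
from the single `seed` in `sim_config()`; deterministic modes are
bit-reproducible, which the pipeline test verifies by byte-comparing CSV
artifacts across runs.

Sequelae of transport accidents (Y85.9) redistribute in the same step and
to the same targets as V99: both are "transport crash, details unknown" for
the purpose of this hierarchy. Whether level-1 garbage should target all
causes or only injury-adjacent ones is genuinely open; the registry follows
the all-causes convention, and a custom registry file can narrow it.

## Limitations

* The proportionate method's assumption is untestable on real data from
  within the data; the bias experiments quantify direction, not magnitude.
* Corrections cannot recover deaths never registered; availability
  assessment flags, but does not fix, missing country-years.
* The registry ships one defensible reading of the code sets; GBD- or
  WHO-variant analyses should supply their own YAML.
* Trend estimates use endpoints only; countries with volatile small counts
  get volatile trends, which is inherent to the geometric-mean estimator's
  design.
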