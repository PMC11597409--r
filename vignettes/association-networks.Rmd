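---
title: "Proximity association networks and their demographic predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity association networks and their demographic predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gorassoc asks what predicts how strongly adult female gorillas associate.
Female gorillas disperse between groups repeatedly, so stable kin-based
bonds are largely absent; the package implements the full chain of analysis
used to test whether association strength instead tracks short-term
demographic similarity — shared infant care, recent immigration, dominance
rank, and group instability.

## The measurement model

The raw observation is an instantaneous scan taken every 10 minutes during a
15–60 minute focal follow of one adult female: her activity and the set of
adult females within 5 m of her. From the scans of one group over one window
we tally, per female, $N_a$ — the number of scans with $a$ as focal — and,
per unordered dyad, $N_{ab}$ — the number of scans, from either member's
focals, on which the two were within 5 m. The dyadic association strength is
the simple ratio

$$\mathrm{Strength}_{ab} = \frac{N_{ab}}{N_a + N_b} \in [0, 1],$$

and a female's individual (node) strength is her weighted degree, the sum of
her dyadic strengths. Windows are half-open (`[start, end)`), dyads
unordered, and the matrix symmetric with zero diagonal by construction.

One refinement matters for partially co-resident dyads. If female $b$
immigrates mid-window, scans of $a$ taken before $b$ arrived can never
contribute to $N_{ab}$, so dividing by $a$'s full-window scan count would
mechanically deflate the pair's strength. The package therefore counts each
member's denominator scans only over the dyad's joint residency within the
window. For fully co-resident dyads (the overwhelming majority) this is
identical to the plain tally; for immigration and emigration years it scores
the dyad over its joint exposure. Without this correction, simulation shows
the "new immigrant" term absorbs a purely mechanical negative bias — its
null-calibration intervals missed zero far more often than nominal — which
would be indistinguishable from the social effect the analysis is trying to
measure. The per-node focal counts written to `node_strength.csv` remain
plain tallies. The alternative reading of the individual score, a per-capita
neighbour rate (total times seen within 5 m over own scan count), is
available via `node_strength_mode = "raw_rate"`.

## Dominance

Hierarchies are Elo ratings computed separately per group and sex from dated
displacement/avoidance events: everyone starts at 1000, $k = 100$, the
winner gains $k(1 - p)$ with $p$ the classic base-10 logistic expectation at
scale 400. Individuals joining an already-rated hierarchy enter at the
bottom, i.e. at the current minimum among active members. Daily scores are
carried forward between interactions, averaged per calendar year over each
individual's active days only (no imputation before entry or after exit),
and min–max standardized per group-year so the top female scores 1 and the
bottom 0 regardless of group size or interaction rate. A dyad's average rank
is the mean of its two standardized ranks. The top-ranked male of each
group-year is that year's alpha; a lone male is alpha by default. Ties are
broken by earlier group entry and then id, so results are deterministic, and
events are sorted internally by date (then winner, then loser), so input
order is irrelevant. With a single female, or all scores tied, the
standardized rank is set to 0.5 with a warning rather than being undefined.

## Covariates and model tables

The demographic predictors follow strict date rules:

* **dependent infant** — an offspring younger than 365 days on strictly more
  than 183 days of the calendar year ("more than 6 months");
* **new immigrant** — the first scored year of an immigration tenure; a
  female joining on or before 1 July is scored (and flagged) that year,
  later joiners are first scored the following year and their entry year is
  excluded from all tables (the cutoff is configurable);
* **last year in group** — an emigration (not death or censoring) occurs in
  the following calendar year;
* **new alpha male** — the alpha's identity differs from the previous
  year's; the first observed year of a group has no defined value and its
  rows are dropped;
* **group size / female number** — weaned adults (both sexes) and adult
  females resident for the majority of the year; tenure is years since
  group entry.

Individual-year rows join node strength to these flags plus standardized
rank; dyad-year rows join dyadic strength to the dyad's average rank, a
three-level both/one/none infant category, and either-member immigrant
status. Rows with any undefined predictor are dropped and counted in the
log.

## Inference

The design calls for Bayesian Student-t mixed models. No MCMC backend is
assumed; instead `fit_hierarchical()` fits the same structure by maximum
likelihood with glmmTMB's Student-t family (identity link) and reports Wald
95% intervals, which play the role of the credible intervals: a term is
"meaningful" when its interval excludes zero. The individual model has
random intercepts for female and year; the dyadic model for each member,
the dyad, and year — two separate member intercepts approximate the
multi-membership structure that a Bayesian fit would express directly.
Continuous predictors are standardized by twice their sample standard
deviation so their effect sizes are comparable with binary contrasts; the
binary example $\{0,1\}$ maps to $\pm 0.354$ under the sample-sd convention
(the population-sd reading would give $\pm 0.5$; we follow the convention of
`arm::rescale`). Before fitting, a fixed-effects-only VIF screen (via `car`)
halts on perfect collinearity unless forced. Marginal and conditional $R^2$
use the variance decomposition (fixed-effects variance over total, and fixed
plus random over total), with the Student residual variance taken as
$\sigma^2\nu/(\nu-2)$ when the estimated degrees of freedom allow. Fixed
terms that are constant in a given data set (a small study with no
immigrant, say) are dropped and listed in the diagnostics rather than
crashing the fit. Because the backend is deterministic, a seed plus a
configuration reproduces every number exactly. No multiplicity correction is
applied, matching the analysis design; this is recorded in the fit metadata.

The time-matched models are factor-smooth additive models fitted by REML
with mgcv: `strength ~ condition + s(offset, by = condition, k = 5) +
s(dyad, bs = "re")`. The basis dimension equals the number of distinct
offsets (five), the smallest basis the design supports. A smooth is
classified meaningful by the Wald test of the whole penalized curve at the
interval level — not by its linear component, because an injected pulse
centred on the event is symmetric and has essentially no linear part — and
the REML smoothing-component standard deviation is reported as the smooth's
"sds" (wigglyness).

## The event windows

Two event types re-anchor the yearly windows. A second-birth event arises
for each dyad whose members' infant-dependency periods overlap (births less
than 365 days apart while co-resident); its anchor is the later birth and
offsets −2…+2 are scored. An immigration event is anchored on the group
entry date with offsets 0…+4. Each offset window is
`[anchor + 365k, anchor + 365(k+1))` — the offset-0 window *begins* at the
anchor, since the anchor replaces the 31 December boundary rather than a
window centre; leap days are ignored so all windows are exactly 365 days and
an anchor placed on 1 January of a non-leap year reproduces the calendar
pipeline exactly (this equivalence is a test). Multiple birth pairings of
one dyad within a single 365-day span are one joint-dependency episode and
yield one event; without this rule simultaneous births generate
near-duplicate events whose stacked comparison rows overstate the evidence
for every smooth. For a second-birth event exactly one dyad is focal; for an
immigration event every dyad containing the immigrant experiences the event,
which is what the condition flag encodes. Series at the edge of the
observation period keep their missing offsets (excluded from the model
tables, with a count) rather than dropping the whole event.

## The synthetic study generator

`simulate_study()` emulates the observation process end to end: 3 groups ×
8 years by default, 2–7 adult females per group, ~100 ± 50 focal follows
per female-year (truncated at 5, scaled by residency), 2–6 scans per
follow. Demography evolves at per-female-year rates of 0.15 births, 0.06
immigrations and 0.05 emigrations, with 0.10 alpha turnovers per
group-year — the scale realized in long-term gorilla study groups — plus
subordinate-male joins/departures at 0.4 per group-year, which gives the
within-group variation in weaned-adult group size that real groups show
(and without which group size, female number and group identity would be
perfectly collinear in the models). Groups never drop below two females;
births are spaced at least 365 days; immigrants do not give birth in their
arrival year.

Proximity is generated focal-centrically: at each scan every co-resident
female is within 5 m of the focal with probability
`plogis(beta0 + affinity + beta_rank_avg·meanrank + beta_both_infant·both +
beta_one_infant·one + beta_immigrant·either + RE_focal + RE_partner +
RE_year)`. Defaults: `beta0 = logit(0.08)` (matching the observed scale of
dyadic strength), `beta_both_infant = +1`, `beta_immigrant = −1`,
`beta_rank_avg = +0.5` on the logit scale, dyad affinity sd 0.3, female RE
sd 0.2, year RE sd 0.1. Latent dominance is drawn once per female (ranks
rarely change in these populations); females immigrating during the study
enter below the group minimum, consistent with bottom entry into the Elo
hierarchy; male dominance follows entry seniority so Elo-derived alpha
succession matches the recorded alpha tenures. Agonistic events are drawn
per co-resident same-sex dyad at 12 per year by default, the winner chosen
by the logistic of the latent gap.

Two deliberate frictions are part of the design. The generator's infant
effect switches on whenever both infants are under 12 months *on the scan
date*, while the covariate flag uses the more-than-6-months-of-year rule —
a realistic misclassification stress test that attenuates the recovered
infant effect relative to the injected one. And immigrant entry dates are
uniform over the year, so the mid-year scoring rule is exercised
constantly.

What the generator does not emulate: spatial structure (no movement model —
proximity draws are exchangeable given the covariates), male–female
association beyond alpha identity, infant mortality, observer effort
imbalance within years, and kinship (the study dyads are unrelated).
Passing recovery tests therefore shows the estimation chain is sound under
the stated generative model, not that field data meet its assumptions.

## Simulation scale and what the tests show

The recovery and calibration suites run twenty seeded replicates each at
the default 3 × 8-year scale (a few hundred dyad-year rows per replicate,
comparable to the published analyses of this design). The dyadic model is
required to recover the signs of the injected infant and immigrant effects
with intervals excluding zero, and to cover zero when the effects are
removed, in at least 16 of 20 replicates. The event-GAM check uses a
dedicated pulse scenario (only the both-infant effect injected, no common
year shocks): when other demographic effects are active, the non-focal
dyads' series are genuinely non-flat, so a flat "no" smooth is a property
only of the clean-pulse design.

## Known limitations

* Wald intervals from a maximum-likelihood fit are an approximation to the
  posterior intervals the design describes; with few random-effect levels
  they can be slightly anticonservative.
* The member random intercepts `(1|id1) + (1|id2)` under-pool relative to a
  true multi-membership term when the same female appears in both columns.
* Event series of co-occurring events share comparison dyads (duplicated,
  matched per event); the dyad random intercept absorbs only part of that
  dependence.
* The Elo bottom-entry rule uses the current active minimum; alternatives
  (fixed start, minimum minus an offset) would shift early ratings, though
  yearly means are insensitive at realistic event volumes.
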