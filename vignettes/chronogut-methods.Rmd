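---
title: "Social jetlag, diet and the gut microbiome: methods and design"
author: "chronogut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social jetlag, diet and the gut microbiome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronogut)
```

## The scientific problem

Social jetlag (SJL) is the chronic misalignment between a person's
endogenous circadian phase and the sleep schedule imposed by the working
week, quantified as the difference between the mid-sleep point on weekend
and weekday nights. Even modest SJL has been linked to poorer diet
quality, low-grade inflammation and metabolic disturbance. `chronogut`
implements an end-to-end analysis connecting SJL to the gut microbiome in
a deeply phenotyped cohort of the PREDICT 1 type: questionnaire sleep
times, time-stamped meal logs, food-frequency (FFQ) intakes, continuous
glucose monitoring (CGM), postprandial blood series and a species-level
relative-abundance table from stool metagenomics.

Because the real cohort data are access-restricted, the package ships a
synthetic-cohort generator with planted, recoverable effects; every
analysis stage is tested against that ground truth.

## Sleep metrics

For each day type, the mid-sleep point is the clock time halfway between
bed and wake times, with wake times at or before bed times advanced by
24 h. SJL is the weekend-minus-weekday mid-sleep difference on the
circular clock, representative chosen in (−12, +12] h; a participant is
classified as having SJL when the difference is **≥ 1.5 h** (inclusive
boundary). Chronotype is proxied by the weekend mid-sleep time; habitual
sleep duration is the unweighted mean of weekday and weekend time in bed
(the questionnaire has no latency information, so duration means time in
bed), categorised as short (< 7 h), average (7–9 h, both ends inclusive)
or long (> 9 h).

Records are excluded, in order, when (1) any time is missing, (2) sleep
onset falls in `[08:00, 17:00)` — the half-open interval is our
deterministic reading of "between 8 am and 5 pm", (3) sleep offset falls
after 12:00 noon on the 24 h clock (we read "12 pm" as noon; wake times
past midnight map below noon and are retained), (4) time in bed is < 2 h
or > 15 h, or (5) SJL is negative (weekday mid-sleep later than weekend),
which is excluded rather than truncated. Clock times are held as integer
minutes from midnight and differenced on an unwrapped axis, so all derived
quantities are invariant to 24 h shifts and free of float drift.

```{r}
q <- data.frame(participant_id = "p1", bed_week = "23:30",
                wake_week = "07:30", bed_weekend = "01:00",
                wake_weekend = "09:30")
deriveSleep(q)$derived[, c("sjl", "sjl_flag", "chronotype", "habitual_h")]
```

## Eating occasions and diet features

Meal-log events within one participant-day are chained into an eating
occasion (EO) whenever consecutive events are less than 30 min apart; a
gap of 30 min or more starts a new occasion. The ≥ 50 kcal floor applies
to the *merged* occasion (sub-threshold events inside a chain still
contribute energy; isolated sub-threshold events are dropped) — the
study's wording defines the threshold on the occasion, not the event, and
we flag this reading explicitly. Occasions at or above 400 kcal (females)
or 500 kcal (males) are main meals; the rest are snacks. First/last EO
times use occasion *start* times (a logging convention the source is
silent on). The eating window is last minus first EO, the fasting window
its 24 h complement — taken as the complement because a literal
"difference between last and first occasion" would make fasting identical
to eating. Days outside 500–5000 kcal (females) / 500–8000 kcal (males)
are discarded; surviving days are averaged per participant, clock-time
features on an unwrapped axis so a 23:30/00:30 midpoint pair averages to
midnight.

FFQ records are screened by the ratio of reported energy to
Harris–Benedict basal metabolic rate (original 1919 coefficients),
excluding ratios outside [0.52, 2.58] or records with more than ten
unanswered items. The plant-based diet index family (PDI, hPDI, uPDI) is
scored from cohort quintiles of each food group (ties get the average
rank, floored to a quintile — deterministic and order-independent):
plant groups ascending and animal groups descending for PDI; healthy
plant ascending and all else descending for hPDI; less-healthy plant
ascending and all else descending for uPDI. HEI and aMED are not
implemented: their operational definitions live in external dietary
software, while the PDI family is fully specifiable from the group map.

## Metabolic markers

Postprandial series are sampled at 0, 15, 30, 60, 120, 180, 240, 270,
300 and 360 min. The incremental area under the curve (iAUC) is the
baseline-subtracted trapezoidal area; the default `positive_only` mode
(Wolever-style) clamps sub-baseline segments to zero with
linearly-interpolated baseline crossings, because the cited trapezoidal
convention leaves sub-baseline handling open; signed `net` areas are
available by flag. GlycA's 6 h rise is the 6 h value minus fasting, signed.
CGM readings within 12 h of device fit are discarded (sensor
calibration); over retained readings CV = 100·SD/mean (sample SD, the
CGM-field convention) and time in range is the percentage inside the
closed interval [3.9, 5.6] mmol/L.

## Differential-abundance screen

Species prevalent (relative abundance strictly > 0 — abundance tables
encode absence as exact zeros, so no epsilon) in at least 20 % of *both*
groups are tested with a two-sided Mann–Whitney U test per species; exact
p-values for combined n ≤ 20 without ties, otherwise the normal
approximation with tie and continuity correction. Benjamini–Hochberg
q-values are computed across the retained species only (filter first,
then test). Cohen's d uses pooled SD on arcsine-square-root transformed
abundances — the transform the mediation stage applies — with a raw-scale
option, since the d scale is not pinned down by the source analysis.
A species is significant when q < 0.2 **and** |d| > 0.2. A complementary
screen reports species prevalent (≥ 20 %) in exactly one group, ranked by
absolute prevalence difference. Whole-microbiome discrimination follows
the 100-iteration 80/20 stratified bootstrap with a random-forest
classifier (`ranger`, probability forests), summarised by the median test
AUC computed from the rank formula. Age-confounding is addressed by
composing `matchByAge()` (greedy seeded nearest-neighbour matching inside
the overlapping age range, optional caliper) with a re-screen.

## Mediation

The mediated effect of SJL on a species runs through a diet variable
(e.g. nut intake or hPDI). Two linear models are fitted — mediator
`M ~ X + covariates` and outcome `Y ~ X + M + covariates`, each with a
family random intercept via `lme4` when clustering is supplied (random
intercept only: family relatedness is an adjustment, not a slope
structure) — and effects follow the product-of-coefficients decomposition
without exposure–mediator interaction (the source reports single
proportions, implying this decomposition): ACME = a·b, ADE = c′,
total = c′ + a·b, so ACME + ADE ≡ total at the point estimates.
Inference is quasi-Bayesian with 1000 draws by default (the cited
mediation framework's default; fast and smooth), drawing coefficient
vectors from their asymptotic joint normals; percentile intervals,
tail-probability p-values. The proportion mediated is the median of
a·b/(c′ + a·b) over draws, reported as a percentage, retained (flagged,
not truncated) outside [0, 1], and flagged `unstable_proportion` whenever
the total-effect interval covers zero. Categorical covariates enter
treatment-coded with first-level reference.

```{r}
set.seed(1)
n <- 600
x <- rbinom(n, 1, 0.3)
m <- 0.5 * x + rnorm(n)
y <- 0.8 * x + 0.4 * m + rnorm(n)
fitMediation(data.frame(x, m, y), "x", "m", "y", nSims = 500, seed = 1)
```

## Covariate-adjusted comparisons

Group differences in continuous outcomes use linear models
`outcome ~ group + sex + age + BMI + ethnicity + education`. Normality is
checked on the *raw* outcome with Shapiro–Wilk (the stated procedure
tests the data, not residuals; a residual-based option exists); when
p < 0.05 the log (positive data) and sqrt (non-negative data) candidates
are tried and the larger W wins. BH correction is applied per outcome
family (e.g. the fasting-biomarker panel), with the family boundaries
configurable since shared q-values across printed rows only imply
per-block families. Family relatedness can be absorbed through
cluster-robust standard errors on the family ID. Interaction models add
`group × moderator` with simple-effects contrasts via `emmeans`
(continuous moderators evaluated at mean ± 1 SD). Partial correlations
use double residualisation with t-based p-values on n − k − 2 degrees of
freedom. Contingency tests are Pearson chi-square without Yates
correction by default (the source is silent; a flag enables it).

## The synthetic cohort: what it emulates, and what it does not

Defaults reproduce the published cohort structure: n = 934, SJL
prevalence 16 %, an SJL group 8.4 y younger and more male (39 % vs 25 %),
weekday/weekend time in bed near 8.1/8.7 h, and SJL food-group shifts
(nuts −3.5, fruits −36, sugar-sweetened beverages +25.2, potatoes +5.3,
fish +7.2 g/day). SJL status is assigned first; bed/wake times are then
sampled (truncated normals, minute resolution) with the SJL magnitude
kept ≥ 0.05 h away from the 1.5 h boundary so that minute rounding cannot
flip the class — re-deriving SJL from the questionnaire recovers the
assignment essentially always. Where the source prints no value (e.g.
within-group food-group SDs beyond those published, PSQI distribution,
CGM noise), defaults are plausible field values chosen once and
documented here, not claims about the study.

Abundances follow the stated recipe: log-normal species masses closed to
sum 1, zeros from per-species Bernoulli detection (most species 35–95 %
prevalent, four planted below the 20 % filter, three prevalent in the
no-SJL group only). Direct-effect species receive a group shift of
`effect_size_d` (default 0.8) standard deviations *on the observed
arcsine-square-root scale*: detection zeros dilute a latent shift and
inflate the observed SD, so the latent shift is scaled by
sd_obs/π with sd_obs² = π(s² + (1−π)μ²) — this is what makes
`effect_size_d` interpretable by the screen. Mediated species depend on
SJL through nut intake plus a direct path sized so the proportion
mediated equals `mediated_fraction` (default 0.15): with nut shift a and
chosen b, c′ = a·b(1−f)/f. Planted and structural roles are restricted to
sub-dominant taxa (mean relative abundance ≤ 2 %) — realistic, since
differentially abundant species in such screens are rare taxa, and it
keeps compositional closure from leaking planted shifts into null
species. A configurable fraction of participants (default 40 %) form
two-member families sharing a random intercept on the transformed
abundance scale, exercising the mediation models' cluster structure.

Not emulated: metagenomic reads or taxonomic profiling, FFQ item-level
structure, twin heritability (family members share only the abundance
intercept, not age or diet), seasonal or weekday/weekend eating
differences, CGM sensor artefacts. Passing tests therefore demonstrate
that the statistical machinery recovers known effects under the stated
generative assumptions — not that those assumptions describe real
cohorts.

## Numerical and testing choices

All randomness flows from explicit integer seeds through isolated RNG
streams, so package calls never disturb the caller's `.Random.seed` and
identical seeds give byte-identical cohorts and pipeline reports. Test
problem sizes were chosen to make each check sharp but quick: the
segmentation suite compares against an exhaustive partition oracle on 500
random event streams of up to 12 events; small-sample Mann–Whitney
p-values are checked against full permutation enumeration for group sizes
≤ 5; the permuted-label null uses 200 permutations of a 200-sample,
50-species table; mediation recovery uses 50 replicate cohorts at n = 900
with 500 quasi-Bayesian draws each; planted-effect detection pools three
n = 934 cohorts. Degenerate inputs (empty eating days, all-discarded CGM
traces, constant outcomes, singular fits, one-level moderators,
zero-margin tables) raise named errors or flagged missing values rather
than silent numbers.

## Known limitations

The pipeline consumes a relative-abundance table; compositional
log-ratio alternatives (ALDEx2/ANCOM-style) are deliberately out of
scope, as the analysis is rank-based. HOMA-IR is consumed as a provided
column, not computed, because its inputs and formula variant are not
specified by the source analysis. The greedy age-matching is 1:1 without
replacement and order-dependent (seeded); it is not an optimal-matching
algorithm. The proportion mediated is unstable by construction when the
total effect is near zero; interpret it only alongside its flag and the
ACME interval.
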