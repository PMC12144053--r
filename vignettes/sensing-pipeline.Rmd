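---
title: "From app-foreground logs to social-media phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From app-foreground logs to social-media phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smsense turns raw smartphone mobile-sensing logs into analyzable
social-media usage phenotypes for adolescent cohorts. This vignette is the
package's account of the science: the measurement model, the rules that make
missingness explicit, the statistics, the synthetic cohort the tests run on,
and the design decisions that were genuinely open.

## The measurement problem

An Android sensing app (AWARE-style) logs an *applications foreground* event
each time an app comes to the front — one row per launch, with participant,
instant, and package name. It also logs other sensors (screen state,
accelerometer, and so on) as timestamped rows. Three things make these logs
hard to analyze naively:

1. **Launches have no paired "stop" record.** Usage *episodes* must be
   reconstructed from the launch stream plus screen events, under explicit
   termination rules.
2. **Absence of data is ambiguous.** An hour with zero recorded use is
   either a true zero (the teen did not open social media) or a sensing
   failure (the app was killed, battery saver, a crash). Treating the two
   alike biases every downstream statistic.
3. **"Social media" is not one set of apps.** Store-assigned genres,
   research-coded definitions, and survey-defined popular-app lists select
   different app sets and therefore different usage totals.

## Episode reconstruction

`build_episodes()` opens an episode at each foreground event and closes it
at the earliest of:

* the participant's **next foreground event** (one app in the foreground at
  a time — this also guarantees episodes never overlap within participant);
* the next **screen off or lock** event (`unlock` does not reopen the prior
  app — the conservative choice);
* launch + **cap** (`episode_cap_minutes`, default 120).

The cap exists because a final unterminated launch (screen left on, missing
screen rows) would otherwise fabricate multi-hour usage. How the upstream
sensing stack actually terminates foreground episodes is not publicly
documented; these rules are explicit stand-ins, and every one of them is a
named, tested behavior rather than an incidental implementation detail.

Consecutive launches of the *same* package with no intervening screen-off
merge into one episode for **duration**, but each launch still increments
the **checking** count: re-tapping an app you are already using does not
restart usage time, yet it is a check. This is also why the pipeline carries
duration (from episodes) and checking frequency (from events) as separate
features throughout. All intervals are half-open `[start, end)` in epoch
milliseconds, which makes durations exactly additive across bin boundaries —
the hourly apportionment of a boundary-spanning episode is computed by exact
interval intersection, and a per-second brute-force accumulator reproduces
it to numerical precision in the test suite.

## Valid minutes, data yield, and the zero-versus-NA rule

A **valid minute** is a clock-aligned minute window (hh:mm:00–hh:mm:59,
local civil time) containing at least one row from *any* sensor — evidence
the sensing app was alive. The **data yield ratio** of a bin is valid
minutes over bin length; it is a compliance/feasibility metric, not a usage
metric. Because foreground data are event-driven, no per-sensor yield is
meaningful: a silent hour is indistinguishable from an unused phone using
the foreground stream alone, which is exactly why auxiliary sensor rows are
pooled.

The three-valued hour status (`apply_valid_hour_rule()`):

* usage captured in the hour → **observed**, at face value (captured data
  are real regardless of yield);
* no usage and ≥ 30 valid minutes → **zero_filled** (a trusted zero);
* no usage and < 30 valid minutes → **missing** (NA).

The 30-minute (50%) threshold is a researcher-set dial; any choice
introduces some bias, so it is exposed (`valid_hour_min_minutes`) rather
than hard-coded, and the exhaustive 61 × 2 sweep of the rule is part of the
acceptance suite. The day-level analogue (`day_max_missing_hours`, default
12 of 24) excludes days with worse than 50% hour coverage from statistics;
hours outside the enrollment window on partial first/last days count as
missing for this purpose.

Two study-level yield aggregates are reported side by side, because with
unequal enrollment they differ and the convention used by any given paper
is often unstated: the pooled hour-weighted ratio and the mean of
per-participant ratios.

## Category schemes and the app key

The packaged key (`load_key()`) covers 44 apps with four membership flags:

* **sns** — research-coded narrow "social networking" (20 apps);
* **broad** — research-coded broad social media (41 apps; sns ⊆ broad and
  popular ⊆ broad are enforced invariants);
* **google_play** — Play-Store-assigned "Social" genre (26 apps;
  independent of the research coding — it omits YouTube, and a few apps are
  Play-Store-only, e.g. Airtime, BAND, Houseparty);
* **popular** — the survey-defined popular list (9 apps).

Matching is exact and case-sensitive on package names. Category features
are computed by summing member-app features (episodes cannot overlap, so
summation cannot double count), which enforces the nesting invariants by
construction. App catalogs drift as platforms evolve; the key file carries
a schema-version comment and `validate_key()` supports re-categorization
maintenance without touching code.

Multi-coder categorization agreement uses Fleiss' kappa for three or more
raters (pooled-marginal expected agreement) and Cohen's kappa for exactly
two (own-marginal expected agreement); the two formulas are documented
separately because they estimate chance differently. When every cell holds
one identical label, expected agreement is 1 and the ratio is 0/0; the
implementation returns 1 by convention (perfect agreement was observed).

## Statistics

* `summarize_usage()` reports mean/SD/min/max/n at three grains:
  between-person (per-participant means of daily values), daily
  (person-days), and hourly (all non-missing cells, zeros included — the
  hourly grain takes no account of sleep, which is flagged as a caveat
  rather than filtered).
* `icc_between_fraction()` is the one-way random-effects ANOVA estimator:
  within = MSW, between = (MSB − MSW)/k̄ with the unbalanced correction
  k̄ = (N − Σnᵢ²/N)/(k − 1), negative between truncated to 0 (the standard
  convention). The between fraction is ICC(1): the share of variance in a
  repeated daily measure due to stable participant differences.
* `rm_correlation()` is the repeated-measures correlation: center both
  variables within participant, correlate the centered values,
  df = N − k − 1, p from the t transform. It is algebraically the ANCOVA
  common-slope formulation and invariant to per-participant offsets; the
  tests verify both properties against an independent `lm()`/`anova()`
  route. Participants with fewer than two complete pairs are dropped before
  counting N and k.
* `duration_checks_correlation()` applies the same engine to daily duration
  versus daily checks.

Excluded days are dropped listwise per analysis. No multiple-testing
control is applied: the package reports descriptive surfaces, not a
hypothesis family.

## The synthetic cohort generator

Real adolescent sensing data cannot be redistributed, so every stage is
validated against `generate_cohort()`, which emits AWARE-like logs with
known ground truth: foreground launches, a screen-off row closing each
session, auxiliary sensor rows on a per-minute lattice (with sub-minute
jitter, so with no outage every enrolled minute is valid by construction),
and a truth object holding person means, per-day targets and realized
totals, app repertoires, and the outage schedule.

Model, per participant *i* and day *d*:

* person means: gamma draws (right-skewed, positive), moment-matched to
  (`mean_daily_minutes`, `between_sd`), then affine-standardized so the
  *realized* cohort carries exactly the configured person-level mean and SD.
  The standardization is deliberate: at 19–40 participants the sampling
  luck of the person draw otherwise dominates variance-fraction recovery,
  and ground-truth tests should measure pipeline fidelity, not draw luck;
* day targets: normal around the person mean with `within_sd`, truncated at
  0; duration and checking deviations share a bivariate-normal coupling
  (`duration_check_cor`);
* sessions: `target_checks` log-normal lengths (truncated at
  `session_cap`), rescaled to the day's duration target, with start hours
  sampled from the 24-point `diurnal_profile` and laid out left-to-right so
  sessions never overlap; sessions crossing midnight are truncated at the
  day boundary;
* apps: each participant holds a repertoire (mean ~8 apps, SD ~3) sampled
  with inclusion biased by `app_weights`; launches are multinomial over it;
* outages: a Poisson number of log-normal-length windows per participant;
  during an outage *no* rows of any kind are emitted — real usage in an
  outage is unobserved, exactly the ambiguity the valid-hour rule exists
  for;
* reproducibility: one root seed drives person-level draws; per-participant
  child streams make generation order-independent across participants.

### Calibration: latent process versus observed cohort

The published quantities this generator emulates are *observed* ones —
computed after sensing outages and the valid-hour rule have taken their
toll. Passing the latent process through the default outage schedule
removes roughly 20% of usage, adds day-level observation noise of ~30
min/day, and attenuates within-person correlations. The defaults are
therefore deconvolved: latent duration mean 115 min/day (between-SD 72,
within-SD 38), latent checking mean 220/day (between-SD 168, within-SD 55),
latent coupling 0.65, outage rate 1.25/day with log-normal lengths
(meanlog log 240, sdlog 1). Under the default 19 × 31 design this yields an
observed cohort with ~74% pooled data yield, observed broad-category daily
duration near 95 min/day with between-person SD around 60, observed daily
checking near 160–180, observed duration–checking within-person correlation
near 0.5, and between-person variance fractions around 0.55–0.65 for
duration and 0.6–0.75 for checking — the regime reported for one-month
adolescent cohorts of this size. Checking-frequency retention is harsher
than duration retention because a launch whose hour is missing disappears
entirely, while an episode's duration may still be partially observed in an
adjacent hour.

What the generator does **not** emulate: app content and notifications,
weekday/weekend structure, school-calendar effects, within-session pause
behavior, device sharing, network effects between participants, or any
mental-health outcome process. Passing tests therefore demonstrate that the
pipeline measures what the generative model emits — including its
missingness mechanism — not that real adolescent data obey this model.

## Numerical choices and degenerate inputs

* Instants are numeric epoch milliseconds throughout; minute and hour
  windows are clock-aligned in local civil time. Minute→hour assignment
  uses the UTC offset at the containing UTC hour's start (IANA offsets are
  whole minutes; zones transitioning on the half-hour inside an hour are
  the one known approximation).
* Defaults generate in a DST-free zone so binning ground truth is exact;
  wall-clock parsing near DST transitions is handled in ingest (fold →
  earlier UTC offset; gap → adjacent valid time) and tested separately.
* Duplicate sensor rows are dropped with a logged count; zero-length
  episodes are dropped from the episode table but their launches still
  count.
* A launch is counted in the hour containing its start instant only
  (opening an app is instantaneous); whether an upstream pipeline would
  count a boundary-spanning session in both bins is unstated, so the
  start-bin convention is documented rather than assumed universal.
* Negative between-variance estimates truncate to 0; degenerate kappa
  (expected agreement 1) returns 1; `rm_correlation()` errors when no
  participant carries within-person variance.
* Test and acceptance problem sizes: property suites run on cohorts of
  4–19 participants × 5–31 days; parameter recovery uses 40 × 200
  (configured between-fraction exactly 0.600, SD magnitudes chosen so the
  truncation mass of the normal day-target model is negligible and the
  normal-theory fraction formula applies); the brute-force oracle runs on
  1000 random small episode sets.

## Known limitations

* Episode termination rules are modeling conventions, not recovered ground
  truth about the sensing stack; changing the cap or the lock/off handling
  changes duration features.
* The valid-hour rule cannot distinguish "phone off by choice" from
  "sensing failed"; both read as low yield. Any threshold biases zeros.
* iOS devices cannot contribute foreground data at all; the pipeline is
  Android-shaped by necessity.
* Category keys age quickly; the packaged key reflects a 2020 cohort and
  should be re-validated before reuse (`validate_key()`).
* The hourly grain includes sleep hours; interpret hourly means
  accordingly.
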