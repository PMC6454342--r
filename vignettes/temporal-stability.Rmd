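---
title: "Daily smartphone-use parameters and their temporal stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily smartphone-use parameters and their temporal stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenuse)
```

`screenuse` quantifies a person's smartphone use from the only signal a
passive logger reliably records — timestamped `screen_on`, `screen_off`
and `notification` events — and asks two reliability questions of the
resulting daily parameters: how short a block of data still represents a
two-month pattern (the *fundamental time unit*), and how far apart two
use periods can lie before they stop resembling each other (the
*independent cycle*). This vignette explains the underlying model, every
tunable choice and its default, what the synthetic cohort generator does
and does not emulate, and the package's known limitations.

## From events to episodes

A *use episode* runs from a `screen_on` to the next `screen_off` of the
same user. Real device logs are imperfect, so `pair_screen_events()`
resolves anomalies deterministically and counts each kind in a QC table
rather than dropping anything silently:

* a second `screen_on` before any `screen_off` supersedes the first
  (duplicate wake events behave this way on devices);
* an orphan `screen_off` is dropped;
* zero-length intervals are dropped.

An episode is *proactive* (self-initiated) when no notification arrived
in the `proactive_window` seconds before screen-on, and *reactive*
otherwise. The window defaults to 60 s and is half-open,
`[start - 60, start)`: a notification exactly 60 s before screen-on
counts, one exactly at screen-on does not (the screen is already turning
on). Enlarging the window is monotone — it can only turn proactive
episodes reactive. Only wall-clock time matters: a notification that
arrived while the screen was still on in a previous episode still
silences the "proactive" label of the next one if it falls inside its
window. Whether a logger should instead ignore notifications delivered
to an already-lit screen is unobservable from events alone; the
wall-clock rule is the reproducible choice.

Days are bounded by *local midnight* in the configured timezone
(`study_config(tz = )`; timestamps themselves always carry explicit UTC
offsets). A use episode crossing midnight is split, each piece counting
in its own day and inheriting the proactive flag; this keeps every daily
duration bounded by 86,400 s. Gaps between uses — including the gap from
midnight to the first use and from the last use to the next midnight —
become *nonuse* episodes, so each day is a strictly alternating
use/nonuse sequence covering the full day. Each user's first and last
calendar day are dropped by default (`exclude_first_last_day = TRUE`)
because real recordings begin and end mid-day; for synthetic cohorts,
whose days are complete by construction, the analyses in this package's
examples and tests turn the exclusion off.

### Sleep

Sleeping time must not count as voluntary nonuse, so it is flagged
before the reciprocity statistics are computed. The logger records no
sleep, so a policy has to infer it — the largest single assumption in
the pipeline, and deliberately configurable (`sleep_policy()`):

* `longest_overnight_gap` (default): per day, the nonuse episode with
  the largest overlap with a night window (21:00–11:00) is flagged
  whole, provided it lasts at least `min_hours = 4` h. Selecting by
  *overlap* rather than raw length prevents a long midday gap from
  masquerading as sleep. Because days are split at midnight, the short
  pre-midnight tail of an overnight gap stays unflagged; it only ever
  appears as the last episode of a day, where it cannot enter SI or CI
  triplets, so the effect is confined to a mild RMSSD contribution.
* `fixed_window(start, end)`: everything inside a clock window is sleep;
  partially overlapping nonuse episodes are split so exactly the inside
  part is flagged.
* `none`: for data already cleaned upstream.

After flagging, the reciprocity statistics drop the flagged episodes.
`sleep_bridge = "adjacent"` (default) concatenates the remainder into
one sequence — the removed gap's neighbours become adjacent —
while `"segment"` refuses to difference or pair across the removal and
pools numerators and denominators over the day's segments. The two
agree whenever sleep sits at the edge of the day, which is the typical
case; both are kept because neither convention is derivable from the
parameter definitions alone.

## The seven daily parameters

For each user-day: `F` (number of use episodes), `D` (summed use
duration, s), and `PF`/`PD`, the same restricted to proactive episodes.
Three statistics then describe the *reciprocity* of use and nonuse, all
in seconds, all computed on the sleep-excluded alternating durations
`A_1..A_n`:

* **RMSSD** `= sqrt( sum_{i<n} (A_{i+1} - A_i)^2 / (n-1) )`. Low values
  mean adjacent use and nonuse episodes are similar in length.
  Undefined when fewer than two episodes remain.
* **Similarity Index.** Each nonuse episode `X_i` is compared with its
  `lookahead_k = 3` following use episodes; SI is the mean of the 3k
  absolute differences. A nonuse episode with fewer than 3 following
  uses in the day is skipped entirely — no partial triplets — which
  keeps SI and CI on the same support. The alternative denominator
  (mean of per-episode means, `si_denominator = "triplet_means"`)
  coincides with the default whenever every eligible episode
  contributes a full triplet, which is always the case at `k = 3`
  with full triplets required; the switch exists for generalized `k`.
* **Control Index.** As SI, but each `X_i` is compared with the *sum*
  of its 3 following uses: `CI = mean |X_i - (Y_i + Y_{i+1} + Y_{i+2})|`.
  A low CI means nonuse pauses match the amount of use that follows
  them — an index of use-control ability.

Degenerate days yield `NA`, never zero: a zero would fake perfect
reciprocity and poison period means. Period summaries
(`summarize_period()`) average each parameter over the days where it is
defined and record the contributing-day count.

Useful invariants (all tested): `PF <= F`, `PD <= D`; multiplying all
durations by `c > 0` scales RMSSD, SI and CI by `c`; adding a constant
to all durations leaves RMSSD unchanged but not SI or CI.

## The stability analyses

Both analyses start from per-user means of daily parameters over blocks
of whole weeks, with week 1 anchored at each user's first recorded day.

**Fundamental time unit** (`unit_vs_total()`): for block lengths 1, 2
and 4 weeks, the grid-aligned, non-overlapping blocks of an 8-week
record (8, 4 and 2 of them) are each correlated across users with the
8-week mean, parameter by parameter. A correlation at or above
`high_corr_threshold = 0.75` counts as "high". The block is part of the
reference mean, as in the original design of this analysis;
`leave_block_out = TRUE` provides the stricter variant. With the block
equal to the whole record the correlation is identically 1 — a useful
self-check, not a finding.

**Independent cycle** (`independent_cycle()`): for 1- or 2-week periods,
all ordered pairs of non-overlapping blocks at *sliding* weekly offsets
whose gap is exactly TI weeks are correlated across users, and the pair
correlations are averaged into one reliability index per TI. For 1-week
periods in 8 weeks this gives 7, 6, …, 1 pairs for TI = 0..6. The two
analyses intentionally use different block designs (grid-aligned versus
sliding); the sliding design is what makes "7 correlations averaged at
TI = 0" come out. For 2-week periods the grid-aligned subset can be
requested with `ti = c(0, 2, 4)`.

Correlations are Pearson r with unadjusted two-sided p-values (the
analysis is exploratory; no multiplicity correction — a deliberate
limitation, not an oversight). Any cell with fewer than 3 users or zero
variance is reported `NA`, never coerced; users with undefined parameter
means drop out of that cell only, with counts retained.

## The synthetic cohort generator

Real cohorts of this kind are privacy-restricted, so
`generate_cohort()` produces event streams with the structure the
analyses assume. Defaults describe a deliberately heavy-using cohort of
33 users over 8 weeks, calibrated to the published summary statistics
shipped in `reference_cohort_stats()`:

| trait | distribution | default |
|---|---|---|
| episodes/day | log-normal, moment-matched | mean 57.29, SD 22.96 |
| mean episode duration | log-normal, moment-matched | mean 360.7 s (=> ~5.7 h/day), CV 0.5 |
| within-day durations | log-normal | sigma 1.0 |
| proactive probability | clipped normal | 0.401 (SD 0.14) |
| proactive/overall duration ratio | log-normal | 0.58 (sigma 0.45) |
| sleep window | clipped normals | ~23:12 to ~07:30 |
| weekend multiplier | clipped normal | 1.1 (SD 0.15), week-normalized |
| weekly drift | log-scale random walk | SD 0.05/week |

Two of these deserve comment. The *proactive-duration ratio* below 1
makes proactive episodes shorter than reactive ones, so that proactive
use is ~40% of episodes but only ~23% of use time, as the reference
table implies; reactive durations are lengthened correspondingly so the
overall mean is preserved. The *drift* is a multiplicative random walk
on each user's weekly episode rate — the single knob that makes
between-period correlations decay with the time interval; 0.05/week
produces the mild decay typical of such cohorts, 0 gives perfectly
stable traits, and larger values erode reliability monotonically (a
tested property).

Counts are Poisson per day; episodes are placed in the waking span with
at-least-1-second random gaps (Dirichlet-distributed remainder). Days
whose sampled durations cannot fit the waking span are re-drawn up to
100 times, then scaled down with a warning — under strong drift this
truncates the heaviest days. Each reactive episode receives exactly one
notification placed inside its own pre-onset window but outside every
proactive episode's window (it suffices to stay clear of the two nearest
proactive neighbours); when episodes are so crammed that no such instant
exists, the episode is relabelled proactive. The 60-s classifier
therefore recovers the generator's labels *exactly* — a closed loop the
tests assert at 100%.

The addiction construct is a standard-normal latent tied by a Gaussian
copula to the user's *proactive-use-duration propensity* — the
standardized log of (rate x proactive probability x mean duration x
duration ratio), i.e. the log of the user's expected daily PD. The
copula correlation defaults to 0.4. Tying the latent to the composite
rather than to any single factor is what lets the observable r(PD,
SPAI-5) land in the intended neighbourhood: the log-normal shape of PD
and the questionnaire discretization (affine map to mean 12.55, SD 2.41,
rounded and clipped to 5–20) attenuate the copula's 0.4 to roughly
0.3–0.45 in large cohorts. SPAI-5 items are a flat decomposition of the
total; item-level structure is not modelled.

What the generator does **not** emulate: within-day circadian structure
beyond the sleep window, app-level content, missing days or compliance
lapses, autocorrelated day-to-day noise, and the extreme dispersion of
real proactive-duration distributions (the reference table's PD SD
exceeds its mean; the defaults approximate but do not reproduce that
tail — matching it is left to the configurable duration sigmas). Its
gaps are also smoother than real human pacing, so the reciprocity
statistics run lower than the published cohort means. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* computes its
definitions correctly and that the *analyses* recover known generating
structure — not that real data would show the same stability profile.

## Numerical and design notes

* Problem sizes: the test suite's Monte-Carlo properties use 100-user,
  8-week cohorts with 20 replicates per drift condition, and a single
  500-user cohort for the addiction-correlation recovery — sizes at
  which sampling error is small relative to the tested margins while a
  full run stays comfortably interactive.
* Timestamps are kept at millisecond resolution throughout (whole-second
  rounding would create spurious zero-length episodes in dense streams);
  interval arithmetic uses half-open `[start, end)` everywhere, so an
  episode ending exactly at midnight belongs to the earlier day.
* Ties in event logs (identical timestamps) keep input order via stable
  sorts — identical input bytes always produce identical results.
* Undefined statistics serialize as empty CSV cells and read back as
  `NA`; no sentinel numbers anywhere.
* The day-sequence alternation invariant after `fixed_window` splitting
  is "no two use episodes adjacent"; nonuse may appear as consecutive
  pieces with different sleep flags.

## Limitations

Screen-on/off pairs cannot see what the phone is used for, nor
distinguish engaged use from an idle lit screen. Sleep is inferred, not
measured. Different behaviour patterns can produce identical reciprocity
values (frequent even short bouts versus sparse sporadic checking). And
the stability criteria (r >= .75, and .90 for 4-week blocks) are
conventions inherited from the reliability literature, not optimized
thresholds.
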