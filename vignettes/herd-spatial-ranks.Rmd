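---
title: "Spatial proximity ranks in a GPS-collared herd: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial proximity ranks in a GPS-collared herd: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdrank)
```

## The model

The package analyses the spatial organisation of a herd from virtual-fence
collar logs. The underlying behavioural question is whether a herd keeps a
stable internal geometry — a few animals persistently central, others
persistently peripheral — which would justify collaring only the central
("leading") individuals.

The measurement chain is deliberately nonparametric, because collar data are
lossy and serially dependent:

1. Positions are aligned to a common grid of 96 quarter-hour UTC intervals
   per day, since collars poll asynchronously. Intervals are half-open
   `[t, t + 15 min)`; a fix on a boundary belongs to the later interval.
   Multiple fixes by one cow in an interval (polls pooled with warning and
   zap messages, which also carry positions) reduce to the coordinate-wise
   median; medians are order-free, so pooling order is irrelevant.
2. For each interval, all pairwise great-circle distances are computed and
   each cow is scored by the **median of its distances to all herdmates** —
   a proximity-centrality score, robust to a single far-flung neighbour.
3. Scores are ranked ascending within the interval (rank 1 = most central).
   Exact ties get midranks, which preserves the rank-sum invariant
   Σr = n(n+1)/2 that several downstream statistics rely on.
4. A cow's ranks within a day collapse to the **daily median rank**, and
   daily medians accumulate into the **cumulative rank curve**. The final
   cumulative value orders the herd: persistent centrality accumulates
   slowly.

Day-to-day stability of the ranking is quantified by Kendall's coefficient
of concordance, with days as raters and cows as items,

$$W = \frac{12\,\sum_i (R_i - m(n+1)/2)^2}{m^2(n^3-n) - m\sum_j T_j},$$

where $R_i$ is cow $i$'s rank-sum over the $m$ days and $T_j$ the tie term
of day $j$. Daily median ranks are half-integers, not rankings, so each
day's vector is **re-ranked to midranks before computing W**; without this
step the tie-corrected formula is not defined on its intended scale. Both
the tie-corrected and uncorrected variants are reported
(`concordance.json`), since either convention is found in practice.
Significance uses $\chi^2 = m(n-1)W$ on $n-1$ degrees of freedom. Under
independent days, $E[W] \approx 1/m$ — a useful calibration target that the
test suite verifies by simulation at m = 45, n = 17.

Distributional shape per cow is summarised by moment skewness and
**non-excess kurtosis** ($m_4/m_2^2$, normal = 3). The n-normalised moment
convention is pinned deliberately: many libraries default to excess kurtosis
or bias-corrected estimators, which would shift every value by a constant
and break comparability with the conventional ±0.5 / ±1 skewness reading
thresholds. Bias-corrected variants are available behind a flag.

## The GPS-accuracy null

Collar GNSS fixes are accurate to roughly 3.5–10 m. To check that observed
structure is not inaccuracy in disguise, the package implements a
distance-randomization null: within every interval the vector of per-cow
median distances is shuffled by a uniform permutation, destroying the
cow–distance association while preserving each interval's distance multiset
exactly, and the full downstream pipeline (ranks → daily medians →
cumulative curves → Mann–Whitney matrices) is re-run, by default over 10
seeded replicates. Because the permutation leaves each cow uniformly ranked,
null cumulative finals concentrate near m·median(1..n) (405 at 45 days ×
17 cows), with extremes over cows × replicates spanning roughly ±15 rank
units — far narrower than what genuinely structured data produce.

The randomization mechanism was a genuinely open design choice: "randomizing
distances" could equally mean perturbing positions. The permutation mode is
the default because it removes cow identity *exactly* without changing the
distance distribution; positional Gaussian jitter at collar accuracy
(`jitter_positions`) is provided as the physically motivated alternative.
Both are seeded. Mann–Whitney U tests use the exact distribution for
combined n ≤ 20 without ties and the tie- and continuity-corrected normal
approximation otherwise; p-value matrices are reported uncorrected (a Holm
column is optional) because the matrices are read as a pattern, not as
individual hypotheses.

## The synthetic herd generator

There is no public accession for the field data this kind of analysis is run
on, so the generator is a first-class module: every pipeline stage, and the
recovery claim itself, is validated against herds with known structure.

The herd centroid follows a correlated random walk — lognormal step lengths
(median ≈ 20 m per 15 min, a grazing pace), wrapped-normal turning angles
(sd 0.8 rad), and a mild (2 %/step) attraction to the paddock origin that
keeps 45-day tracks inside a paddock-scale range. Cow *i*'s displacement
from the centroid is AR(1) per axis with persistence φ (default 0.9 per
15-min step) and stationary standard deviation σᵢ. The σ vector **is** the
planted hierarchy: `planted_order()` returns cows by ascending σ, and the
default σ ∈ [10, 150] m in a ~160-ha paddock is a plausible spread for a
loosely cohesive beef herd (the real spread distribution is unpublished;
this default is a modelling choice, not a calibration). Collars poll at
per-cow phase offsets uniform on [0, 15) min, with isotropic GPS noise
(default sd 2.5 m per axis, consistent with a 3.5–10 m accuracy circle),
5 % dropout, optional whole-day outages (to exercise the day-exclusion
filter), and a 1 % rate of warning/zap messages as extra position sources.

What the generator does *not* emulate: behavioural responses to the virtual
border, spatially correlated GPS error (multipath, canopy), within-interval
movement between the grid point and the poll offset, and fission–fusion
subgrouping. Passing tests therefore demonstrate that the pipeline measures
what it claims on a cohesive single-group herd with independent noise — not
that any real herd is such a herd.

A robustness note discovered during development: GPS noise at collar
accuracy flips a non-trivial share of *interval-level* ranks (adjacent cows'
instantaneous median distances frequently sit within noise range of each
other), but the daily median aggregation absorbs almost all of it — under
default spreads, fewer than 1 in 100 cow-day median ranks move by more than
one rank even at 10 m noise. This is precisely why the method aggregates to
daily medians before any inference, and the synthetic tests assert the
daily-level property rather than an interval-level one.

## Numerical and policy choices

- **Distances**: haversine on a sphere of radius 6 371 008.8 m. At ≤ 2 km
  extents the spherical-vs-ellipsoidal error is sub-metre; the all-pairs
  matrix uses a vectorised implementation verified against
  `geosphere::distHaversine` to 10⁻⁹ m.
- **Medians of even counts**: mean of the two central order statistics,
  applied per coordinate.
- **Quartiles**: type-7 linear interpolation; Tukey 1.5·IQR fences select
  outliers but never truncate min/max.
- **KDE**: Gaussian kernel, Silverman bandwidth 0.9·min(sd, IQR/1.34)·n^(−1/5),
  512-point grid, 3-bandwidth cut — common defaults, all exposed, bandwidth
  echoed in the output for audit. The peak height is reported as
  density × 100 (percent scale). Grid values within a 10⁻⁹ relative band of
  the maximum count as tied and resolve to the lower rank, so exactly
  symmetric bimodal inputs behave deterministically.
- **Missing cows within a kept day**: default policy ranks among the cows
  present (`present-only`; ranks 1..n_present); `complete-only` instead
  drops any interval with an absence. Both are exposed because collars
  "lose signal for short periods" in real deployments and neither policy is
  canonically right: present-only keeps power, complete-only keeps rank
  scales strictly comparable.
- **Missing daily ranks in cumulative curves**: carry-forward (the curve
  does not advance; the gap is flagged) rather than imputation — fabricating
  ranks would distort the concordance input. For Kendall's W, where a
  complete matrix is required, `run_pipeline()` imputes the day's median
  rank for the missing cow and logs it prominently.
- **Parsing**: strict by default (any malformed row aborts with its line
  number); lenient mode drops, counts and reports rejected rows, preserving
  the records-in = kept + rejected accounting.
- **Seeding**: every stochastic entry point takes an explicit seed;
  replicate k of the null uses base_seed + k, recorded in the output, so any
  replicate can be regenerated in isolation.

## Problem sizes used in validation

The test suite validates at the reference design scale where the science
demands it — the null cumulative range and its calibration run at 17 cows ×
45 days × 96 intervals × 10 replicates, and hierarchy recovery at the full
45-day design (planted σ 10–150 m, φ = 0.9, recovered with Spearman ρ ≥ 0.9
between planted and cumulative-final order) — and at reduced scale (5–8
cows, a few days) for unit-level properties, where the invariants being
checked (rank-sum conservation, label invariance, idempotence, determinism)
are size-free.

## Known limitations

- Median-based centrality compresses the extremes: a cow must be
  persistently central across *most* intervals of *most* days to stand out,
  so short-lived leadership episodes are invisible by construction.
- Ranks are relative; a day on which the whole herd scatters looks identical
  to one where it bunches. Absolute spread is available in
  `median_distance_m` but is not used by the rank statistics.
- The concordance test treats days as exchangeable raters; serial
  correlation across days (likely in real herds) makes its p-value
  anti-conservative. The cumulative curve and the randomization contrast do
  not share this assumption.
- With `present-only` ranking, daily medians on days with many absences mix
  rank scales (1..n_present varies); the day-exclusion filter at the full
  herd size is the guard, and lowering it trades this bias for sample size.
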