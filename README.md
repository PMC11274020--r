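# herdrank

Spatial proximity ranks and concordance analysis for GPS-collared herds.

## The problem

Virtual-fence systems (such as Nofence©) keep livestock inside a GPS-defined
border with a collar per animal. Collars are expensive, so a recurring
question is whether a herd organises itself around a few leading individuals
— if it does, collaring only those animals might suffice. The collars
themselves produce the data to ask that question: every collar reports a
timestamped GPS position roughly every 15 minutes (plus border warnings and
electric-pulse "zap" events, which also carry positions).

`herdrank` turns those message logs into a spatial hierarchy analysis:

1. **Ingest** — parse the message log, map collar serials to animals
   (collars get swapped; one animal may own two serials in disjoint validity
   windows), bin positions into the 96 quarter-hour UTC intervals of each
   day (intervals are half-open, the first is 00:00–00:15), take per-cow
   coordinate-wise medians within an interval, and drop days on which fewer
   than the full herd registered.
2. **Ranking** — per interval, compute all pairwise great-circle distances
   (haversine, R = 6 371 008.8 m); each cow's proximity score is the
   *median* of its distances to all herdmates (16 distances in a 17-cow
   herd); rank scores ascending (rank 1 = most central, midranks on ties);
   collapse each cow's ranks to a *daily median rank*; accumulate daily
   medians into a *cumulative rank curve*, whose final value orders the herd
   along a rough cohesion hierarchy.
3. **Statistics** — Kendall's coefficient of concordance *W* across days
   (tie-corrected, with the χ² = m(n−1)W test), moment skewness and
   non-excess kurtosis (normal = 3) of each cow's daily ranks,
   Gaussian-KDE density peaks (Silverman bandwidth, peak height on the
   percent scale), Spearman correlations, and five-number boxplot
   summaries.
4. **Accuracy null** — the distance-randomization null: within every
   interval, shuffle which cow owns which median distance, re-run the whole
   downstream pipeline (10 replicates by default), and compare via
   cumulative-range overlap and pairwise Mann–Whitney U matrices. If the
   observed structure survives this contrast, GPS error is not driving it.
5. **Synthetic herds** — a correlated-random-walk herd simulator with a
   planted cohesion hierarchy (per-cow AR(1) spread σᵢ around the herd
   centroid), collar phase offsets, GPS noise, dropout and whole-day
   outages, emitting the exact log dialect the ingest stage reads — so the
   full pipeline, including its ability to *recover* a known hierarchy, is
   testable without any field data.

## Worked example

Simulate a 17-cow herd for 20 days with a planted hierarchy (σ from 10 m for
`Cow01` to 150 m for `Cow17`), then run the analysis:

```r
library(herdrank)

cfg    <- sim_config(n_cows = 17, n_days = 20, seed = 5)
sim    <- simulate_message_log(cfg)
iv     <- bin_intervals(apply_collar_map(sim$log, sim$collar_map))
filt   <- exclude_incomplete_days(iv)
ir     <- interval_ranks(filt$intervals)
daily  <- daily_median_ranks(ir)
finals <- cumulative_finals(cumulative_curves(daily))

head(finals, 5)
#> # A tibble: 5 × 2
#>   cow_id cumulative_final
#>   <chr>             <dbl>
#> 1 Cow01              62.2
#> 2 Cow02              73.8
#> 3 Cow03              87
#> 4 Cow04              98.2
#> 5 Cow05             115

kendalls_w(daily_rank_matrix(daily))
#> Kendall's W = 0.9181 (m = 20 days, n = 17 cows, ties corrected)
#> chi-squared = 293.79, df = 16, p = 4.91e-53
```

The five most cohesive cows by cumulative rank are exactly the five
smallest-σ cows that were planted, and the strong day-to-day concordance
(W = 0.92) reflects the planted structure; a herd with equal σ for every cow
gives W near the independence expectation 1/m instead. The one-shot
orchestrator `run_pipeline(messages, collars, out_dir)` runs the same chain
plus the null model and writes tidy CSV/JSON outputs with a hashed manifest;
`inst/cli/herdrank.R` wraps it for shell use.

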