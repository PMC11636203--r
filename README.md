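# beegate

Analysis of hive-entrance fiducial-tag detection logs: from raw per-frame
tag sightings of individually marked honey bees to foraging trips and their
duration statistics.

## The problem

Entrance-monitoring rigs for honey bee colonies film a narrow tunnel at the
hive entrance and read a small circular fiducial tag glued to each bee's
thorax. Every readable frame yields a *detection* — tag ID, timestamp,
image position (x, y), orientation — appended to a text log. Turning weeks
of such logs into biology requires three steps, which this package
implements and validates end to end:

1. **Event segmentation.** Same-ID detections separated by at most a
   grouping window *g* (default 60 s) form one *event*; a longer gap starts
   a new event. One minute is therefore the shortest resolvable trip.
2. **Direction classification.** Each event's net displacement *Δ* along
   the tunnel's long axis (signed positive toward the hive) labels it
   `enter` (Δ ≥ τ), `exit` (Δ ≤ −τ), or `unknown` (|Δ| < τ or fewer than 2
   detections), with τ = 0.25 × axis length by default.
3. **Trip pairing.** After discarding unknown events, an exit event
   followed by the consecutive entry event of the same bee is a *trip* with
   duration `enter.t_start − exit.t_end`; unmatched exits/enters are failed
   exits/entries. Reports give counts, category percentages, per-ID
   tallies, and mean/median/mode of the duration distribution.

Because field data has no ground truth, the package ships a synthetic
entrance-traffic simulator (behaviour mixtures of foraging, cleansing and
orientation flights, failed exits/entries, loitering; per-frame and
per-traversal detection failure) whose known excursions benchmark the whole
pipeline, plus a model of the circular 44-bit tag family itself: layout,
rendering, decoding, printable sheet generation, and the white-pixel
dilation pre-pass that recovers tags degraded by printer ink bleed.

Intended users: researchers running camera/tag entrance monitors who need a
tested, scriptable post-processing chain, and anyone who wants to stress
such a chain against simulated traffic before trusting it on field logs.

## Worked example

```r
library(beegate)

# a day of traffic for 10 tagged bees, with ground truth
sc  <- traffic_scenario(n_bees = 10, duration_days = 1, seed = 42)
sim <- simulate_traffic(sc)

res <- analyze_colony(sim$detections, run_config(verbose = FALSE))
print(res$report)
#> Colony activity report
#> ----------------------
#> Detections:            5772
#> Events:                99
#> Detections per event:  58.30
#>   enter:      43 (43.43%)
#>   exit:       41 (41.41%)
#>   unknown:    15 (15.15%)
#> Trips:                 39
#> Trips under 2 h:      39
#> <duration_stats> n = 39 | mean 15 min 17 s | median 6 min 14 s | mode 1 min 08 s

rr <- recovery_rate(sim$truth, res$trips, tolerance_s = 5)
sprintf("recovery: %.3f (%d / %d detectable)", rr$rate, rr$n_recovered,
        rr$n_detectable)
#> "recovery: 1.000 (38 / 38 detectable)"
```

Reading: 10 bees produced 5772 detections that segment into 99 events; the
15% unknown events are the simulator's failed exits/entries and loitering
bouts, which carry no net displacement. Pairing yields 39 trips, all under
two hours, with the heavily right-skewed duration distribution typical of
foraging (mode ≈ 1 min, mean ≈ 15 min). All 38 excursions whose two
traversals were actually detected are recovered as trips with the correct
duration; the one undetectable excursion lost a traversal to the
simulator's tag-occlusion model.

The same pipeline runs from a shell via the thin wrapper in `exec/`:

```sh
beegate simulate --seed 42 --out log.csv --truth truth.json
beegate analyze log.csv --out results/      # report + spreadsheet + figures
beegate render-tags --ids 5000-5099 --out tags.svg
beegate plot-events log.csv --id 5003 --out figs/
```

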