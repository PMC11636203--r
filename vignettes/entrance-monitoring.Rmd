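---
title: "Methods: from entrance-camera tag detections to foraging trips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from entrance-camera tag detections to foraging trips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beegate)
```

## The measurement problem

A camera watches the entrance tunnel of a honey-bee hive. Each worker bee
carries a small circular fiducial tag glued to its thorax; every video frame
in which a tag is readable yields one *detection*: the tag ID, a timestamp,
the tag's position in the image, and its orientation. A foraging bee
walking out through the tunnel produces a short burst of detections, is
absent while foraging, and produces another burst on return. The analysis
task is to turn a multi-day stream of such detections into *trips* — paired
departures and returns of individual bees — and to summarise the trip-
duration distribution, which is the quantity downstream work uses to reason
about foraging range.

This package implements that whole chain, plus the two components needed to
test it without hardware: a traffic simulator with ground truth, and the
tag-layout model with rendering and decoding.

## Event segmentation

Detections are first ordered chronologically (stable sort; ties keep input
order). Within each tag ID, consecutive detections at most `gap_seconds`
apart belong to the same *event*; a gap longer than the window starts a new
event. The boundary is inclusive: a gap of exactly `gap_seconds` does not
split. The default window is 60 s, which makes one minute the shortest trip
the system can resolve — an intentional floor that separates real
excursions from in-tunnel milling. Streams of different IDs never interact.

The grouping is validated two ways: a property suite over randomized
streams, and an exhaustive oracle that enumerates every possible
segmentation of a stream (all $2^{n-1}$ split patterns) and checks that
exactly one satisfies the event invariants and that the streaming algorithm
returns it.

## Enter/exit classification

The source system reports event categories but not the rule that assigns
them, so the classifier here is a declared reconstruction, chosen because
published trajectory plots show category tracking the direction of travel
across the long image axis. For each event we compute the *net
displacement*: last detection position minus first, projected on the
tunnel's long axis (the 800-px dimension at the default field of view) and
signed positive toward the hive side. Then

* `enter` if displacement ≥ `displacement_threshold_frac` × axis length,
* `exit` if ≤ −threshold,
* `unknown` otherwise, and always for events with fewer than
  `min_detections_for_direction` (default 2) detections.

The default threshold fraction is 0.25 (200 px): tolerant of partial
traversals while rejecting loitering. It is exposed in configuration
precisely because it is a reconstruction, not a published constant.
Recorded tag orientation is deliberately *not* used: a bee's instantaneous
heading is a poor proxy for travel direction (bees back up, turn, and groom
in the tunnel), while net displacement is robust. The classifier is
antisymmetric (reversing a trajectory swaps enter and exit) and invariant
under uniform translation along the axis; both are property-tested.

## Trip pairing and statistics

A *trip* is an exit event followed by the consecutive entry event of the
same tag. Pairing proceeds per ID over chronologically sorted events:

1. `unknown` events are removed first. They carry no directional
   information; removing them after pairing would instead break almost
   every exit–enter adjacency, since in field data roughly half of events
   are unknown.
2. Each `enter` is paired with the *latest* preceding unpaired `exit`.
   Earlier exits in a run are failed exits; enters with no preceding exit
   are failed entries. Both are discarded. No event joins two trips.

Trip duration is `enter.t_start − exit.t_end`: last sighting while leaving
to first sighting on return, the closest log-derived approximation of time
outside the hive. (The alternative start-to-start convention would add the
outbound traversal time to every trip.) By construction every duration
exceeds the grouping window.

`trip_statistics()` reports mean and median over raw seconds; the mode is
computed at 1-second resolution (ties to the smallest value, matching the
right-skewed shape of trip distributions) and the histogram is binned in
minutes. An empty trip set yields `n = 0` with flagged, non-NaN moments.
The colony report adds category percentages (always summing to 100 within
rounding), the count of trips under a configurable cutoff (default 2 h),
and per-ID tallies. On empty input, percentages render as "—" rather than
NaN. Note one field-data caveat: the mean detections-per-event figure is
printed as the direct quotient of detections over events; summaries of the
original deployment quote a slightly different per-event average whose
basis is not stated, and no attempt is made to imitate it.

## The synthetic traffic generator

`simulate_traffic()` emulates what the entrance camera sees, with ground
truth. Its defaults are the package's declared study conditions:

* **Geometry and sampling.** 800 × 320 px field of view, hive to the left;
  straight-line traversals along the tunnel axis at 200 px/s (about 2 cm/s
  walking speed over the ~76 mm tunnel) with ±20 px uniform cross-axis
  jitter; 15 Hz frame rate, the source system's throughput cap.
* **Behaviour mixture** (per activity): foraging trip 0.55, cleansing
  flight 0.15, orientation flight 0.10, failed exit 0.08, failed entry
  0.05, loiter 0.07. Field distributions of the failure behaviours are not
  characterised anywhere; these weights are declared assumptions.
* **Durations.** Foraging trips are log-normal with `meanlog = 6.27`,
  `sdlog = 1.22`, putting the mode near 2 min and the mean near 18–19 min —
  the documented heavy skew toward 1–4 min trips. Durations are truncated
  to [61 s, 4 h]: below the grouping window a round-trip is unresolvable by
  construction, and foragers return the same day. Cleansing flights draw
  from [5, 60] s, orientation flights from [250, 300] s.
* **Scheduling.** Activities fall in a 07:00–19:00 daily window (bees fly
  in daylight) at a Poisson mean of 6 per bee per day, separated by
  exponential in-hive dwells (mean 30 min) with a 120 s floor — a returning
  bee that re-exited within the grouping window would be unresolvable by
  any window-based segmentation, so the generator does not produce such
  turnarounds. `exact_excursions_per_bee` fixes the ground-truth count for
  validation scenarios.
* **Detection failure.** Each in-view frame is read with probability
  `p_frame_detect` (default 0.9); a whole traversal is lost with
  probability `p_traversal_missed` (default 0.05), modelling bees crawling
  upside-down through the tunnel.

Ground truth records, per excursion, the last in-view moment on the way out
(`t_leave`), the first in-view moment on return (`t_return`), the behaviour
label, and how many detections each traversal produced. With perfect
detection the pipeline's trip duration equals `t_return − t_leave` exactly
(to the log's millisecond resolution), which is how the end-to-end recovery
tests can demand sub-frame agreement.

What the generator does **not** emulate: curved or reversing trajectories
within a traversal, image clutter and mis-decodes (tag IDs are always read
correctly when read at all), variable walking speed, night activity, and
drift between colonies. Passing recovery tests therefore demonstrate the
correctness of the segmentation/pairing logic under the stated motion
model, not detector performance on real imagery.

`recovery_rate()` counts an excursion as *detectable* when both traversals
produced at least `min_detections` detections and the duration exceeds the
grouping window; a detectable excursion is *recovered* when a trip of the
same tag overlaps it and matches its duration within a tolerance. The
matcher is cross-checked against an independent brute-force matcher in the
tests.

## The circular tag model

Tags are a 10 × 10 cell grid approximating a circle: 20 ignored corner
cells, a white outer ring (20 cells), a black detection ring (16 cells),
and 44 data cells — codewords therefore live in $[0, 2^{44})$. The grid
shipped in `extdata/circle44_layout_synthetic.txt` is a synthetic
reconstruction built from those published constraints by classifying cells
by distance from the grid centre; the upstream family's exact corner
layout is not restated machine-readably anywhere, so codewords rendered
here are internally consistent but not interchangeable with the upstream
family. Bit significance follows raster scan of the data cells.

`render_tag()` and `decode_raster()` are exact inverses on clean,
axis-aligned renders. Decoding reads each data cell as its mean intensity
thresholded at mid-gray, with an error (not a guess) when the mean falls
within ±10% of the threshold. Whole-cell averaging — rather than a single
centre-pixel probe — is what makes the decoder degrade under ink bleed the
way a real detector does: printed black ink that creeps one pixel into
every white region (simulated as a 1-px erosion of white) drops shrunken
white cells below threshold, and `dilate_white()` (grayscale morphological
dilation, default 3 × 3 box) restores them exactly, because dilation after
erosion is a morphological opening that is the identity on regions at
least one kernel wide. A centre-pixel probe would be blind to symmetric
erosion (the centre pixel is the last to go) and could not exhibit the
failure mode the dilation pre-pass exists to fix.

`naive_tag_detector()` is the reference detector behind `detect_tags()`:
it thresholds dark pixels, closes intra-tag gaps with a box dilation of
known cell size, labels connected components, takes bounding boxes as tag
candidates and decodes them, discarding candidates that fail. It assumes
unrotated tags at known scale and reports orientation 0 — it is the test
oracle for rendered frames, and any real tag-family detector binding can
be injected in its place through the same narrow contract (frame in;
id/x/y/theta out). Printable sheets (`make_sheet()`) place each 2 mm tag
inside a 2.6 mm cut circle (ratio 1.3) with an orientation stripe on the
forward edge, reject layouts whose cut circles would overlap within the
0.1 mm plotter precision, and reject cut circles that would clip border or
data cells.

## Numerical and format choices

* Timestamps are naive local time, carried internally as POSIXct pinned to
  UTC at millisecond resolution; the log dialect (ISO-8601 with optional
  fractional seconds, comma-separated, header
  `timestamp,tag_id,x,y,theta,cpu_temp`) round-trips losslessly, and
  numeric fields print at full precision. The original system's on-disk
  format is only shown pictorially, so this dialect is a defined,
  diff-friendly superset of its content; a pluggable per-line parser hook
  ingests other dialects.
* Lenient parsing (skip and record malformed lines) is the default for
  field data; strict mode aborts on the first bad line. Malformed lines
  are never silently dropped — they are returned with line numbers.
* The event spreadsheet is written as CSV and as single-file SpreadsheetML
  (`.xls`), an XML workbook format Excel and LibreOffice open natively; the
  environment provides no xlsx zip writer and the tabular payload does not
  need one.
* Problem sizes in the validation suite — 1000 oracle streams, a 500-
  excursion perfect-detection scenario, 200-excursion degradation ladders,
  100 render/decode codewords — were chosen to exercise every branch at
  desk scale while keeping the default test run fast.

## Known limitations

* The enter/exit rule is a reconstruction; against real field data its
  threshold would need calibration, and events a real system calls unknown
  for image-quality reasons are here unknown only for geometric ones.
* The reference detector does not handle rotation, scale uncertainty, or
  clutter; it exists to close the render→detect→log loop in tests.
* Trips interrupted by missed traversals appear as failed exits/entries
  and are discarded rather than imputed.
* Colony-level population dynamics, robbing, drifting and night activity
  are out of scope for the simulator.
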