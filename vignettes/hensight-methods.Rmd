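---
title: "Measuring cluster and unrest behaviour of laying hens from overhead video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cluster and unrest behaviour of laying hens from overhead video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Floor-housed laying hens express welfare-relevant group behaviours that are
visible from a ceiling camera: *agglomeration* (birds packing together, e.g.
around a feeder or when cold) and *unrest* (the flock moving about). hensight
turns a sequence of overhead grayscale frames into two scalar time series
that quantify these behaviours, relates them to the thermal environment, and
compares housing treatments (for instance monochromatic lighting colours)
with standard ANOVA/Tukey machinery.

The package makes no attempt to track individual birds. Threshold
segmentation of low-resolution analogue footage yields *blobs* — connected
foreground regions that are one bird or a touching group of birds — and both
indexes are deliberately defined on blob statistics, which are robust where
identity tracking is not.

## From frames to blobs

Each frame passes through four steps:

1. **ROI crop.** A polygon delimiting the object-free floor is drawn once
   and applied to every frame (`roi_polygon()`, `crop_roi()`). Pixels
   outside the polygon are set to background; the result is cropped to the
   polygon's bounding box with the offset recorded, so centroids can be
   mapped back. All coordinates in the package are 0-based, origin at the
   top-left pixel centre, x = column, y = row.
2. **Gaussian low-pass** (`lowpass()`), with reflective borders. The kernel
   is the canonical choice for suppressing sensor noise before
   thresholding; `sigma_px = 0` disables it. The filter preserves total
   intensity and constant frames exactly.
3. **Threshold** (`binarize()`). Otsu's between-class-variance criterion is
   the default because it adapts to global illumination differences between
   recordings (e.g. between lighting treatments of different colour); a
   fixed threshold is available for footage where the modes are known.
   Polarity (birds brighter or darker than the litter) is a per-run setting
   with no universal default.
4. **Connected components** (`label_components()`), 8-connected, so birds
   touching diagonally count as one cluster. Components below `min_area`
   (default 50 px² at 352 × 240, a noise floor) are discarded but their
   area is reported, so foreground area is conserved. Per blob we record
   area (pixel count), centroid (mean pixel coordinate), and perimeter
   defined as the number of pixel edges between foreground and background,
   including hole boundaries and the frame border. That perimeter
   convention is exactly testable (a 10 × 10 square has perimeter 40),
   which is why it is the contract; smoother estimators would change values
   by a bounded factor without changing any comparison.

## The two indexes

For a frame with `nA` blobs of mean area `Ā` (px²), mean perimeter `P̄`
(px), mean pairwise centroid distance `D̄` (px), in a cropped frame of
height `h` and width `w`:

```
cluster index = 2 Ā √(h² + w²) / (P̄ · D̄ · (nA − 1))
```

Higher values mean a tighter flock: packing reduces `D̄` and merges blobs
(reducing `nA`, raising `Ā`). The diagonal makes the numerator scale with
the scene. The trailing count term is typographically ambiguous in parts of
the literature (`nA − 1` vs `1/nA` readings); both are implemented behind
`variant =` (`"n_minus_1"`, the default, and `"n_inverse"`), every output
records which variant produced it, and the two are monotone in the same
direction, so no comparison changes with the reading. The index is a
unitful pixel-scaled ratio; we do not rescale it.

When a term is undefined — fewer than two blobs under `n_minus_1`; no blobs,
or a single blob (whose `D̄` does not exist) under `n_inverse` — the frame is
flagged `valid = FALSE` and excluded from means. No numeric value is ever
fabricated for such frames.

The unrest index compares the centroid sets `F(i−1)`, `F(i)` of two frames
1 s apart using the symmetric Hausdorff distance `dH`:

```
unrest index(i) = k · max{ dH(F(i), F(i−1)), dH(F(i−1), F(i)) }   [cm]
```

`k = 2 H tan(α/2) / w` converts pixels to centimetres from the camera mount
height `H` (cm), lens opening angle `α` and frame width `w` (px); the
default geometry (150 cm, 60°, 352 px) gives k ≈ 0.492 cm/px. The Hausdorff
distance is computed on blob centroids, not contours, matching the
centre-of-mass definition of the statistic; it is zero exactly when the two
centroid sets coincide. Missing or empty frames break the 1-s pairing —
there is no interpolation.

Source video is decoded to frames at 1 fps upstream of the package; the
index cadence is defined at 1 Hz because that is the pairing interval of
the unrest statistic.

## Thermal environment

A datalogger records temperature and relative humidity every 5 min. The
temperature–humidity index

```
THI = 0.8 T + RH (T − 14.3) / 100 + 46.3
```

is strictly increasing in `T` (slope `0.8 + RH/100`) and changes direction
in `RH` at `T = 14.3` °C. Hourly THI is computed from the hourly-mean `T`
and `RH` (not the mean of per-record THI; the difference is second-order,
but one convention must be fixed). Classification uses the laying-hen
thermoneutral limits THI 59 (cold) and 78 (heat) as *strict* inequalities —
"above"/"below" — so a value exactly at a limit is comfort. The default
rule is THI-only; a joint rule that also triggers on air temperature
(< 15 °C cold, > 28 °C heat) is available as `rule = "thi_or_temp"`, since
both conventions exist in the welfare literature and the package asserts
neither as canonical. Each 15-min recording window is labeled by the class
of the mean THI over the clock hours it overlaps; windows without thermal
coverage are labeled `NA` and excluded, with a message.

## Statistical comparison

The experimental unit is **one recording** (its mean index over valid
frames), not one frame: frames 1 s apart are strongly autocorrelated, and
treating them as replicates would pseudo-replicate massively. Units carry
treatment, date, period (morning/afternoon) and comfort class.

`anova_tukey()` fits `response ~ treatment * factor` on the units and
reports cell means with compact letter displays: lowercase letters compare
treatments within a level (row), uppercase letters compare levels within a
treatment (column); groups sharing a letter are not significantly different
at `alpha` (default 0.05). Pairwise decisions use the studentized range on
cell means with the harmonic mean of the cell sizes — a standard,
reproducible choice for mildly unbalanced designs — with the error variance
and degrees of freedom from the two-way fit. The letter assignment itself
is the insert-and-absorb algorithm, verified in the test suite both against
`multcomp` on a balanced one-way design and against its defining property
(letters never contradict the pairwise decision matrix). Cells with fewer
than two units are omitted from comparisons and reported.

"Declaring a treatment difference", where the package's calibration is
assessed, means the treatment main-effect F test at `alpha`: it is the one
test whose null rate should equal `alpha` by construction, whereas
letter-based definitions aggregate many familywise-controlled tests across
slices.

## The synthetic flock generator

The study design hensight targets publishes no raw video, so validation
rests on an agent-based generator (`flock_sim_config()`,
`simulate_flock()`, `render_frames()`, `simulate_thermal()`) with known
ground truth. Its defaults encode the housed-group conditions the package
is built for: 20 birds per group on a 352 × 240 px floor, one first-order
step per second,

```
position(t+1) = position(t) + β (attractor − position(t)) + N(0, σ² I)
```

reflected at the walls (reflection rather than clipping, so σ is not
attenuated near walls). `σ` (px/s) is the motility ground truth behind the
unrest index; `β` pulls birds toward a feeder stand-in and is the ground
truth behind the cluster index. Birds render as filled ellipses
(semi-axes 12 × 8 px by default, ~7 % floor coverage for 20 birds — chosen
for the sparseness of segmented overhead footage of a small pen rather than
for metric realism) whose orientation is redrawn uniformly every frame to
stress the morphometry code without a posture model; `orientation =
"per_bird"` holds orientations fixed, which is what makes a motionless
flock render bit-identical frames. Overlapping birds merge into one blob,
as threshold segmentation of real footage would produce. The thermal
generator draws each hour's (T, RH) from class-specific boxes placed
strictly inside the scheduled comfort class with margin to the 59/78
limits, plus small per-record jitter, so an hourly mean never straddles a
boundary by construction.

The generator is a validation device, not a locomotion model: it has no
bird–bird exclusion, no pecking or feeding events, no photoperiod, and no
lighting-spectrum effect. Consequently, passing its tests demonstrates that
the measurement chain recovers known motility/attraction orderings and
calibrated null behaviour — not that any particular husbandry effect exists
in real flocks.

One domain-of-validity consequence matters for sweeps: under strong
attraction (β = 0.5) a default-geometry flock collapses onto the attractor
and merges into a *single* blob, where the cluster index is undefined
(`nA = 1`). The attraction-recovery sweep therefore uses a small bird
footprint (semi-axes 4 × 3 px, `min_area` 10) so the statistic stays inside
its domain across all β levels; the collapse itself is documented here as a
limitation of the index, which cannot distinguish "maximally clustered"
from "not measurable" once the flock is one blob.

## Problem sizes and numerical choices

The validation suite and the acceptance script run a scaled season — 3
treatments × 3–6 days × 2 periods with 60–90 s recordings at 1 fps — which
preserves the full design structure (treatments, periods, comfort classes,
per-recording units) at desk scale. Ground-truth orderings in the default
season are motility blue > green > red (σ = 10, 5, 2) and attraction
red > green = blue (β = 0.4, 0, 0).

Other fixed choices: Hausdorff and pairwise distances are computed from
coordinate differences (not the expanded quadratic form), so identical
points give exact zeros; Otsu's criterion has a plateau of maximizers
across an empty histogram gap, and any plateau point is accepted;
`mean_ci()` is the two-sided t interval; per-recording simulator seeds are
derived deterministically from the season seed; all CSV/JSON outputs
contain no wall-clock state, so a rerun with the same configuration and
seed reproduces them byte for byte.

## Worked example

```{r example}
library(hensight)

dir <- tempfile("season")
simulate_season(season_config(n_days = 3, duration_s = 60), dir, seed = 1)
res <- run_pipeline(run_config(dir, file.path(dir, "report"),
                               sigma_px = 0, method = "fixed", threshold = 127,
                               seed = 1))
res$comparisons$unrest_by_period
```

## Known limitations

* Blob-level measurement: once birds merge, individual contributions are
  unrecoverable, and a fully merged flock makes the cluster index
  undefined rather than maximal.
* The unrest index is a set distance: it is insensitive to which bird
  moved, and a single far-moving bird dominates the frame pair.
* The thermal classification assumes the logger represents the whole pen
  (one climate per house).
* The synthetic generator validates the measurement chain, not hen
  biology; effect sizes recovered from it say nothing about real lighting
  treatments.
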