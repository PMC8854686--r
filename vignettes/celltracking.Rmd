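---
title: "Tracking cells by detection, by pattern matching, and by hand: the models behind trackcells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking cells by detection, by pattern matching, and by hand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackcells)
```

## The problem

Quantifying single-cell dynamics in a time-lapse recording requires
following every nucleus through hundreds of frames, across divisions,
missed detections and close encounters. No automatic tracker is error-free
on real data, so a usable tracking engine must provide three things at
once: a fast automatic tracker for the easy majority, a precise
single-target tracker for the difficult minority, and an editing layer to
fix what remains — plus a way to *measure* how good the result is.
`trackcells` implements this combination headlessly, with a synthetic
ground-truth generator standing in for microscopy data so that every claim
the package makes about itself is checked by computation.

## Spot detection

A fluorescent nucleus is, to first order, an isotropic Gaussian blob of
scale $\sigma_b$ on a flat background. The detector convolves each frame
with the scale-normalized negated Laplacian of Gaussian,
$-\sigma^2 \nabla^2 G_\sigma$, built as a separable kernel of radius
$\lceil 4\sigma\rceil$ and corrected to exactly zero sum, so constant
images map to (numerically) zero and the operator is linear. For a blob of
amplitude $A$ with $\sigma_b = \sigma$ the peak response is $A/2$; scale
normalization keeps that height comparable across $\sigma$, which is what
makes a single absolute `threshold` meaningful.

Candidate spots are $3\times3$ local maxima above the threshold. Greedy
non-maximum suppression in descending response order removes maxima closer
than `min_distance` to an accepted one; ties are broken lexicographically
by (row, col) so the output is identical across platforms. Peak positions
are refined by a per-axis three-point parabolic fit, clamped to ±0.5 px.

Defaults (`sigma = 3.5`, `threshold = 8`, `min_distance = 5`) are chosen
for the package's canonical imagery — nuclei of $\sigma_b \approx 3\text{–}4$ px
and amplitude ≥ 80 over read noise of a few counts, where the matched peak
response (≈ 40+) clears the threshold by a wide margin while white-noise
response maxima (s.d. ≈ 2 counts here) stay far below it.

## Region formation

Region shapes are grown by marker-controlled watershed: the frame is
smoothed (`smoothing_sigma`, default 1 px), a foreground is delimited, and
the inverted smoothed intensity is priority-flooded from the spot markers
(8-connectivity, insertion-order tie-break, implemented in C++), so each
marker claims the basin around it. Labels partition the reachable
foreground; each region is 8-connected and contains its marker by
construction; markers falling on background yield empty regions and are
reported rather than silently dropped.

The foreground rule is the one genuinely open design choice. A global Otsu
threshold (offered as `fg_method = "otsu"`) delimits bright-versus-dark
well but places the cut far down the intensity shoulder, so regions extend
well beyond what one would call the nucleus. The default `"halfmax"`
therefore starts from the Otsu foreground and then trims each watershed
basin to the pixels above the background (median of the smoothed frame)
plus half its own peak height — the per-cell FWHM contour, the standard
definition of a Gaussian spot's extent and robust to cell-to-cell
brightness variation. A fixed absolute threshold is available for
calibrated data. This choice matters for region-overlap scores (SEG);
it does not affect spot positions or linking.

Features are computed per region (or per bounding box for spot-only ROIs):
area, centroid, per-channel mean and integrated intensity, and circularity
$4\pi A / P^2$. The perimeter $P$ is the Freeman chain-code length of the
traced outer boundary (straight moves 1, diagonal moves $\sqrt2$), which
overestimates smooth contours by ~5% on average; rasterized disks land
near circularity 0.9, and the tests assert the [0.85, 1.05] band rather
than 1.0.

## Linking

Frame-to-frame correspondence is the classical assignment formulation.
For $n$ sources and $m$ targets, an $(n+m)\times(n+m)$ matrix holds link
costs $d^2_{ij}$ (squared centroid displacement) in the top-left block,
with pairs beyond `max_link_dist` forbidden; death and birth diagonals
cost $b =$ `alt_cost_factor` $\times$ the largest finite link cost
(falling back to `max_link_dist`$^2$), and the bottom-right block mirrors
link feasibility at zero cost. With `alt_cost_factor` just above 1
(default 1.05) the optimum accepts every plausible link and still lets
objects appear and disappear. Optional relative area and intensity
penalties, $w\,|\Delta f|/\max(f)$, can disambiguate neighbours whose
geometry alone cannot — the close-contact situation. The solver is an
exact $O(n^3)$ Jonker–Volgenant shortest-augmenting-path implementation;
its optimality is asserted against exhaustive permutation search in the
test suite. Where several optima exist any minimum-cost assignment is
acceptable; tests compare costs, not pairings.

A second assignment over segment endpoints repairs what the frame-by-frame
pass cannot see:

* **Gap closing** — a segment end may adopt a segment start $g$ frames
  later ($1 \le g-1 \le$ `max_gap_frames`, within `max_link_dist`) at cost
  $d^2 (g-1)$. Closed gaps keep no interpolated nodes; the track simply
  jumps frames.
* **Division** — a segment start one frame after a node of another segment
  within `max_split_dist` may become that cell's daughter at cost $d^2$.
  An anchor may adopt at most two daughters in total: an interior anchor
  (whose own continuation is the first daughter) enters the problem once
  and, if chosen, the mother is cut there; a segment end enters twice.
  A segment end assigned a single start is treated as a wider-radius
  continuation rather than a one-daughter "division".

No-event alternatives cost `alt_cost_factor` × the largest finite
candidate. Merging (cell fusion) is deliberately not modelled. The result
is renumbered deterministically (by first frame, then first ROI id) and
always satisfies the lineage invariants: strictly increasing frames,
parents ending strictly before children, at most two daughters, no cycles,
each (frame, roi) in one track.

Coordinates are 1-based (row, col) with inclusive bounding boxes — the
natural R convention — and the 0-based frame numbering of the Cell
Tracking Challenge layout is handled entirely at the I/O boundary.

## Sequential tracking

The particle filter keeps $n$ candidate positions (default 300). Each step
propagates them by a zero-mean Gaussian random walk (`motion_sigma`,
default 5 px/frame — a search radius, not a motion estimate; there is no
velocity state), scores the patch around each particle against the
template by normalized cross-correlation, weights particles by
$\exp(\beta\,\mathrm{NCC})$ with $\beta = 10$, and resamples
systematically when the effective sample size drops below half of $n$.
The estimate is the weighted mean; the confidence reported per frame is
the best particle similarity. NCC is used because it is bounded and
illumination-invariant; patches with zero variance score 0 by definition,
so flat background neither attracts nor repels the tracker and a uniform
frame degenerates to uniform weights. The template is fixed by default
(drift-safe); an exponential-moving-average update is available for
slowly deforming targets. Backward tracking is the same algorithm with a
descending frame sequence.

The RNG state is carried inside the particle cloud, so a fixed
`rng_seed` gives bit-identical tracks, independent of anything else the
session has done. `resume_from()` implements the cancel–correct–resume
workflow: nodes before the correction frame are kept, the template is
re-seeded at the corrected position, and the remaining frames are re-run
on a substream derived from the original seed and the resume frame.

## Editing

Edits are value-producing (the input lineage is never mutated) and every
operation either yields a valid lineage or fails with a message:

* `cut_track(lin, id, f)` keeps frames ≤ f under the original id (and
  parent); the tail gets a fresh id and no parent; daughters re-point to
  the tail — the only re-pointing that preserves parent-before-child.
* Interior `delete_roi_node()` splits at the hole rather than bridging
  it: identity is never silently invented; re-joining is an explicit
  `link_tracks()`.
* Deleting a track orphans its daughters (cascade available) — minimal
  destructive side effects.
* `apply_script()` replays a line-oriented edit script atomically: the
  first failing command reports its index and leaves the inputs
  untouched.

The fuzz test applies 50 random edits and asserts validity after every
accepted one.

## Evaluation

Matching between ground truth and result is per frame and strict-majority:
result object $R$ claims ground-truth object $G$ iff
$|G \cap R| > \tfrac12|G|$, which makes the assignment unique; exact
halves do not match. SEG is the mean Jaccard over all ground-truth objects
(zero when unmatched), averaged over objects across all frames, not over
per-frame means. DET and TRA compare the tracking graphs (nodes =
object-in-frame, edges = track links incl. gap jumps, and parent links):
the weighted count of node splits, false negatives, false positives,
redundant edges, missing edges and wrongly-typed edges needed to turn the
result graph into the truth, normalized by the cost of building the truth
from nothing. The default weights (5, 10, 1, 1, 1.5, 1) are the published
evaluation defaults and are configurable. Parent edges are compared
as-is, with no one-frame tolerance. The implementation is checked three
ways: hand-computed fixtures asserted exactly, an error-injection suite
checking that each single error lowers exactly the right score, and a
seven-fixture parity suite whose expected values were recorded once from
an independently written evaluator and committed
(`tests/testthat/metrics_reference.json`).

## The synthetic generator

`generate_movie()` emulates fluorescence nuclear imagery: Gaussian-blob
cells (σ 3–4 px, amplitude 80–120 over background 10 by default) moving by
Brownian diffusion (0.8 px/frame) plus a common drift with reflecting
boundaries, Poisson shot noise followed by Gaussian read noise (σ 4), and
ground truth defined *before* noise: each cell's mask is its half-maximum
contour, with contested pixels going to the stronger contribution, so
masks are always disjoint and unambiguous. The default field — 15 cells on
256×256 over 30 frames, minimum initial separation 30 px, two scheduled
divisions — is the benign, well-separated regime: nuclei a detector of
this class should resolve everywhere.

Two knobs reproduce the error regimes that dominate real corrections:

* `contact_fraction` seeds pairs of cells 6 px apart that travel
  rigidly together — under 2σ apart, their joint intensity is unimodal,
  so a blob detector sees one object (under-segmentation).
* `swell_factor` controls the late mitotic shape change: for the two
  frames before a split the mother is rendered as a two-lobed figure
  elongating along the division axis (lobe separation
  $(\text{swell}-1)\,2\sigma\tau$, $\tau = \tfrac13,\tfrac23$). A plain
  radial swelling cannot mislead a LoG detector (a broader Gaussian still
  has a single response maximum); the bilobed anaphase figure is what
  actually invites over-segmentation, and at `swell_factor = 3` it
  reliably does. The default 1.5 keeps the figure compact and harmless.

Daughters separate at 12 px (≈ 1.5 nuclear FWHM diameters, resolvable by
construction in the benign regime) and keep a small persistent
post-mitotic migration apart (0.4 px/frame), as daughter cells do after
cytokinesis; without it, random diffusion regularly walks siblings back
into contact and the "benign" regime stops being benign.

The RNG draw order is fixed and documented in `?generate_movie`
(appearance, placement, scheduled-division axes, then per frame:
diffusion, division decisions and axes, then noise), so an independent
consumer of the same stream can replay the simulation — the test suite
does exactly that to verify the stochastic division count.

What the generator does **not** emulate: textured chromatin, uneven
illumination, photobleaching, shape irregularity, phase-contrast or
bright-field appearance, fusions, or cells entering and leaving the field.
Passing the end-to-end tests therefore shows the pipeline's logic is
correct under its stated model — exact lineage recovery when objects are
resolvable, graceful and repairable failure when they are not — and says
nothing about segmentation accuracy on, say, phase-contrast data, where an
external detector plugin would carry the recognition burden.

## The repair workflow

On the hard regime (`contact_fraction = 0.2`, `swell_factor = 3`) the
automatic pipeline leaves exactly the two documented error classes, and
the package's repair recipes mirror the interactive ones:

1. **Close contact.** One seed position per cell (the stand-in for a
   user's click) starts two sequential trackers over the movie. Because
   the pair travels rigidly, their offset is regularized to its
   componentwise median; in every frame where both smoothed centers fall
   in the same detected ROI, that region is split by the perpendicular
   bisector of the two centers. The split-line accuracy is bounded by
   tracker bias on heavily overlapping patterns (roughly half the mean
   positional error); in the worst such frames a residual mismatch can
   survive — the situation where an interactive user would fall back to
   manual placement.
2. **Over-segmentation.** At each division site, ROIs within 12 px of the
   mitotic figure in its two pre-split frames are deleted and replaced by
   one ROI covering their union — the delete-and-redraw edit.
3. **Relink all.** `relink_movie()` reapplies both linking stages to the
   repaired ROI set; repaired, imported and detected ROIs are treated
   identically, and the division edges are rediscovered by the split
   stage.

On the seeded hard regime in the test suite, TRA goes from 0.965 before
repair to exactly 1.0 after.

## Numerical and testing choices

* Kernel radii $\lceil 4\sigma\rceil$ (clipped to the frame); convolution
  via FFT with replicate boundaries.
* Assignment ties: any minimum-cost solution accepted; costs compared to
  $10^{-12}$ relative tolerance against brute force.
* Reflecting boundaries keep simulated cells 15 px inside the field so
  blobs never truncate.
* 16-bit TIFF round trips are exact for integer intensities; CSV
  centroids are written to $10^{-4}$ px; CTC track tables use 0-based
  frames and parent label 0 for "none".
* Problem sizes in the suite are chosen to finish in seconds while still
  exercising every code path: 200 assignment problems up to 6×6 against
  brute force, 30-frame 256×256 movies for the end-to-end and repair
  checks, 20-seed benchmarks for the particle filter (mean error
  ≈ 0.5 px at amplitude/noise = 20, well under the 2 px contract, and
  monotone in particle count).

## Known limitations

* Fusions (merges) are not modelled in linking; a merge appears as one
  death plus growth of the survivor.
* The particle filter tracks position only; it does not propagate region
  shape, and on two near-identical overlapping patterns its estimate is
  biased toward their joint centroid.
* SEG requires regions; spot-only workflows get DET/TRA but no
  region-overlap score.
* 2D only; z-stacks must be projected upstream.
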