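---
title: "Methods: terminus choreography and dif-cassette excision analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terminus choreography and dif-cassette excision analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(difcycle)
```

# What the package measures

Bacterial chromosome dimers are resolved by XerCD site-specific
recombination at *dif*, a site in the replication terminus (*ter*), under
the control of the septum-located DNA translocase FtsK. Two experimental
readouts quantify when and how this machinery acts:

1. **The dif-cassette excision assay.** A reporter cassette flanked by two
   *dif* sites interrupts *lacZ*; every excision event turns a blue colony
   lineage white on X-Gal. Scoring the non-recombined (blue) colony
   fraction before and after growth yields a per-generation excision
   frequency.
2. **Single-cell choreography.** Fluorescent labelling of a
   terminus-proximal locus, combined with bright-field imaging of cell
   shape, reveals when sister *ter* copies separate relative to the onset
   of division-septum constriction — the window in which FtsK can engage
   the chromosome.

`difcycle` implements both computations as a tested pipeline, together
with a stochastic single-cell simulator whose ground truth exercises every
analysis stage without external data.

# The excision-frequency estimator

With `Ri` and `Rf` the initial and final non-recombined fractions and `n`
the number of divisions (from cell counts, `n = ln(Nf/Ni)/ln 2`), the
per-generation excision probability is

$$ f = 1 - e^{\ln(R_f / R_i) / n}, $$

which reduces to `1 - exp(ln(Rf)/n)` when the starting culture is fully
non-recombined (`Ri = 1`). `excision_frequency()` attaches a warning when
`Rf` falls outside the 10–90% window in which the readout is well
conditioned. The *recA*-dependency — the fraction of excision attributable
to homologous-recombination-generated chromosome dimers — is
`1 - f(recA-)/f(recA+)` (`reca_dependency()`); sampling noise can push it
below zero, and such values are reported verbatim with a warning rather
than clamped, so replicate averages stay unbiased.

Replicate aggregation (`estimate_excision()`) defaults to computing `f`
per replicate and averaging, matching how per-experiment means are
reported; pooling ratios first is available behind a flag. Uncertainty is
a percentile bootstrap over replicates (`bootstrap_ci()`). Percentile
intervals undercover at very small replicate counts (a generic
small-sample property, noticeable at 3–5 replicates); the package's
calibration experiments therefore evaluate coverage at 16 replicates,
where the interval performs close to nominal.

The plating simulator (`simulate_plating()`) follows founder lineages
through lag (no divisions), `n` exponential doublings and stationary phase
(no divisions), excising per division with probability
`f_indep (+ f_dep if recA+)`, and scores colonies by binomial sampling —
so the closed form `E[Rf] = (1-f)^n` and the estimator can be checked
against each other end to end. Lag and stationary phases are modelled as
contributing no divisions at all, consistent with excision being coupled
to division.

# The simulator

## Cells, lanes and geometry

Cells are rods of fixed 1 µm width whose pole-to-pole length grows
exponentially at `ln 2 / generation_time`, dividing at mid-cell after a
per-cell cycle time drawn around the preset mean. Geometrically a cell is
an axis-aligned rectangle: length, positions and every downstream
statistic depend only on the pole-to-pole extent, so rounded caps would
add rendering cost without changing any measured quantity.

Each founder occupies one image lane; descendants stay stacked end to end,
daughters replacing their mother in place with a 0.45 µm gap opened at
scission (newly divided siblings slide apart). This layout keeps
frame-to-frame mask overlap high for tracking while guaranteeing cells
never collide. Founders start at a uniformly random cycle phase
(`founder_phase = NULL`), giving desynchronised, steady-state-like
populations; a fixed phase is available for deterministic examples.

## Cycle timing and focus trajectories

Two cycle fractions govern the choreography: `t_sep` (sister-focus
separation) and `t_con` (first optically visible constriction). The
literature reports population means (e.g. separation at ~40% of the cycle
in fast growth, ~80% in slow growth, constriction at ~60% and ~80%
respectively); between-cell variability is not reported, so both are drawn
from truncated normals with sd 0.05 cycle units — a modelling choice,
flagged here and in the configuration. An alternative constant-hazard mode
(`sep_hazard`) makes separation age exponential, used to calibrate the
duplication-rate estimator against a programmed hazard.

A focus relaxes exponentially (time constant `relocation_time`, 6 min)
toward its current target: birth position → mid-cell before separation;
after separation the two sisters jump apart by 2 × `sep_jump` (0.12
relative units, making them immediately resolvable, as abrupt splitting
appears in time-lapse data) and relax toward the quarter positions
(0.25/0.75). Gaussian positional jitter (sd 0.01 cell lengths) is added
per frame. With overlapping replication rounds enabled (fast-growth
presets), each of the two foci may split again late in the cycle
(fraction 0.9, probability 0.4 per focus), producing 3–4 focus cells whose
daughters are born with two foci — a phenomenological model of re-initiated
replication, not an explicit replisome simulation. At scission the
mother's foci are partitioned by position; daughter coordinates are
re-expressed with the old pole at 0.

Presets bundle these choices: `Ec-slow` (92 min generation time,
t_sep = t_con = 0.8, 4 min frames), `Ec-fast` (40 min, t_sep 0.4,
t_con 0.6, 2 min frames, overlapping rounds), `Vc-slow`/`Vc-fast`
(polar birth position, separation trailing constriction), and two
perturbation presets chosen as plausible shifts rather than fitted values:
`dMatP` (premature release, t_sep 0.55) and `ftsK-ATP-` (separation
deferred to t_sep 0.97).

Reproducibility is strict: every cell consumes a private RNG stream hashed
from its lineage identifier and the master seed, so the same cell receives
the same randomness regardless of how many founders are simulated.

## Rendering

The fluorescence channel is a sum of isotropic Gaussian spots
(`psf_sigma` 0.08 µm) at the true focus positions over a constant
background, plus additive Gaussian noise. The bright-field channel is a
32-plane defocus stack spanning ±1.6 µm: each plane shows the cell body as
a signed, blurred rectangle whose contrast reverses through focus,
following an odd envelope `(z/z0)·exp(−z²/2z0²)` (peak contrast at
z0 = 0.5 µm defocus, decaying beyond — bright-field contrast vanishes both
in focus and far from it), with edge blur growing with defocus. From
septation onset a transverse Gaussian "dark line" (width 0.15 µm) erodes
the local contrast, its depth growing from 0.3 at onset towards 0.9 at
scission. Every term is separable in x and y, so a plane is one outer
product per lane — this closed-form optics model is what makes rendering
hundreds of complete cell cycles practical. Default intensity scales
(background 100, spot amplitude 500, fluorescence noise sd 5; bright-field
contrast 60, noise sd 3 per plane) correspond to comfortably detectable
but realistic signal-to-noise.

# The measurement pipeline

**Shape reconstruction** collapses each bright-field stack by the
per-pixel standard deviation across planes (`reconstruct_shape_image()`):
because cell-body contrast reverses sign through focus, the statistic is
near zero in background and large inside cells, and a constriction appears
as a transverse dark line. **Segmentation** is Otsu thresholding with a
3-pixel closing/opening cleanup and connected components; geometry comes
from second-moment principal axes. Sub-pixel pole positions are refined as
the half-interior-level crossings of a 1-px-binned axial profile
(`refine_axial_extent()`), which removes the whole-pixel quantisation and
neighbour-bleed bias of the binary mask.

**Tracking** links regions by maximal mask overlap after a growth
registration step: cells stacked in a lane drift in proportion to their
position as everything elongates, so the previous frame's labels are
rescaled (per horizontal band) to the current occupied extent before
overlaps are counted. Ties are broken by centroid displacement,
deterministically. A one-to-two event is provisional — segmentation splits
deeply constricted cells before scission — and is confirmed as a division
only when the two candidates' long axes deviate by > 15° or their gap
exceeds 1 pixel for 2 consecutive frames; until then the pair is analysed
as its union, and a re-merge discards the split as noise. Each confirmed
daughter's new pole is the end adjacent to its sibling; polarity never
changes within a life. A *complete cycle* is a cell followed from its
observed birth to its own confirmed division — the population entering at
frame 0 and cells still alive at the end are excluded from cycle-resolved
statistics.

**Profiles and kymographs.** Per-frame long-axis profiles use bins of at
least ~1.5 px (sub-pixel bins sample single edge pixels and spike);
profiles are min-max rescaled per frame — making every statistic invariant
to per-frame affine intensity changes and every cell equally weighted —
oriented old pole first, and resampled onto a fixed (default 101 × 101)
cycle-time × relative-length grid (`cycle_kymograph()`). The consensus
image is the plain element-wise mean. Because each cell's rows are
individually rescaled, the consensus mid-cell intensity approximates the
fraction of cells not yet separated at that cycle fraction;
`estimate_split_time()` reads the separation time as the first row
(persisting one row) where the central ±0.03 window falls below 0.5 —
an estimate of the *median* separation fraction.

**Septation detection** (`detect_septation()`) fits, per frame, a
quadratic baseline to the flanks of the lightly smoothed profile's central
60% — the central detection window \\[0.35, 0.65\\] is excluded from the
fit, so a real constriction neither bends the baseline nor inflates the
noise estimate; the quadratic absorbs the broad intensity dome of short
cells. A constriction is called when the windowed minimum dips below the
baseline by ≥ 3 × a robust scale (MAD of flank residuals, floored at 4% of
the profile range so only an appreciable fraction of the cell's own
contrast counts as "visible"), and the dip persists at a stable position
(within 8% of the length) in the next frame. Detection cannot precede the
physical onset; on synthetic data with default noise it lands on the onset
frame or one frame late. Snapshot constriction classification
(`has_constriction()`) applies the same dip criterion to a single frame.

**Focus detection** (`detect_foci()`) convolves the fluorescence image
with a scale-normalised Laplacian-of-Gaussian at the PSF scale, keeps
in-mask local maxima whose intensity exceeds the in-cell median + 5 MAD
(falling back to 10% of the in-cell dynamic range when the MAD degenerates,
e.g. noise-free data), merges peaks closer than 2 PSF sigmas (brighter
wins), refines positions by intensity-weighted centroids, and reports at
most four foci — downstream statistics pool "3 or more" into one class.
Positions are mapped to relative long-axis coordinates using the refined
axial extent.

**Aggregation.** `snapshot_stats()` classifies cells by constriction ×
focus class and reports counts, position tables and the strict `d < 0.05`
mid-cell fraction ("less than 5% of the cell length" is read as a strict
inequality). `align_to_septation()` re-indexes each cell's frames so
septation detection is offset 0; `duplication_rate()` counts 1→2
transitions per at-risk single-focus cell per minute, requiring the second
focus to persist one further frame so detection blinking is not scored
(focus-count decreases are likewise never scored as reverse duplications).

# Validation design

Every statistic has two routes: through the imaging pipeline on rendered
movies, and directly from simulator ground truth under the same
observation protocol (`truth_observations()` and friends — frames on the
imaging lattice, divisions requiring two post-scission frames, septation
requiring two consecutive constricting frames). On noise-free renders the
two routes agree exactly for every count and frequency, and to 0.01
relative-length units for position statistics; medians are compared where
a class holds at least 10 foci, since the median of one or two foci is not
a stable statistic. The mid-cell fraction is a count with a hard threshold
on a continuous coordinate, so the two routes may differ by exactly the
foci whose true distance from centre lies within the position tolerance of
the 5% cut; the tests bound the disagreement by that boundary mass.

Problem sizes in the test suite were chosen as the smallest that make the
checks statistically meaningful: ~200 complete cell cycles for oracle
equivalence and parameter recovery (split-row recovery to ±0.05 cycle
units; septation within +0/+1 frame on ≥95% of cells), 100 seeded
replicate experiments of 16 platings for estimator bias and bootstrap
coverage, and 10⁴ lineages per simulated plating.

# What the simulator does and does not emulate

It reproduces the statistical structure the analysis assumes:
exponentially growing desynchronised rods, timed separation and
constriction, resolvable sister foci, defocus-dependent bright-field
contrast with a septal dark line, shot-like additive noise, and
division-coupled cassette excision. It does **not** model diffraction
beyond a Gaussian PSF, phase-contrast optics, curved or crowded 2-D
microcolonies, segmentation-adversarial cell shapes, replisome or polymer
dynamics, photobleaching, uneven illumination, or nutrient shifts. Passing
the recovery tests therefore demonstrates the *correctness of the
computations* under the stated model, not the robustness of segmentation
or tracking on arbitrary real microscopy — the components most sensitive
to those gaps (the unpublished lab segmentation tool's heuristics, manual
spot calling) are exactly the ones the original analyses handled with
human supervision.

# Known limitations

* Bright-field septation detection is conservative: a dip must reach the
  4%-of-range floor, so very shallow early constrictions are dated late;
  on real data the method can only bound the onset from above.
* The provisional-division rule assumes siblings eventually separate by
  more than a pixel; in a filament/no-scission regime (`scission_enabled
  = FALSE`) divisions are, correctly, never confirmed.
* Lane-stacked growth is a 1-D idealisation; the growth-registration step
  in tracking exists precisely because of it and has no tuning for 2-D
  colony geometry.
* The excision estimator ignores differential plating efficiency between
  recombined and non-recombined cells, as does the underlying assay
  arithmetic.
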