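---
title: "Quantifying leukocyte migration in wound-healing time-lapse assays"
author: "leukotrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leukocyte migration in wound-healing time-lapse assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukotrax)
```

## Scope

`leukotrax` quantifies the migratory behaviour of myeloid cells —
neutrophil-like granulocytes and monocyte/macrophage-like cells — in
two-channel fluorescence time-lapse recordings of larval wound-healing
assays. The pipeline has four measurement stages and one generative stage:

1. **segment** — dual-threshold cell detection and morphometrics (whole-cell
   area WCA, cell-body area CBA, normalized lamellipodia area NLA, length,
   lamellipodia count, channel subset, density, wound geometry);
2. **track** — criterion-based frame-to-frame linking;
3. **kinematics** — instantaneous and average speed, path length, net
   displacement, activation time, cohort comparisons;
4. **circstats** — polar transformation of displacement vectors, Rayleigh
   uniformity test, rose histograms;
5. **simulate** — an agent-based generator of ground-truth trajectories and
   rendered image stacks, used to validate all of the above by parameter
   recovery.

Because raw microscopy of such assays is rarely deposited, the simulator is
a first-class component: every measurement stage is tested against synthetic
data whose generative parameters are set to published summary statistics,
and the stage must recover them.

## Morphometrics: the dual-threshold model

Lamellipodia — the thin sheet-like protrusions that drive crawling — carry
visibly less fluorescence than the cell body. Thresholding one channel at
two levels therefore separates the compartments: pixels at or above a low
threshold `t_cell` form the *whole-cell* mask, pixels at or above a high
threshold `t_body` form the *cell-body* mask (a subset by construction).
The normalized lamellipodia area is

$$\mathrm{NLA} = \frac{\mathrm{WCA}}{\mathrm{CBA}} \ge 1,$$

equal to 1 for a cell without protrusions and larger for cells with
extensive lamellipodia; macrophage-like cells score systematically higher
than granulocyte-like cells.

Candidate cells are connected components of the whole-cell mask. Two
filters mirror standard practice: a component without any body component
inside it is debris, and components whose tip-to-tip length falls outside
10–60 µm are debris or fused aggregates. Lengths are maximum pairwise
pixel-centre distances (computed on the convex hull). Lamellipodia are
counted as connected components of the whole-minus-body fringe with area of
at least `min_lobe_area` (default 5 µm², suppressing single-pixel slivers).

Real assays set the two thresholds manually and do not report them;
absolute NLA values are therefore threshold-dependent, and only *orderings*
(macrophage > granulocyte) are scientifically portable. Defaults here are
Otsu's threshold on the intensity histogram for `t_body` with
`t_cell = 0.4 t_body`, both overridable; on simulations the pipeline uses
midpoints between the configured background, lamellipodium and body
intensities.

Wound geometry is measured on a user-supplied mask: area as pixel count
(reported in mm²) and perimeter with a Cauchy–Crofton estimator (line-grid
intersection counts in four directions, `L = π/8 (n_0 + n_90 +
(n_45 + n_135)/\sqrt2)` in pixel units). Naive pixel-edge counting
overestimates a circle's perimeter by ~27%; Crofton is accurate to ~1% on
discs at these resolutions, at the price of under-reading sharp corners
(a 100×100 px square measures ~378 rather than 400 px). The estimator name
is recorded in the output.

## Tracking: the three criteria

Linking follows the classic rule set: (i) detections already satisfy the
size range; (ii) *continuous presence* — a missed detection terminates the
track, and a reappearing cell starts a new track id (no gap closing);
(iii) *no jump of more than two body sizes* between consecutive frames.
"Body size" is the equivalent diameter $2\sqrt{\mathrm{WCA}/\pi}$ of the
earlier detection, which is robust to frame-to-frame lamellipodial
flicker. Matching is one-to-one and greedy in ascending distance with
deterministic tie-breaking (lower cell labels win); an exhaustive
optimal-assignment variant (`method = "optimal"`) exists for verification
and matches the greedy pair count at assay-like densities, where cells are
sparse relative to the gate.

## Kinematics

For a track sampled at interval $\Delta t$ (2 min by default, the standard
acquisition rate):

* *point speed*: step distance / $\Delta t$ per consecutive frame pair;
* *average speed*: total path length / elapsed time (equals the mean point
  speed at even spacing);
* *net displacement vector*: last minus first position;
* *activation time*: elapsed time from wounding to the first sustained
  displacement of more than one body size. Operationally, sliding windows
  of `window_frames` frames are scanned and the activation frame is the
  start of the first run of `window_frames` consecutive windows whose
  displacement each exceeds the body length. The default window (3 frames,
  6 min) suits fast granulocytes; for slow macrophage-like cells the window
  must span roughly `body_length / speed` or the rule never fires — the
  cohort tests use 10 frames (20 min) for both phenotypes. Here
  "body size" is the CBA-based diameter $2\sqrt{\mathrm{CBA}/\pi}$, since
  the criterion names the cell body.

Cohort contrasts (speeds, activation times, NLA) use the two-sided
Mann–Whitney rank test via `compare_groups()` (exact null for small untied
samples, normal approximation with tie correction otherwise).

## Circular statistics

Displacement vectors are converted to polar form in the plotting
convention: 0° along +x, angles counterclockwise in a y-up display frame.
Image-frame dy (y-down) is negated during conversion, so a wound placed
straight below the field centre lies at 270°, the conventional layout of
the assay's rose plots. Zero-length vectors carry no direction; they are
excluded and counted.

The Rayleigh test uses the mean resultant length
$\bar R = |\sum_j e^{i\theta_j}|/n$, $z = n\bar R^2$, and the standard
small-sample approximation

$$p = \exp\!\left(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)\right),
\qquad R = n\bar R,$$

the form used by the common circular-statistics toolboxes. A Monte-Carlo
p-value under the uniform null (`method = "mc"`) provides an independent
check; across $n \in \{10, 50, 200\}$ and a 10⁶-draw null the
approximation agrees within ~3% down to tail probabilities of 10⁻³.

Per-track *net* displacements over an analysis window are the default
vectors (per-step angles are also available). The window is a parameter,
not a constant: published analyses vary between 1 h, 2 h and full
recordings, so `run_pipeline()` takes `window = c(first, last)` frames and
defaults to wound onset through the end of the recording. Tracks whose net
displacement stays below `min_net_displacement` (default 15 µm, about one
body size) are not migrating and are excluded from the directional
analysis — tracking procedures in these assays follow *migrating* cells,
and including stationary cells' noise vectors dilutes and tilts the
circular mean. The wound bearing computed from the field geometry is
reported alongside every Rayleigh result.

## The synthetic-data generator

The generator is an agent-based biased persistent random walk. The
literature describes *behaviour* (activation delays, speed ranges,
directionality), not a mechanistic model, so the simplest model producing
those statistics was chosen, with every parameter in the configuration
rather than hard-coded.

**Motion.** Per frame, an activated agent keeps a wrapped-normal
perturbation of its previous heading (SD `heading_sd` = 0.4 rad) with
probability `persistence`, otherwise reorients toward the wound centre
with a wrapped-normal draw of concentration `chemotactic_strength`
(SD $1/\sqrt\kappa$; $\kappa = 0$ is uniform). Step length is
$\max(0, N(\mu_v, \sigma_v))\,\Delta t$, capped at the phenotype's peak
speed. Quiescent agents take isotropic steps at `quiescent_speed_factor`
(default 0.2) of the activated speed — pre-wound baseline motility is not
reported in the literature, so this is a package choice. Boundaries are
reflective, keeping the cell count constant over a fixed field of view.

**Activation.** Each cell samples an activation delay once
($N(\mu_d, \sigma_d)$ truncated at 0) and switches quiescent→activated
when the time since wounding exceeds it. With an infected wound, activated
cells within `stall_radius` of the wound centre switch irreversibly to
`stalled` and move at `stall_speed_factor` of their drawn speed —
reproducing the reduced macrophage/granulocyte speeds at infected wounds
as a speed effect only (no phagocytosis modelling).

**Rendering.** A cell is a bright body disc plus dimmer lamellipodial lobe
discs overlapping the body rim; the lobe count is redrawn each frame from
the phenotype's range (shape flickers), granulocyte lobes sit within ±45°
of the heading, macrophage lobes spread around the full circle. Lobe radii
are solved numerically so the area added outside the body equals the
configured per-lobe area, making ground-truth whole-cell areas analytic.
Gaussian background noise is added and intensities clamped at zero. A cell
appears in a channel iff its channel flag is positive. Trajectories and
rendering consume separate seed streams, so the ground-truth table is
identical whether or not frames are rendered; `run_pipeline(render =
FALSE)` runs the downstream statistics on ground-truth centroids, the fast
path used for replicate studies.

**Default calibration.** 1.6 µm/px, 2-min frames, a 1000×800 µm
(0.8 mm²) field, and a 150 µm-radius wound (0.3 mm biopsy punch) centred
on the bottom edge of the field — the punch removes tissue at the fin
margin, so cells approach from the tissue side and the wound bearing from
the field centre is 270°. Phenotype defaults target the published summary
statistics:

| parameter | granulocyte | macrophage (and mpeg-only) |
|---|---|---|
| count (default mix) | 60 | 35 (+5 mpeg-only) |
| body radius (µm) | 5.5 ± 0.4 | 7.0 ± 0.5 |
| lobes per frame | 1–3 × 27.5 µm² | 4–6 × 35 µm² |
| implied mean WCA (µm²) | ≈ 150 | ≈ 330 |
| implied mean NLA | ≈ 1.58 | ≈ 2.13 |
| speed (µm/min) | 4 ± 1, peak 20 | 1.5 ± 0.5, peak 10 |
| activation delay (min) | 10 ± 5 | 40 ± 15 |
| persistence / chemotaxis κ | 0.6 / 4 | 0.5 / 3 |
| channels | lurp⁺ | lurp⁺ mpeg⁺ (mpeg⁺ only) |

The mpeg-only subpopulation is 5% of the default mix, and the default
macrophage+mpeg-only density in a 0.8 mm² field is 50/mm²; the
tissue-resident density benchmark (30 macrophages/mm²) is recovered on a
dedicated 2 mm² unwounded configuration. Speed and WCA targets are chosen
so that the *measured* pipeline output — not the generative input — lands
on the published values; rasterisation and lamellipodial flicker inflate
measured speeds by roughly 5% at granulocyte scale, which the acceptance
bands absorb.

## What the simulator does and does not emulate

It reproduces: two phenotypes with distinct size/shape/speed
distributions, a 5% mpeg-only subpopulation, wound-directed chemotaxis
with phenotype-specific activation delays, infection-induced stalling,
dual-intensity rendering with background noise, and assay-scale densities.

It does not reproduce: vasculature and extravasation geometry, 3-D optics
or point-spread functions, phagocytosis events (the "target chasing" speed
profile appears only as a stall), cell division or death, intensity
bleaching, or touching-cell resolution (there is no watershed splitting;
the measurement pipeline instead discards fused aggregates by the length
cut-offs, and cohort statistics at realistic densities carry a small loss
from such merges). Passing tests on synthetic data therefore validate the
*measurement algebra* and its statistical behaviour, not robustness to
every artefact of real microscopy.

## Numerical choices

* Thresholds on simulations: midpoints of configured intensities;
  otherwise Otsu with `t_cell = 0.4 t_body`. `t_body ≤ t_cell` is an
  error.
* Greedy linking ties broken by (distance, earlier label, later label) —
  fully deterministic.
* Activation windows: displacement is straight-line over the window, and
  the activation frame is the window start of the first qualifying run.
  A cell stepping 3 µm/frame with a 10 µm body never activates under a
  3-frame window (9 µm < 10 µm) — the rule is a threshold, not a trend
  test.
* `circ_mean` snaps values within 10⁻⁹ of 360° to 0 and refuses samples
  with vanishing resultant length.
* Degenerate inputs error early with stage-tagged messages in
  `run_pipeline()`; an empty simulation (all counts zero) is an error, not
  an empty report.
* All randomness flows from the single config seed; per-frame seeds are
  drawn up-front so stages are reproducible independently.

## Problem sizes used by the test-suite studies

Replicate studies run on the ground-truth fast path: 50 wound-directed
replicates of the default assay (joint criterion: Rayleigh p < 0.05 and
circular mean within 15° of the wound bearing) and 200 null replicates
(40 isotropic granulocytes, 25 frames) for the type-I error of the
Rayleigh test at α = 0.05. Rendered-pipeline studies use 5 single-frame
replicates for composition and density, two 2-frame replicates for
morphometrics, and 30-frame single-phenotype cohorts (60 cells) for the
speed bands. Round-trip tracking validation uses 20 quiescent
macrophage-like cells over 60 noise-free frames on a 2000×1600 µm field,
where cells are sparse enough that identity switches should not occur.
These sizes are the package's chosen balance between statistical
resolution and a test suite that runs in minutes.

## Known limitations

* Measured speeds carry a small positive bias from centroid flicker
  (lobes are redrawn each frame); it is ~5% for granulocytes under
  chemotaxis and grows when headings decorrelate. Speeds on ground-truth
  centroids are unbiased.
* Absolute NLA values depend on the threshold pair; compare NLA only
  within a fixed thresholding scheme.
* Whole-cell centroids of strongly polarised cells sit up to ~2 px off the
  body centre; body-mask centroids would be less biased but noisier under
  flicker.
* At densities well above ~100 cells/mm² fused aggregates begin to distort
  cohort means; the detection-level length cut-offs remove most but not
  all of them.
* The Rayleigh p approximation is accurate for n ≥ 10; below that use the
  Monte-Carlo method.

## A complete run

```{r, eval = FALSE}
cfg <- simulation_config(seed = 7)        # default sterile punch-wound assay
report <- run_pipeline(cfg, out_dir = "assay_out")
report                                    # counts, Rayleigh result, bearing
recover_parameters(report)                # generative vs recovered table
plot(report$rose)                         # rose plot of migration directions
```
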