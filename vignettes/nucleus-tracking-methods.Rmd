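---
title: "Methods: semi-automated 3D nucleus tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated 3D nucleus tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nuctrackr implements tracking-by-detection for fluorescently labelled cell
nuclei in 3D time-lapse movies of dense epithelial tissue such as intestinal
organoids. This vignette is the package's own account of the method: the
models, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## The problem

H2B-labelled nuclei in organoid movies are bright anisotropic blobs imaged at
high lateral but poor axial resolution (defaults: 0.32 µm/px in xy, 2 µm
between z-slices, 12 min between frames — see `image_resolution()`). Nuclei
are densely packed and visually overlap, especially along z; intensity varies
strongly within and between cells; parts of the image saturate; and debris
from dead cells mimics live nuclei. Whole-organoid manual tracking is
prohibitively slow, so the pipeline automates detection and linking and then
*flags* the small fraction of suspicious events for manual review, rather
than promising error-free output.

The pipeline has three stages plus an evaluation layer:

1. **Detection** — a small 3D convolutional network regresses a heatmap whose
   local maxima are nucleus centers.
2. **Linking** — detections in consecutive frames are connected by solving a
   global division-aware minimum-cost problem.
3. **Error flagging** — six rules mark improbable events (appearances,
   disappearances, implausible movement or volume changes, over-fast
   re-division, merges) for curation.

## Detection by heatmap regression

Rather than segmenting nuclei (which would require painful manually
segmented training data), the network is trained on point annotations
rendered as target heatmaps: black volumes with a 2D Gaussian spot
(σ = 2 px, amplitude 1) at each nucleus center (`make_target_heatmap()`).
Because axial resolution is so much coarser than lateral, a spot lives only
in its own z-slice. Overlapping spots combine by voxel-wise maximum so
targets stay in [0, 1].

The network (`build_detector()`) is an encoder–decoder with skip
connections in which *every* convolution input is concatenated with three
channels holding the absolute voxel coordinates, normalized to [0, 1] over
the full stack. This intentionally breaks translation equivariance: nuclei
near the bottom of the stack are imaged differently from nuclei near the
objective, and absolute depth is informative. Coordinates are normalized
per stack (not per patch) so the depth signal survives training on small
patches. Design choices the source material leaves open, fixed here once:

* pooling is 2×2 in (y, x) only — with ~16 z-slices there is nothing to
  gain from halving z;
* convolutions are 3×3 in-plane with a single-slice extent at the
  full-resolution level and 3×3×3 from the second level down, where
  cross-slice context is aggregated; this respects the ~6:1 voxel
  anisotropy and costs a third of an isotropic kernel at the most expensive
  level;
* defaults `depth = 3`, `base_filters = 16`; the desk-scale experiments in
  the tests use `depth = 2`, `base_filters = 12` -- enough capacity to learn
  both nucleus response and debris suppression on synthetic blobs within a
  few hundred gradient steps;
* optimiser Adam, batch 4 and lr 1e-3 by default; the desk-scale runs use
  batch 2 with a stepped rate (3e-3 dropping to 1e-3 for the last three
  epochs), a standard small-budget schedule.

Training samples random 64×64 px columns (full z extent) and perturbs each
image/target pair: x/y/z flips, in-plane rotation by a uniform 0–360°
angle, 80–120% scaling, a brightness shift of at most 10% of the image
maximum, and a contrast factor c ∈ [0.5, 1.5] applied as
I′ = (I − ⟨I⟩)·c + ⟨I⟩. A full 3D rotation is deliberately *not* applied:
with 2 µm z-steps it is ill-defined. Targets are re-clamped at 0 after
interpolation.

The loss is a weighted mean squared error: with f the fraction of nonzero
target voxels, spot voxels get raw weight 1 − f and background voxels get
f, normalised to mean weight 1. Without this the network collapses to
predicting black images, since f is typically below 1%.

At inference the heatmap is linearly interpolated along z to isotropic
voxels, 3D local maxima above `threshold_rel` (default 0.1) of the global
maximum are extracted, greedily thinned to a minimum pairwise distance
(default 2 µm), and each peak's z is mapped back to the nearest image
slice (`detect_peaks()`). Both peak parameters are exposed, and how they
should be set depends on the trained network at hand: a briefly trained
demonstration network separates nuclei from background less sharply than a
fully trained one, so its optimal threshold is higher. The package
therefore provides `calibrate_threshold()`, which picks the threshold by
detection F1 on annotated *validation* frames never used for testing —
ordinary detector practice. In the desk-scale experiments the suppression
radius is set to 3 µm, the generator's minimum nucleus spacing, since two
peaks closer than the closest physically possible pair of nuclei are
necessarily one nucleus. Prediction optionally averages the four in-plane
flip variants (`predict_heatmap(..., tta = TRUE)`): the network is trained
under random flips with unflipped coordinate channels, so flipping the
image, predicting and unflipping the prediction is consistent by
construction, and the averaging suppresses spurious background bumps of a
briefly trained network; the desk-scale evaluations use it.

## Gaussian shape fitting and the volume proxy

Linking and error checking need a per-nucleus size estimate. Each nucleus is
modelled as a 3D Gaussian
$$G(\vec x) = a\,\exp\left(-\tfrac12 (\vec x-\vec\mu)^T \Sigma^{-1} (\vec x-\vec\mu)\right)$$
with peak intensity $a$, center $\vec\mu$ (µm) and covariance $\Sigma$
(µm²). Fitting the whole image would also fit debris, so a segmentation
cascade first isolates plausible foreground and splits it into seeded
clusters (`segment_foreground()`):

1. per-slice adaptive threshold (local mean over a 51 px window plus an
   offset of 2% of the dynamic range — both exposed in
   `segmentation_config()`);
2. removal of voxels whose iso-intensity Gaussian curvature is negative —
   these are the saddle-shaped valleys *between* two nearby nuclei. The
   curvature is computed from Gaussian derivatives (σ = 1 voxel) via the
   implicit-surface formula $K = \nabla I\,\mathrm{adj}(H)\,\nabla I^T /
   |\nabla I|^4$; only its sign is used;
3. 3D hole filling;
4. three rounds of erosion with a 3×3×1 cross kernel, which makes touching
   nuclei fall apart into separate connected components;
5. component labelling and seed assignment.

One Gaussian per seed is then fitted *jointly per cluster* to a blurred
version of the image (σ = 2 px in xy, 0.5 slice in z), minimising the sum of
squared differences over the cluster's filled-mask voxels with bounded
least squares (`minpack.lm::nls.lm`, ≤ 200 iterations, relative tolerance
1e-6). The covariance is parameterised by its Cholesky factor so it stays
positive-definite; means are constrained to within 5 µm of their seeds;
amplitudes to [0, 2·max]. Since the pre-fit blur adds a known covariance to
every true nucleus, the fitted covariance is deconvolved (the blur
covariance is subtracted, eigenvalues floored at (0.05 µm)², amplitude
rescaled to conserve integrated intensity) so reported shapes describe the
nucleus, not the blurred image. Non-converged fits return their
seed-initialised shape flagged `unreliable`.

The **volume proxy** is `Cov(x,x)·Cov(y,y)·Cov(z,z)` — the product of the
three diagonal covariance entries. Dimensionally this is µm⁶, not a
volume; it is nevertheless used verbatim as the relative size measure
everywhere (link costs, division scoring, the volume error rules), and no
attempt is made to convert it to a literal µm³ volume. The tests show it is
stable over time for non-dividing synthetic nuclei (coefficient of
variation < 0.2).

## Global linking

A link connects a detection at frame t to one at t + 1; a division is a
detection with two outgoing links. Nearest-neighbour linking
(`nearest_neighbor_link()`, the baseline) fails on dense data — it
fragments tracks, invents divisions, and happily gives a mother three
daughters. Instead, candidate links are enumerated — for every detection,
looking both forward and backward, all partners at most twice as far as its
nearest neighbour (`generate_candidates()`) — and a globally optimal subset
is selected.

The objective (`solution_objective()`) is built from five scored rules with
multiplicative weights (defaults 20, 100, 150, 150, 30;
`link_weights()`):

* an ordinary link costs `w_link · (ΔX + ΔV/3)` with ΔX the movement in µm
  and ΔV the volume-proxy change;
* every track end and every track start costs `w_end` / `w_start`
  (favouring long tracks over fragments) — except at the movie boundary,
  where tracks legitimately begin and end, so the first/last frames are
  exempt;
* every detection left out of all tracks costs `w_ignore` (otherwise an
  empty solution would be "optimal");
* divisions carry a plausibility score
  $s = \tfrac12\,\frac{2V_m}{V_{d1}+V_{d2}} + \tfrac12\,\frac{2I_m}{I_{d1}+I_{d2}}$
  from the mother/daughter volume proxies and peak intensities. A division
  is only allowed where s ≥ 1, contributes `−w_division · (s − 1)` to the
  objective (stronger evidence, cheaper division), and halves the rule-1
  cost of the two daughter links, since nuclei genuinely move fast and
  shrink around mitosis. The exact functional form of s is this package's
  own, chosen to honour the qualitative contract (gate at 1, driven by
  volume and intensity changes); when volume proxies are missing the score
  falls back to the intensity ratio alone.

High start/end penalties relative to `w_ignore` are what suppress debris:
a debris blob that would form many short tracks is cheaper to ignore.

The optimisation is an exact 0/1 integer program (one binary per candidate
link, per gated division pair, per ignore/start/end decision;
`solve_links()`), solved with the HiGHS mixed-integer solver through the
`scipy` runtime — the contract is global optimality, and any exact method is
conformant. A tiny deterministic perturbation (1e-9 per candidate rank)
makes the returned optimum reproducible among ties; objectives are reported
from the unperturbed costs. An independent exhaustive solver
(`brute_force_link()`, depth-first enumeration with an admissible bound) is
kept in the package purely as a test oracle; the suite checks objective
equality on hundreds of random instances.

## Error flagging

`check_experiment()` applies six rules, each yielding one warning per
violation, with positions at the first/last movie frame exempt from the
appearance/disappearance rule: (1) every nucleus must link to the previous
and next frame; (2) at least 10 h (configurable) must pass before a cell on
the same lineage branch divides again — measured along the ancestor chain
to the nearest dividing ancestor; (3) movement ≤ 10 µm per frame step;
(4) a mother must outweigh her daughters combined; (5) the volume proxy may
not shrink more than 3-fold along any single link (the minimal reading of
the rule — per link, not per track); (6) no merges, no more than two
daughters. Rules 4–5 are skipped with a notice when no shapes are
available. Warnings can be suppressed (cell death, leaving the field of
view); suppression is persisted in the JSON file and survives re-checks.
`recheck_after_edit()` recomputes warnings for the edited positions and
their link neighbours only, and is required by a property test to agree
exactly with a full re-check restricted to that neighbourhood.

## Evaluation protocol

`match_detections()` assigns detections to ground-truth centers greedily in
ascending distance order, capped at 5 µm, at most one assignment per
center. Unmatched ground truth counts as a false negative; an unmatched
detection within 5 µm of *some* center is a false positive, and one further
than that from every center is *rejected* — treated as outside the
annotated region and not counted, which keeps partial annotations from
inflating the false-positive count. The greedy ascending-distance rule is a
deterministic choice (the alternative, optimal assignment, differs only in
contrived geometry). `match_links()` matches a true link when some
predicted link connects detections within 5 µm of both endpoints, one
predicted link per true link; leftover predicted links far from all
annotations at both endpoints are rejected likewise.
`precision_recall_f1()` turns counts into precision, recall and the
harmonic-mean F1, with zero-denominator cases defined as 0.

For mask-based external scorers the package writes the Cell Tracking
Challenge layout (`export_ctc()`): since the tracker produces points, each
position is drawn as a 5 µm-radius sphere on the anisotropic voxel grid,
overlap resolved by nearest position (`make_pseudo_masks()`), labelled by
track, one 16-bit TIFF per frame plus the four-column
`label begin end parent` track table. The detection/tracking accuracy
measures themselves are the external scorer's job and are deliberately not
reimplemented.

## The synthetic movie generator

Every stage is testable without real data through `simulate_movie()`. It
emulates the imaging conditions above: nuclei are anisotropic 3D Gaussian
blobs (σ ≈ 1.3–1.9 µm laterally, 1.6–2.2 µm axially, random in-plane
orientation, amplitudes 0.4–0.9 of full scale) doing a Gaussian random walk
(σ = 1 µm/frame by default — the motion scale is a free choice, stated
here because no quantitative motion statistics were available to copy),
placed with ≥ 3 µm spacing, plus static half-size debris blobs, additive
Gaussian noise (σ = 0.02), and clipping of the top 10% of the dynamic
range. Divisions replace a mother by two daughters 3.2 µm apart whose
volume proxies are each 0.42× the mother's — chosen so clean ground truth
satisfies the volume error rules by construction (sum 0.84 < 1 for rule 4,
per-link shrink 2.4 < 3 for rule 5) — and daughters wait out a minimum
cell-cycle age (default 10 h, matching the rule-2 threshold) before
dividing again. A single integer seed drives everything; per-frame noise
seeds are derived deterministically from it, so movies are bit-identical
across runs.

`degrade_ground_truth()` turns perfect ground truth into an imperfect
detector: independent misses, isotropic jitter, and binomially many uniform
spurious detections per frame. This lets linking and evaluation be tested
in a controlled detection-error regime.

**What the synthetic tests do not show.** The generator renders smooth
Gaussian blobs: no chromatin texture, no real organoid geometry (crypts,
lumen), no z-dependent attenuation, no nuclear-envelope breakdown
morphology around mitosis. Passing the synthetic end-to-end tests
demonstrates that the machinery is correct (shapes recoverable, links
globally optimal, rules firing exactly when violated), not that the tiny
demonstration network matches the detection accuracy a fully trained
network reaches on real movies.

## Problem sizes and numerical notes

The test suite and the acceptance script run everything at desk scale,
chosen so the full pipeline exercises every behaviour in minutes on one
CPU: movies of 30 nuclei × 40 frames at 16×128×128 voxels for linking and
checking; 16×64×64 volumes, 20 training volumes, 10 epochs × 20 steps ×
batch 2 for the demonstration detector; 100–200 random instances for the
solver oracle. Tolerances follow the quantities' own scales: fit recovery
is asserted at 0.5 px / 10%, solver agreement at 1e-6 absolute on
objectives, statistical checks at three standard errors. Ties in peak
suppression are broken by intensity then array order; ties among optimal
link sets by lexicographic candidate order. Degenerate inputs (empty
frames, all-zero heatmaps, all-zero targets, empty clusters) are defined
behaviours, not errors, and are covered by tests.

One printed detail of the Gaussian model deserves a note: the standard
bell-shaped density requires the −½ factor in the exponent, and that is
what `gaussian_eval()` implements. And a unit caveat repeated from above:
the "volume" everywhere in this package is the µm⁶ product proxy, useful
for ratios and comparisons, not a literal volume.

## Known limitations

* The division score is a documented stand-in honouring its qualitative
  contract, not a published formula.
* The demonstration network is small and CPU-trained; real deployments
  should train the default-size network on real annotated movies.
* The exact integer-programming solve scales comfortably to desk-scale
  movies (thousands of candidates); very long dense movies may need the
  problem split into overlapping windows, which the package does not do.
* Interactive curation is API-level only (`move_position()`,
  `delete_position()`, `add_link()`, …, plus `recheck_after_edit()`);
  there is no GUI.
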