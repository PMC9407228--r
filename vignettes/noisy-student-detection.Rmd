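---
title: "Sensitivity-calibrated noisy-student training for brain metastasis detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity-calibrated noisy-student training for brain metastasis detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nsbm)
```

## The detection problem

Small brain metastases (BM, diameters under 15 mm) enhance in post-contrast
T1-weighted 3D MRI but are easy to overlook: they are a few voxels wide at
1 mm resolution, their intensity resembles cortical vessels, and an exam
holds a quarter of a billion voxels of which only a few hundred belong to
lesions.  `nsbm` implements a two-stage detection framework plus a
semi-supervised training strategy around it:

1. **Candidate generation** — a constrained multi-scale
   Laplacian-of-Gaussian (LoG) blob detector proposes a bounded number of
   putative lesion centres per exam.
2. **Candidate classification** — a 3D convolutional patch classifier
   (the CropNet family) maps a 16 mm cubic region of interest (ROI) around
   each candidate to a probability that it contains a metastasis.
3. **Noisy-student self-training** — a lower-capacity teacher
   (CropNet-b2-16mm) trained on labeled exams pseudo-labels the candidates
   of a much larger unlabeled cohort at a response threshold `mu`
   calibrated to a target training sensitivity `ts`; a higher-capacity
   student (CropNet-b4-16mm) then trains on labeled and pseudo-labeled
   patches under data noising, with the pseudo half of the loss weighted
   by `lambda`.  The student may replace the teacher and the cycle can be
   iterated.

Detection quality is summarised by FROC curves: lesion sensitivity versus
the average number of false positives per exam (AFP), with a detection
counting a lesion as found when it lies within 1.5 mm (inclusive) of the
lesion centre.

Because cohorts of this kind are private, the package ships a synthetic
phantom generator that emulates the cohort structure and the per-lesion
statistics of such a screening population, so every stage — and the whole
loop — runs and is tested end-to-end without any clinical data.

## The models

CropNet-bX-Ymm is a contracting 3D CNN: `X` blocks of
(3^3 convolution, ReLU, dropout) per resolution level, 2x max-pooling
between levels, and a flattened single-unit sigmoid head.  The default
four-level width schedule (64, 128, 256, 512) gives ~14.1 million
trainable parameters for the b2 teacher and ~32.9 million for the b4
student; the capacity ordering (student >= teacher) is what enables
knowledge expansion in the noisy-student scheme.  The implementation is a
from-scratch RcppArmadillo network (shifted-GEMM 3D convolution, Adam),
fully deterministic under seeds.

Training is *paired*: every batch holds equal numbers of positive and
negative patches (and equally sized labeled and pseudo halves for the
student), countering the extreme class imbalance of the candidate stream.
The teacher minimises mean binary cross-entropy; the student minimises
`bce(labeled) + lambda * bce(pseudo)` with each half mean-reduced
separately, so `lambda = 1` recovers the equal weighting of classic noisy
student and `lambda = 0` degenerates to supervised training.

Threshold calibration follows the strict detection rule `response > mu`:
with `L` training lesions and per-lesion maximum teacher responses, `mu`
is the `ceiling(ts * L)`-th largest maximum, reduced by a relative nudge
of 1e-9 so that lesion still counts as detected.  Lesions that the
candidate stage never captured enter the curve as never-detected
(`-Inf`), so an unreachable `ts` raises an error reporting the achievable
peak.  Sensitivity is pooled over all training lesions rather than
averaged per exam, matching the single-threshold FROC construction.

## Data noising

Training patches are noised by (in order) Simard-style elastic
deformation (uniform(-1,1)^3 displacement field, Gaussian-smoothed with
`sigma = 4` voxels, scaled by `alpha = 2` voxels), random gamma correction
(`gamma ~ U(0.8, 1.25)`), and an axis-aligned orthogonal transform (random
90-degree rotations, per-axis flips with probability 0.5).  Defaults were
chosen so a centred lesion's intensity centroid stays within the 1.5 mm
matching tolerance across noising draws — the noising must never move a
positive patch out of "positive" semantics — and the orthogonal rotations
are interpolation-free, preserving the voxel multiset exactly.
Arbitrary-angle rotation exists behind `arbitrary_rotation = TRUE` but is
off by default for exactly that label-safety reason.  Pseudo-labeling
inference always sees un-noised patches; noise lives only inside the
training losses.

## The phantom generator

`phantom_params()` defines the synthetic exam model:

* **Geometry** — a 64^3 grid at 1 mm^3 (a desk-scale field of view; the
  generator itself accepts full-brain grids such as 192^3).
* **Lesions** — diameters follow a log-normal truncated to [2, 14] mm
  whose underlying parameters are found by numerical moment matching so
  the *post-truncation* mean and SD hit 5.45 and 2.67 mm; counts per exam
  are Poisson with mean 4.29 (zero-lesion exams allowed — they exercise
  the AFP denominator); centres are uniform in the brain ellipsoid with a
  minimum 8 mm pairwise separation within an exam so 1.5 mm matching is
  unambiguous; contrasts are uniform on 25–60 intensity units over a
  background of ~100.  Lesions are rendered as spheres with a soft
  (logistic, 0.35 mm) edge.
* **Vessels** — 3–8 random smooth polylines with a Gaussian tubular
  cross-section (radius 0.5–1.5 mm) and lesion-like contrast (30–70):
  the dominant false-positive mode of enhancing-lesion detectors.
* **Background and noise** — a smooth ellipsoidal brain with
  low-frequency texture bumps (amplitude 8), plus Rician-like noise
  (magnitude of a complex Gaussian, sigma 4).

Repeated exams of one patient draw fresh lesions: the population
statistics above are reported per patient in screening cohorts, but
training operates per exam and the generator makes no attempt to model
longitudinal persistence.  The phantom deliberately omits anatomy (tissue
classes, skull, bias fields), so passing tests demonstrate the
*mechanics* of the pipeline — capture, calibration, pseudo-labeling,
paired training, FROC bookkeeping — not clinical performance.

The population sampler `sample_lesion_population()` draws marginal
statistics (`separate = FALSE` by default) because a single brain cannot
pack thousands of separated lesions; exam assembly always enforces the
separation.

## Candidate-stage choices

The LoG stage computes the bright-blob scale-normalized response
`-sigma^2 * Laplacian(G_sigma * I)` over sigmas {1, 1.75, 2.5, 3.25, 4} mm
(blob radius ~ sigma * sqrt(3), covering 2–14 mm diameters), takes
26-connected *per-scale* spatial maxima inside the brain mask, merges them
across scales by non-maximum suppression (2 mm radius, highest response
wins), and keeps at most 300 candidates above the minimum response 0.01.
Three choices deserve explanation:

* **Per-scale maxima, not 4D scale-space maxima.**  With sigma^2
  normalization the response of broad structures grows with sigma, so in a
  joint 4D maximum a displaced coarse-scale blob frequently annihilates
  the exactly-centred fine-scale peak of a small lesion sitting near
  texture or a vessel.
* **Centre refinement.**  The scale-space peak of an 9–14 mm lesion is a
  shallow plateau whose voxel argmax wanders 1.5–3.5 mm under background
  texture.  Each surviving blob therefore proposes three centre
  hypotheses — the voxel argmax, the mean-shift centroid of the
  above-half-maximum LoG response at its own scale, and the converged
  centroid of the upper intensity range of the lightly smoothed volume —
  deduplicated at 1 mm before the candidate cap.  All three coincide for
  a symmetric blob on a flat background.
* **Pipeline normalization.**  The detector input is normalized per exam
  by mapping the 1st percentile to 0 and the maximum to 1.  A percentile
  upper anchor with clipping (the `normalize_intensity()` default maps
  p99 to 1) flattens lesion cores on desk-scale grids, where even one
  large lesion exceeds any percentile clip budget, and a clipped plateau
  has no blob response.

With the default configuration the pooled capture rate on the default
30-exam synthetic cohort is ~0.96 at <= 300 candidates per exam — the
sensitivity ceiling of everything downstream.

## The desk-scale reference benchmark

The acceptance suite exercises the full semi-supervised loop on a fixed
synthetic benchmark chosen to fit comfortably in CPU minutes:

* cohort: 12 labeled training exams, 40 unlabeled exams, 20 held-out
  labeled test exams (64^3 phantoms, default parameters, fixed seed);
* models: teacher CropNet-b2-16mm and student CropNet-b4-16mm with the
  narrow width schedule (4, 8, 16, 32) and dropout 0;
* training: Adam, learning rate 1e-3, 250 paired-batch iterations,
  teacher batches 16+16, student batches 8+8+8+8, `ts = 0.90`,
  `lambda = 1`, one student iteration, three training seeds;
* pseudo-labeling: up to 100 candidate patches per unlabeled exam.

Three desk-scale deviations from the full-scale defaults are deliberate.
First, the learning rate is 1e-3 rather than 5e-5: the full-scale recipe
pairs its small rate with 12,000 iterations, and at a few hundred
iterations that combination never leaves the initialization.  Second,
dropout is 0: with 8–16 convolution layers of only 4–32 channels,
multiplicative Bernoulli noise at every block prevents the narrow student
from optimizing at all (the wide full-scale network averages that noise
over hundreds of channels; its 0.15 rate remains the package default).
Model noising at desk scale therefore comes from the data-noising
pipeline alone.  Third, batch sizes and iteration counts are scaled to
single-CPU minutes; the full-scale compositions (150+150 and
75+75+75+75) remain the `training_config()` defaults and are asserted
exactly in the batch-contract tests.

AFP read off a 20-exam FROC curve at a fixed high sensitivity is a noisy
statistic — a single borderline lesion moves the operating threshold and
can change AFP by tens of false positives — so the benchmark's
noisy-student check compares *medians across the three seeds* at 90%
pooled sensitivity, and the lambda-interpolation check uses a
Monte-Carlo tolerance estimated from the same benchmark: the standard
deviation of the teacher's AFP across the three seeds (never below 5
AFP).  Both checks are directional analogues of the full-scale findings;
the printed clinical magnitudes are bound to the private data and are not
asserted.

## Numerical and degenerate-input behaviour

* Volumes follow the voxel-centre convention (`world = origin +
  index * spacing`, 0-based); resampling to 1 mm^3 preserves the world
  extent to within half a voxel and uses trilinear interpolation (exact
  on linear fields), with reflect-101 mirroring at boundaries everywhere
  a boundary policy is needed (smoothing, ROI extraction, elastic
  resampling).
* `normalize_intensity()` on a constant volume warns and returns zeros.
* Binary cross-entropy clips responses to [1e-7, 1 - 1e-7].
* Candidate ordering breaks response ties lexicographically by centre, so
  ranks are reproducible; all randomness (phantom structure and noise,
  initialization, batch sampling, noising, dropout) is driven by logged
  integer seeds and every pipeline stage is bitwise reproducible under
  them.
* Exact-zero ReLU outputs can tie inside max-pooling windows; the
  backward pass routes gradient to the first maximising child, a valid
  subgradient choice.

## Known limitations

* The phantom is a geometry-and-statistics emulator, not an anatomical
  simulator; absolute AFP values on phantoms say nothing about clinical
  AFP.
* The from-scratch network trains on one CPU core; full-scale
  (64–512-channel, 12,000-iteration) training is supported by the code
  paths but is hours of compute and is not exercised by the tests.
* Candidate detection assumes isotropically resampled, normalized input;
  feeding raw anisotropic volumes is a contract violation, not a handled
  case.
* `run_experiment()` reproduces the sweep layout (ts, lambda, student
  iterations, labeled fraction) at configurable scale; the tests run a
  single small cell.
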