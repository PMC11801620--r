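---
title: "Methods: random-forest segmentation and morphometry of collagen fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest segmentation and morphometry of collagen fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilseg)
```

## The problem

Transmission electron micrographs of extracellular-matrix collagen show
fibril cross-sections as bright disks wrapped in a darker rim, on a mid-gray,
noisy, often blotchily stained background. Neither the bright interior nor
the dark rim is a well-defined boundary, so global thresholding is unreliable
and manual annotation is subjective: two readers can disagree on a fibril's
area by a factor of two or more simply by choosing different edges. Yet the
quantities of biological interest -- how many fibrils there are, how large
they are, and how their sizes are distributed -- all hinge on exactly that
edge decision.

`fibrilseg` replaces the per-image human decision with a trainable pixel
classifier: a small bank of contrast- and edge-sensitive filters turns each
pixel into a feature vector, a random forest votes fibril vs background, and
fixed post-processing plus instance-level morphometry turn the votes into
counts, diameters and size distributions. Once trained on a handful of
annotated images, the same frozen model is applied to every image of a
study, so edge definitions are consistent across time points by
construction.

## The pixel classification model

Each micrograph is held on a continuous 0--255 intensity scale (16-bit
inputs are rescaled linearly) and expanded into nine feature channels, in a
fixed order shared by training and prediction:

| # | channel | definition | parameters |
|---|---------|------------|------------|
| 1 | `raw` | intensity | -- |
| 2 | `canny` | Canny edge map, coded 0/255 | hysteresis 100/200 on the Sobel magnitude |
| 3 | `roberts` | $\sqrt{g_1^2+g_2^2}$ of the two 2x2 diagonal kernels | -- |
| 4 | `sobel` | $\sqrt{G_x^2+G_y^2}$, 3x3 | -- |
| 5 | `scharr` | as Sobel with 3/10 weights | -- |
| 6 | `prewitt` | as Sobel with unit weights | -- |
| 7 | `gaussian_s1` | Gaussian smoothing | $\sigma = 1$ px |
| 8 | `gaussian_s3` | Gaussian smoothing | $\sigma = 3$ px |
| 9 | `median3` | square median filter | 3x3 window |

The raw channel carries the interior-brightness signal (fibril interiors are
identified by intensity, not only by edges); the gradient magnitudes respond
to both the inner and outer boundary of the rim; the two smoothing scales
give the classifier denoised context. The channel list is closed on
purpose: no texture features, no multiscale pyramid. `stack_to_table()`
flattens stacks to one row per pixel (image order, then row-major scan) --
that tibble is literally what the forest trains on.

A note on two parameter readings that the configuration records explicitly:
a median filter has a window, not a sigma, so the "size 3" median is
implemented as a 3x3 window; and the Canny channel is written 0/255 to stay
on the common intensity scale (a 0/1 coding is available via
`feature_config(canny_scale = 1)` and is forwarded with the model, so
training and prediction can never disagree about it).

The classifier is a random forest with **8 trees** (`ranger`, single
thread, seeded; other tree parameters are the library defaults, frozen into
the model metadata). Pixels pooled across all training images are split
80/20 at random; the 20 % holdout provides the pixel-accuracy estimate
stored with the model. The per-pixel fibril probability is the fraction of
the 8 trees voting fibril, and the hard class is probability >= 0.5 -- an
exact 4--4 tie counts as fibril, a fixed rule chosen so prediction is
deterministic. When several reviewer annotations exist per training image,
one is chosen at random per image (seeded, `mask_selection_seed`), which
folds between-reviewer edge variability into the training signal instead of
averaging it away.

## Post-processing and instance extraction

The raw class map is rendered 0/255, blurred with a **7x7 Gaussian kernel**
and binarized at **100**: single stray fibril pixels cannot survive (the
kernel's central weight times 255 stays far below the threshold) while
solid blobs are reproduced up to a one-pixel boundary shift. The kernel's
sigma is not implied by its size; the package fixes $\sigma = 1.1$ px, a
common size-derived choice, and exposes it in the configuration so it is
auditable. The blur is applied to the hard class map by default; blurring
the probability surface instead (`postprocess_input = "prob"`) is available
but changes the operation from denoising a segmentation to thresholding a
confidence field, so it is not the default. No morphological opening,
closing, hole-filling or watershed splitting is performed -- the cleanup is
exactly blur + threshold, and touching fibrils therefore merge (see
Limitations).

Instances are 8-connected components (ImageJ's particle-analysis
convention; 4-connectivity is available), labeled 1..K in row-major scan
order. All coordinates in the package are 1-based `[row, col]` with the
origin at top-left, matching R matrix semantics.

## Morphometry

Each instance's area is `pixel_count * pixel_size^2`; instances outside
**10--5000 nm²** are discarded as specks and merged clumps. Because every
size statistic scales with the calibration, `pixel_size` (nm/px) is a
required input everywhere -- there is no default, and a TIFF x-resolution
tag is used only when explicitly requested.

Each surviving instance gets a moment ellipse in the equal-area (ImageJ)
convention: orientation and axis ratio come from the second central moments
(with the 1/12 within-pixel variance added to both diagonal moments), and
both axes are rescaled so $\pi \cdot \text{major} \cdot \text{minor} / 4$
equals the region's area exactly. The **minor axis is the reported
diameter**, which is insensitive to oblique sectioning (a tilted cylinder
elongates only the major axis). Degenerate regions -- a single pixel, or
collinear pixels, detected as a vanishing transverse eigenvalue *before*
the 1/12 correction -- return the equal-area circle.

Size distributions use **14 bins of 10 nm spanning 10--150 nm**,
left-closed right-open except the last bin [140, 150], which is closed so a
150 nm diameter is not dropped. Diameters outside 10--150 nm remain in the
fibril count and the mean (the area filter, not the histogram, is the
exclusion rule) but are not histogrammed; fractions are normalized by the
in-range total. The mean diameter is taken over all area-filter survivors,
not only histogram-range fibrils -- both are computable, and the survivors'
mean is the default because the filter is the single declared exclusion
rule.

Fibrils touching the image border are measured by default
(`exclude_border = TRUE` is available); their truncated areas are part of
what the area filter already governs.

## Evaluation machinery

*Consensus ground truth.* Three reviewer masks are merged by pixel-wise
2-of-3 majority, which deletes single-reviewer outlier strokes. Consensus
instances pass through the same 10--5000 nm² area filter as measurement, so
the ground-truth count $N_{GT}$ and the measured counts are commensurable.

*Matching.* Every overlapping (predicted, ground-truth) instance pair gets
an IoU (intersection over union of pixel sets). Pairs are assigned greedily
in descending IoU, each instance used at most once, ties broken by
(predicted label, ground-truth label) so matching is deterministic. A
prediction whose assigned IoU is at least **0.33** is a true positive;
everything else, including unassigned predictions, is a false positive, so
$TP + FP$ equals the number of predictions. The threshold is deliberately
looser than the conventional 0.5 because rim ambiguity alone can change an
instance's area severalfold without the detection being wrong. False
negatives are implicit: $FN = N_{GT} - TP$.

*Metrics.*

$$P = \frac{TP}{TP+FP}, \qquad R = \frac{TP}{N_{GT}}, \qquad
F_1 = \frac{2PR}{P+R}.$$

Multi-image reports pool $TP$, $FP$ and $N_{GT}$ across images for the
combined row -- pooled counts, never averaged per-image metrics. Agreement
of measured quantities with truth is summarized by the parity $R^2$
against the identity line,
$1 - \sum (y_i - x_i)^2 / \sum (y_i - \bar y)^2$: the reference line of a
parity plot is truth itself, not a fitted regression (the squared Pearson
correlation of a fitted line is available as `method = "fit"`). Identity
$R^2$ can be negative when disagreement exceeds the measured spread; that
is informative, not an error. Percent errors are
$100\,|m - t|/t$. Metrics are conventionally read at three decimals;
package tests compare at $|\Delta| \le 0.0005$.

## The synthetic phantom

`simulate_micrograph()` draws what the evaluation needs and nothing more:
circular fibril cross-sections with a bright interior and a 2 px darker rim
on a mid-gray background -- reproducing the two-boundary ambiguity that
motivates the classifier -- plus additive Gaussian noise and smooth
blotches mimicking stain artifacts. Truth is recorded before noise, so it
is exact. Defaults: 256 x 256 px at 2 nm/px, 25 fibrils, diameters
truncated-normal (60, 10) nm within (10, 150), background/interior/rim gray
levels 120/170/70, noise sd 10, 3 blotches. The recorded "true" diameter is
the full disk extent *including* the rim, and the truth mask covers the
same extent, so recovered-diameter bias is directly interpretable.

Placement is dart throwing with a minimum edge-to-edge gap of 3 px and a
bounded retry budget. Two numerical details matter: all diameters are
sampled *before* placement and kept through center retries (re-drawing a
diameter after a failed placement would bias the accepted population toward
small fibrils -- the truncated-normal sampling test is sensitive enough to
catch this), and larger disks are placed first, which keeps dense packings
feasible without changing the sampled population.

`simulate_reviewer()` models annotation imperfection per fibril: omission
with a set probability, and dilation or erosion by a disk of radius drawn
from `-jitter_px..jitter_px`, emulating differing edge definitions. Three
such reviewers feed the consensus machinery in tests exactly as real
reviewers would.

What the phantom does *not* emulate: elliptical or irregular cross-section
shapes, touching or overlapping fibrils, intensity gradients across the
field, correlated (structured) noise, and any physical image-formation
model. Passing the synthetic end-to-end test therefore demonstrates that
the pipeline's machinery is correct and well-calibrated in an easier regime
than real tissue; it does not certify performance on dense, low-contrast
real micrographs.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on generated data.
The end-to-end study trains on five 256 x 256 px synthetic micrographs
(about 3.3 x 10^5 labeled pixels) and segments five held-out ones; the
acceptance run makes the ten images heterogeneous (15--30 fibrils per
image, mean diameters 46--66 nm) because parity $R^2$ is degenerate when
every image shares one condition -- the measured between-image spread in
its denominator vanishes. Oracle-equivalence properties (flood-fill
labeling, exhaustive-assignment matching, direct-tabulation histograms,
per-pixel vote consensus) each run on at least one hundred randomized small
instances under fixed seeds.

Every stochastic step -- diameter sampling, placement, noise, reviewer
jitter, mask selection, the 80/20 split, forest fitting -- is governed by
explicit seeds, and prediction is vote-counting, so identical
configuration plus seeds reproduce every mask, table and report bit for
bit. Classifier artifacts carry their feature schema and configuration and
refuse to predict on a mismatched stack.

## Known limitations

- Touching fibrils are not split: blur + threshold is the entire cleanup,
  so dense packings undercount and the area filter removes large fused
  clumps entirely.
- The area filter silently removes genuine fibrils above ~80 nm diameter
  (area > 5000 nm²); with size laws concentrated well below that, the
  effect is negligible, but heavy-tailed populations would need the bounds
  revisited in configuration.
- Holdout pixels are drawn from the same images as training pixels, so the
  stored holdout accuracy estimates within-image generalization only; new
  imaging conditions deserve fresh held-out images.
- The identity-line $R^2$ is sensitive to the spread of the measured
  values; comparisons across studies should fix the set of images.
- The classifier is per-pixel: no shape prior, no connectivity constraint.
  The forest can be retrained for other bright-interior/dark-rim features,
  but the defaults encode collagen-in-TEM contrast behavior.
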