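# fibrilseg

Random-forest pixel classification and morphometry of collagen fibril
cross-sections in grayscale electron micrographs.

Transmission electron micrographs of extracellular-matrix collagen show
fibril cross-sections as bright disks with a darker, ambiguous rim on a
noisy mid-gray background. Manual thresholding of such images is
subjective — the choice of edge can change a fibril's apparent area
severalfold — and inconsistent across time points. `fibrilseg` makes the
edge decision once, by training a pixel classifier on a handful of
annotated images, then applies the same frozen model everywhere: it is
aimed at microscopists and image analysts who need consistent fibril
counts, diameters and size distributions across a study.

## The method

1. **Feature bank.** Each pixel becomes a 9-vector: raw intensity; a Canny
   edge map (hysteresis 100/200); Roberts, Sobel, Scharr and Prewitt
   gradient magnitudes; Gaussian smoothing at σ = 1 and σ = 3 px; and a
   3×3 median. All channels live on a common 0–255 scale.
2. **Random forest.** 8 decision trees vote fibril vs background per
   pixel, trained on a seeded 80/20 split of pixels pooled across the
   annotated images; the 20 % holdout accuracy is stored with the model.
   The fibril probability of a pixel is the fraction of trees voting for
   it.
3. **Post-processing.** The 0/255 class map is blurred with a 7×7 Gaussian
   kernel and thresholded at 100, removing salt noise; 8-connected
   components become fibril instances.
4. **Morphometry.** Instances outside 10–5000 nm² are discarded; each
   survivor gets an equal-area moment ellipse (ImageJ convention) whose
   **minor axis is the diameter**, robust to oblique sectioning. Size
   distributions use 14 bins of 10 nm over 10–150 nm.
5. **Evaluation.** Ground truth is the 2-of-3 majority of three reviewer
   masks. Predicted and ground-truth instances are matched one-to-one by
   descending IoU; a prediction with IoU ≥ 0.33 is a true positive, and

   P = TP / (TP + FP),  R = TP / N_GT,  F1 = 2PR / (P + R),

   with multi-image results pooling TP, FP and N_GT. Agreement of measured
   counts, mean diameters and bin fractions with truth is summarized by
   the parity R² against the identity line.

A seeded synthetic-micrograph generator (bright disks with dark rims,
noise, stain blotches, imperfect simulated reviewers) provides exact
ground truth, so the entire pipeline is testable without any real imagery.
Pixel calibration (nm/px) is a required input throughout — a wrong default
would silently corrupt every size statistic, so there is none.

## Worked example

Train on five synthetic micrographs, segment a held-out sixth, quantify
and evaluate:

```r
library(fibrilseg)
library(purrr)

cfg  <- fibril_config(pixel_size = 2, seed = 1)   # nm per pixel is mandatory
sims <- map(1:6, ~ simulate_micrograph(sim_config(seed = .x)))

clf <- fibril_train(map(sims[1:5], "micrograph"),
                  map(sims[1:5], ~ .x$truth$mask), cfg)
glance(clf)
#>   n_trees n_channels n_images n_pixels holdout_fraction holdout_accuracy  seed
#> 1       8          9        5   327680              0.2            1.000     1

seg <- fibril_segment(clf, sims[[6]]$micrograph, cfg)
q   <- fibril_quantify(seg, cfg)
q$summary[, 1:4]
#>   image_id  n_fibrils mean_diameter_nm sd_diameter_nm
#> 1 sim_seed6        24             58.1           14.9

gt  <- consensus_mask(rep(list(sims[[6]]$truth$mask), 3), pixel_size = 2)
rep <- evaluate_segmentation(seg, list(gt), pixel_size = 2)
tidy(rep)[, c("image_id", "n_gt", "n_pred", "tp", "fp",
              "precision", "recall", "f1")]
#>   image_id  n_gt n_pred    tp    fp precision recall    f1
#> 1 sim         23     24    23     1     0.958      1 0.979
#> 2 combined    23     24    23     1     0.958      1 0.979
```

The held-out image truly contains 25 fibrils of mean diameter 61.6 nm,
two of which fall above the 5000 nm² area cap, hence N_GT = 23. The model
recovers 24 instances at mean 58.1 nm — 23 of them matching ground truth
at IoU ≥ 0.33 — i.e. precision 0.958, perfect recall, F1 0.979, and a
mean diameter within 6 % of truth. The small negative diameter bias comes
from the classifier placing the edge just inside the dark rim.

`autoplot()` methods produce the diameter histogram
(`autoplot(summarize_fibrils(q$fibrils))`) and the count parity plot
(`autoplot(rep)`); `tidy()`/`glance()` return tibbles ready for dplyr.

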