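---
title: "Growing a wound-segmentation dataset with transfer learning and active semi-supervised learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing a wound-segmentation dataset with transfer learning and active semi-supervised learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Supervised segmentation models need pixel-accurate masks, and manually
tracing wound boundaries on clinical photographs is slow, expensive and
subjective. When a related *source domain* already has a trained model (for
example, a human-wound segmenter applied to veterinary images of dogs and
cats), most of that annotation effort can be avoided: the pretrained model
proposes masks, a reviewer merely **accepts or discards** each proposal, and
accepted proposals become training labels. Iterating this
review-train-predict cycle is active semi-supervised learning (ASSL). The
package implements that loop end to end, together with a synthetic
wound-image generator so the whole pipeline can be exercised, tested and
benchmarked offline with exact ground truth.

## The training loop

One **round** of ASSL consists of:

1. reset the model weights to the pretrained (source-domain) configuration;
2. train on the current labelled pool — whose labels are previously accepted
   *predicted* masks, not manual annotations — for a fixed number of epochs;
3. evaluate F1 and IoU on a held-out validation split of the pool;
4. predict a mask for **every** image in the dataset;
5. validate every prediction (simulated oracle or recorded human decisions);
6. promote newly accepted unlabeled images into the labelled pool.

Round 0 is special: the pretrained model predicts on all images with no
fine-tuning, and the accepted predictions form the initial pool, substituting
entirely for manual annotation.

The labelled pool is split 90/10 into training and validation
(`n_val = max(1, round(0.1 n))`). The validation subset is drawn once, at the
first trained round, and frozen; newly accepted samples enter training only.
This avoids leaking ever-easier accepted samples into the metric set and
mirrors the fixed validation counts one expects in a practical run. Accepted
masks are permanent: they are never re-validated, which makes the pool
monotone non-decreasing — the defining ratchet of the procedure. Rejected
images are re-predicted afresh every round, since the model has changed.

The loop stops when the accepted fraction over the whole dataset reaches the
target (default 80%), after `max_rounds`, or when the accepted count has not
improved for `plateau_patience = 2` consecutive rounds.

Per-round seeds are derived as `seed + round_index`, so a run is exactly
reproducible while rounds remain distinct.

## The validation oracle

Reviewers apply three binary criteria: (i) the mask must cover the entire
wound; (ii) it must cover *only* the wound — no holes, no spurious parts;
(iii) its shape must follow the correct boundary. These are qualitative
judgements; the simulated oracle used for synthetic runs and tests makes them
quantitative against ground truth:

| criterion | predicate | default |
|---|---|---|
| i, coverage | recall ≥ `min_coverage_recall` | 0.90 |
| ii, only wound | precision ≥ `min_precision`, hole area ≤ 1% of mask, no component beyond the largest | 0.90 / 0.01 / 0 |
| iii, boundary | symmetric mean contour distance ≤ 2% of the image diagonal | 0.02 |

Every threshold is a package decision (the clinical criteria carry no
numbers), chosen once so that a perfect mask always passes and each synthetic
corruption mode at severity ≥ 0.3 fails exactly its targeted criterion. The
oracle consumes masks only — never image pixels — so it is a pure,
reproducible stand-in for the reviewer. Holes are measured as
enclosed-background area via fill-hull, components by connected-component
labelling, and boundary distance by averaging, in both directions, the
distance from each 4-connected contour pixel to the nearest contour pixel of
the other mask.

We considered a stricter coverage bar (0.95); it produces cleaner
pseudo-labels but starves the pool of the marginal samples that drive
learning, and the loop stalls. 0.90 is the better operating point.

## The model and its loss

The segmentation model is a U-Net-style encoder-decoder implemented natively
(RcppArmadillo): 3×3 same-padding convolutions with leaky-ReLU, 2×2 average
pooling, nearest-neighbour upsampling with skip concatenation, and a 1×1
sigmoid head. The default `tiny` backbone has 3 resolution levels and base
width 8 (~61k parameters); it trains end-to-end on one CPU at 64×64 in
minutes, which is what makes the full loop testable at desk scale. (A base
width of 16 quadruples the arithmetic for no qualitative change in behaviour;
width 8 keeps a five-round benchmark inside a coffee break.) The
`mobilenet_v2` and `efficientnet_b3` names select wider/deeper presets of the
same family — capacity stand-ins that preserve the parameter-count ordering
of the full-scale architectures they allude to, not reproductions of them.

Training minimises the **binary focal loss**

$$
\mathrm{BF}(y, p) = -\alpha\, y (1-p)^\gamma \log p
\;-\; (1-\alpha)(1-y)\, p^\gamma \log(1-p),
$$

with defaults $\alpha = 0.25$, $\gamma = 2$, probabilities clipped to
$[10^{-7}, 1-10^{-7}]$, and mean (not sum) reduction so the value is
resolution-independent. A `beta` parameter is carried alongside alpha and
gamma for interface completeness but plays no role. With $\gamma = 0,
\alpha = 0.5$ the loss is exactly half the binary cross-entropy, which the
tests exploit as an independent check. The optimiser is Adam; the reference
protocol is 100 epochs per round at learning rate $10^{-5}$, which assumes a
strongly pretrained full-scale backbone. Desk-scale runs on the tiny backbone
train from random initialisation, so the benchmark uses 20 epochs per round
at $10^{-3}$ — reduced epochs, proportionally raised rate. Augmentation is
restricted to horizontal and vertical flips, each applied with probability
0.5 to image and mask jointly.

### The binarization threshold is not 0.5

An asymmetric loss de-calibrates the sigmoid output. At a pixel whose true
foreground posterior is $q$, the loss-minimising prediction solves

$$
\min_p\; \alpha q (1-p)^\gamma(-\log p)
+ (1-\alpha)(1-q)p^\gamma(-\log(1-p)),
$$

and at $q = 1/2$ (even evidence) the minimiser is **not** 0.5: for
$\gamma=0$ it is exactly $\alpha$, and for the default
$\alpha=0.25,\gamma=2$ it is ≈ 0.399 (`focal_neutral_threshold()`).
Binarizing at a flat 0.5 therefore under-segments systematically — predicted
contours sit inside the true boundary, most visibly on low-contrast wounds —
and, worse, the shrunken masks become training labels, so the loop amplifies
its own bias. The pipeline consequently binarizes at the loss-matched
neutral threshold by default; `binarize()` itself keeps the conventional 0.5
default for standalone use.

## The synthetic data generator

The generator emulates the statistical structure of a heterogeneous clinical
photo collection, not its appearance:

* **Wound shape**: a union of 1–3 overlapping random ellipses (subsequent
  centres inside the first), rasterised by bisection on a uniform scale so
  the area fraction lands in the configured range (default 5–25% of the
  image). Single connected component and zero holes hold by construction.
* **Wound appearance**: a dark-red hue family with radial darkening and
  speckle noise, alpha-blended over the background with a narrow (σ = 0.4 px)
  soft edge so that the photometric wound extent matches the binary truth —
  a wide soft edge makes "the correct boundary" ill-defined for model and
  oracle alike.
* **Backgrounds**: skin-like (smooth tan field), fabric-like (striped, cool
  hues) and flat-colour families; red hues are excluded from backgrounds,
  as a curated clinical dataset would exclude red-dominated scenes.
* **Lighting**: per-image global gain (0.7–1.3) and gamma (0.8–1.25),
  emulating exposure and illumination variability across devices; a
  four-level camera tag emulates device heterogeneity.
* **Difficulty**: a fraction (default 0.5) of samples are "hard": their wound
  colour is blended toward the background by a factor drawn from a
  *continuum* (default 0.25–0.65). The continuum is essential: the
  source-trained model initially solves only the easy end, and each round's
  acceptances include slightly harder samples that teach the model to handle
  harder ones still. A bimodal easy/hard split (no continuum) freezes the
  loop — we verified this directly.

The pre-training base set (the transfer-learning source domain) is drawn from
the same generator with a different seed and three systematic differences a
curated clinical source dataset would have: no fabric backgrounds, a milder
difficulty profile (30% hard, blends 0.1–0.35), and a **controlled
acquisition protocol** — lighting gain 0.9–1.1 and gamma 0.95–1.05, against
the target's unstandardised 0.7–1.3 / 0.8–1.25. The base model is fitted to
convergence (80 epochs). Both choices matter mechanistically:

* *Convergence*: an under-trained source model still has large gradients on
  easy samples, so fine-tuning on the accepted pool drifts away from the
  robust source features instead of extending them.
* *The lighting gap*: it gives the loop a domain shift it can actually close.
  Exposure robustness is a low-dimensional, global property — once a few
  unusually lit target samples are accepted, the retrained model generalises
  across the whole lighting range and unlocks entire strata of the target
  set. That closable gap, not raw difficulty, is what drives the
  round-on-round growth a transfer-learning + ASSL run exhibits; with an
  identical-lighting source the loop saturates a few points short of the
  target, because extrapolating along the contrast continuum alone is slow.

The pretrained base is a documented stand-in for an unavailable source-domain
model, not a replication of one.

Mask corruptions (`corrupt_mask()`) target the three criteria for testing:
erosion (under-coverage), interior removal at a depth scaled by severity
(holes), disjoint blobs placed away from the mask (spurious), and a
smoothed-noise boundary displacement that preserves area within ±10% by
quantile re-thresholding with deterministic retries (boundary jitter).
Severity 0 is the identity in every mode; effects scale monotonically.

## The desk-scale benchmark

`assl_benchmark()` is the package's headline experiment: 200 synthetic
images (generator seed 42, default difficulty), the tiny backbone pretrained
on the disjoint base set, at most 5 rounds of ASSL with the simulated oracle
at default thresholds, 20 epochs per round. Round 0 accepts roughly
three-quarters of the dataset; closing the lighting gap then lifts the
accepted fraction past the 80% target within the first rounds, reproducing
the qualitative trajectory of a real transfer-learning + ASSL run (partial
initial acceptance, monotone pool growth, high and stable validation F1/IoU
throughout). The whole benchmark takes a few minutes on one CPU.
`scripts/acceptance.R` re-runs exactly this benchmark.

What passing this benchmark does **not** show: anything about photorealistic
wounds, fur, specular highlights, perspective, or inter-observer
disagreement. The generator produces none of those; results on synthetic data
bound the pipeline's correctness, not its clinical performance.

## Numerical choices and degenerate inputs

* Metric conventions: any 0/0 ratio is 0, except that two entirely empty
  masks score 1 on every metric (an empty prediction of an empty reference is
  perfect). These cases never arise from the generator; the convention is for
  API completeness.
* An empty *predicted* mask fails validation (coverage and boundary) rather
  than erroring; an empty *reference* mask is an error — there is nothing to
  cover.
* Masks are stored as {0, 255} single-channel PNG only (JPEG would corrupt
  labels); on read, values above 127 are foreground and any other value
  triggers a warning with a count of coerced pixels.
* Images are resized bilinearly to the model input size; predicted masks are
  upsampled back nearest-neighbour, so labels stay hard.
* All randomness flows from explicit seeds: the generator seed, the training
  seed (C++ `mt19937` driving initialisation, shuffling and flips), and the
  per-round derived seeds. Two runs of any seeded command are byte-identical.
* Problem sizes in the test suite: 32×32 images for model unit tests, 50
  images for the structural-invariant run, 200 for the benchmark — chosen so
  the whole suite runs in well under half an hour on one CPU.

## Human-in-the-loop use

On real data there is no ground truth and the oracle is a person.
`render_overlay()` draws the predicted contour in green with a translucent
fill over the image for review; decisions are recorded per sample in a CSV
(`sample_id, accepted`) and fed back via the `decisions` argument of
`run_round()`/`run_assl()`, which errors listing any sample that still lacks
a decision. The thin command-line front end (`inst/cli/woundassl`) covers
generation, pretraining, oracle-mode runs, mask-directory validation and
report printing.

## Known limitations

* The synthetic domain is deliberately austere; no claim is made about
  transfer to photographic wound images.
* The two larger backbone presets share the tiny preset's architecture family
  and exist for capacity-scaling experiments, not for fidelity to the
  architectures they are named after.
* Inter-observer variability between reviewers is not modelled; the simulated
  oracle is a single deterministic reviewer.
* EXIF orientation metadata in JPEG input is not honoured; images are
  consumed as stored.
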