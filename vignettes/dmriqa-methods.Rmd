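---
title: "Hierarchical no-reference quality assessment for diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical no-reference quality assessment for diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmriqa)
```

## The problem

Diffusion MRI sessions acquire dozens to hundreds of 3D volumes per
subject, and pediatric acquisitions in particular are riddled with motion
artifacts: ghosting along the phase-encode axis, signal dropout in slices,
blurring, and elevated noise. Deciding — quickly, and without a pristine
reference image — whether a slice, a volume, or a whole session is usable
is the quality-assessment (QA) problem this package addresses. Two
practical constraints shape the design:

* **Annotations are scarce.** Rating every volume of every subject is
  prohibitively expensive, so only a small labeled set is available next
  to a much larger unlabeled pool.
* **Annotations are noisy.** Raters typically label whole volumes (or
  sessions), and every slice inherits its volume's label even though
  volumes mix good and bad slices; rater error adds further noise.

The package implements a three-stage hierarchy. A **slice network**
(`sqa_net`) rates each sagittal slice pass / questionable / fail. A
**volume network** (`vqa_net`) agglomerates the slice feature maps of one
volume and rates the volume. **Subject ratings** are rule-based over the
volume ratings. Training combines supervised pretraining, semi-supervised
pseudo-labeling, and iterative self-training that relabels or removes
unreliable training records.

## Networks

Feature maps are `h x w x c` arrays. Four blocks compose the slice
network:

* **DSConv** — a 3x3 depthwise convolution followed by a 1x1 pointwise
  convolution (`9 c_in + c_in c_out` weights instead of `9 c_in c_out`).
* **DSR** — two DSConv/batch-norm/ReLU stages, a 2x2 max-pool, and a
  1x1-stride-2 convolutional shortcut summed with the pooled main path.
* **NLDR** — a DSR block with a nonlocal attention branch inserted as a
  residual add immediately before pooling.
* **NLR** — an identity shortcut around a nonlocal branch:
  `y = x + nonlocal(x)`.
* **CLF** — 3x3 convolution to 3 channels, global average pooling,
  softmax.

The nonlocal operation computes, at each position `i`,

$$ r_i = \frac{1}{C_i(x)} \sum_{\forall j} f(x_i, x_j)\, g(x_j), \qquad
   f(x_i, x_j) = \exp\!\big(\phi(x_i)^\top \psi(x_j)\big), $$

with `C_i(x) = sum_j f(x_i, x_j)`, so each row of attention weights is a
softmax over all positions; `phi`, `psi`, `g` are learned 1x1
convolutions. `g` maps back to the input channel count so the branch can
be added residually; `phi` and `psi` embed into `c/2` channels. The
attention matrix is row-stochastic by construction, which the test suite
asserts against a naive double-loop implementation.

SQA-Net is `DSR(32) -> DSR(64) -> NLDR(128) -> NLDR(256) -> NLR -> CLF` on
144x144 inputs (each DSR/NLDR halves the spatial size, so the NLR feature
map is 9x9x256). The third-stage channel count is read as 128: the
channel progression doubles at every stage, and the ablated variant of
the architecture family is described with a 128/256/512 progression, so a
printed "28" is treated as a dropped digit. VQA-Net reduces each slice's
NLR features to 16 channels with a shared 1x1 convolution, concatenates
the `n_s` reduced maps along the channel axis (slice order is therefore
part of the input contract), and applies an NLR and a CLF block.

The package's default spec quarters all channels and runs on 64x64 inputs
(`net_spec(64)`), which keeps every fit on a single CPU in seconds; the
acquisition-scale geometry is available via `net_spec(144, n_slices =
60)`.

No deep-learning framework is used: forward and backward passes for the
convolutions, batch norm, pooling, attention, and the RMSprop optimizer
are implemented in the package (C++ kernels for convolution/pooling, R
for the rest), and every layer's gradient is verified against finite
differences in the test suite.

## Loss

Both networks minimize a class-balanced focal loss with L2
regularization:

$$ L(p_t) = -\alpha_t (1 - p_t)^{\kappa} \log(p_t)
   + \frac{\lambda}{2 n_w} \sum_w \lVert W_w \rVert_2^2, $$

where `p_t` is the predicted probability of the true class,
`alpha_t = max(N_1, N_2, N_3) / N_t` balances class frequencies (slice
counts for the slice network, volume counts for the volume network), and
the `n_w` weight matrices cover convolution and attention weights but not
biases or batch-norm parameters. Defaults: `lambda = 0.01`; the focusing
exponent `kappa` defaults to 2, the conventional focusing strength, and
is exposed in `train_config()` because results can be sensitive to it.
Probabilities of exactly zero are clamped to `1e-7` with a warning rather
than raising an error.

## Training stages

`train_config()` collects every tunable:

| parameter | default | meaning |
|---|---|---|
| `th_s` | 0.9 | slice confidence threshold, strict (`>`), shared by pseudo-labeling and slice self-training |
| `th_v` | 0.9 | volume confidence threshold, strict |
| `ssl_iters` | 2 | pseudo-label/retrain rounds |
| `st_iters` | 2 | self-training rounds per stage |
| `lr`, `decay` | 1e-5, 5e-8 | RMSprop step size and its per-step decay (acquisition scale) |
| `kappa`, `lambda` | 2, 0.01 | loss parameters |
| `batch_size` | 32 | slices per gradient step |

1. **Pretraining** fits SQA-Net on the labeled slices (labels inherited
   from volume annotations), with rotation (0–30 degrees) and horizontal
   flip augmentation at training time only.
2. **Semi-supervised learning** predicts every unlabeled slice and merges
   those whose maximal probability strictly exceeds `th_s` into the
   labeled pool (provenance `pseudo`), then retrains; pseudo-labels are
   refreshed from scratch each round. Convergence ("until improvement is
   minimal") is implemented as a fixed round count (default 2) combined
   with a per-round model-selection guard: after every retraining round
   the model's accuracy against the stored labels of the original labeled
   pool is measured; a round that degrades that accuracy by more than
   0.5% is rejected (model and relabeling revert to the best state so
   far, the audit log is kept) and iteration continues. The same guard
   protects the slice and volume self-training loops, where an occasional
   diverged refit would otherwise relabel the pool with confident
   mistakes.
3. **Slice self-training** keeps a slice if its prediction agrees with
   its current label *or* clears `th_s`; confident disagreements are
   relabeled (provenance `relabeled`), everything else is removed
   (provenance `removed`, retained in the table but excluded from
   training and never re-admitted). Pseudo-labeled slices are treated
   identically to inherited-label slices. At the first round "previous
   prediction" means the stored label — the only defined predecessor.
4. **Volume initialization** rates unlabeled volumes by rule from their
   predicted slice labels: pass if strictly more than 60% of slices pass;
   fail if more slices fail than *each* of the other two counts;
   questionable otherwise. The alternative reading of the middle rule
   (fail exceeding the *sum* of the others) is available via
   `init_volume_label(..., rule2 = "sum")`; the per-count reading is the
   default because it is the natural-language reading, and the totality
   and consistency of both are checked by exhaustive enumeration.
5. **VQA training** fits the volume network on slice features from the
   frozen slice model (the slice model is shared, not fine-tuned, so the
   refined slice stage is preserved), followed by volume self-training
   with `th_v`.
6. **Subject rules**: pass if more than 80% of a subject's volumes pass;
   fail if more than 20% fail; questionable otherwise. These two rules
   can never both fire, which the tests verify by enumeration.

Setting `ssl_iters = 0` and `st_iters = 0` reduces the pipeline exactly
to supervised pretraining plus rule-based volume initialization; the
iteration counts therefore accept zero.

### Numerical choices

* **Batch norm** uses batch statistics during training and running
  averages at inference. Because fits here are short, running averages
  lag the weights; after every fit the running statistics are re-estimated
  as the equal-weight mean of per-batch moments over the unaugmented
  training set ("precise" re-estimation). Convolutions feeding a
  batch-norm layer carry no bias.
* **Residual ordering** is post-activation: the sum carries no extra
  activation, and each DSR/NLDR main path has exactly two DSConv stages.
* **Argmax ties** break toward the more severe label — conservative for
  quality control.
* **Preprocessing**: slices are zero-padded to the target canvas
  (asymmetric remainders go to the bottom/right) and min-max normalized
  *after* padding, so background zeros participate in the range; a
  constant padded array maps to all zeros. Rotation angles are drawn from
  `[0, 30]` degrees; mirror diversity comes from the random horizontal
  flip.
* **Determinism**: every stochastic step (initialization, shuffling,
  augmentation, simulation) derives from the seed in the configuration
  objects; two runs with identical configuration are bit-reproducible.

## The synthetic cohort

No clinical data ships with the package. `sim_config()` /
`generate_split()` emulate the structure of a pediatric dMRI QA dataset:

* a brain-like phantom per slice (elliptical support, smoothed random
  tissue texture, bright rim) — anatomy varies from slice to slice;
* four severity-graded artifact processes applied in order: half-FOV
  ghosting, zeroed horizontal dropout bands, Gaussian blur, and bounded
  Rician-style magnitude noise with a small floor, all magnitudes
  non-decreasing in a scalar severity in `[0, 1]`;
* slice severities drawn from per-class Beta mixtures (defaults:
  `Beta(2, 10)` for pass-type volumes, `Beta(8, 8)` for questionable,
  `Beta(10, 2.5)` for fail), thresholded at `(0.3, 0.6)` into true slice
  labels; the volume's true label follows from the volume decision rule;
* volume class frequencies matching the 85/25/40 training balance of the
  cohort the simulator stands in for;
* **weak labeling** (every slice stores its volume's label, provenance
  `inherited`) and **exact-count volume label flips** (`flip_rate`) as
  the two label-noise mechanisms.

The default fixture is 4 subjects x 12 volumes x 16 slices of 64x64 — a
scale at which the full pipeline runs on one CPU in about a minute — with
the acquisition geometry (151 volumes x 60 slices at 144x144) available
through the configuration. The label-noise recovery study
(`recovery_experiment()`) uses one labeled subject with 20% volume flips,
two unlabeled subjects, and one accurately annotated test subject, with
five seeded replicates; the desk-scale training configuration
(`toy_train_config()`: RMSprop at 1e-3 with per-step decay 0.005, 10
pretraining epochs, 3 epochs per retraining round) was chosen for this
scale. Two stabilizers matter at desk scale: the decay schedule persists
across retraining rounds of the same model, so refinement refits take
progressively smaller steps, and the convergence guard described above
reverts any refit that degrades accuracy on the stored training labels —
without them, occasional fits drift into a confidently wrong state that
self-training then amplifies.

What the simulator does *not* emulate: real brain anatomy, eddy-current
or susceptibility distortions, b-value/gradient structure, rater-specific
error patterns, or subject-level artifact correlation. Passing the
recovery study therefore demonstrates that the machinery behaves as
designed under controlled label noise — pseudo-labeling expands the
training pool with mostly-correct labels, self-training cleanses flipped
annotations, and neither stage degrades held-out volume accuracy — not
that the printed clinical performance figures transfer. Those figures are
covered in this package only by recomputing the published metric tables
from their confusion matrices.

## Known limitations

* Whole slices are used as input; no brain masking is applied, so
  background could dilute attention at acquisition scale.
* The refinement stages train sequentially, not end-to-end.
* The focusing exponent `kappa` is not pinned by the method's source
  description; sensitivity to it is not explored here.
* The desk-scale study uses small subject counts, so subject-level
  metrics on synthetic data are coarse (steps of 1/12 at volume level).
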