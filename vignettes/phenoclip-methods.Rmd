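---
title: "Methods: language-informed cell phenotyping across marker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: language-informed cell phenotyping across marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiplexed tissue imaging (CODEX, MIBI, IMC, CycIF and related platforms)
measures tens of protein markers per cell in situ. Assigning each segmented
cell a type — cell phenotyping — is the step that turns these images into
biology. The obstacle to doing it at scale is heterogeneity: every
experiment images a different marker panel, with different marker names,
on a different platform with its own intensity characteristics. A
classifier with a fixed input layer cannot transfer between panels.

`phenoclip` treats the panel itself as part of the input. Each channel of a
cell becomes a *token*: the sum of a CNN embedding of the channel's image
patch and a language-model embedding of the marker's name. A transformer
attends across the token set — channel-wise attention, not spatial
attention — so the architecture is indifferent to how many markers there
are and in what order they arrive. Classification is contrastive: the
cell's summary embedding is compared by cosine similarity to embeddings of
cell-type *names*, so the candidate label set can be chosen freely at
inference time ("prediction-set binding"), including restriction to the
types plausible for a tissue.

## Input representation

Images are resampled to 0.5 microns per pixel (nearest neighbor, no
anti-aliasing; the index rule is documented in `?resample_to_mpp` and
fixed exactly so tests can be bitwise). Each channel of each field of view
is clipped at the 99th percentile of its non-zero pixels and min-max
scaled to [0, 1]. For every segmented cell a 64x64 patch is cut, centered
on the integer-rounded mask centroid, with two binary context planes: the
self-mask (the cell's own pixels) and the neighbor-mask (all other cells'
pixels). Cells near the image boundary are zero-padded to a complete
patch. A cell with panel size C is therefore a (C, 3, 64, 64) tensor
(stored in R as dim `(64, 64, 3, C)`); batches are zero-padded to a fixed
channel capacity `C_max` with a padding mask, and padded slots never enter
the computation.

Degenerate channels follow two conventions chosen for determinism: an
all-zero channel passes through unchanged, and a constant non-zero channel
normalizes to zero (min = max), preserving "no contrast, no signal".
Multi-fragment mask labels are centered on the overall mask centroid; we
do not attempt anything cleverer. Resampling precedes normalization in the
pipeline; the two orders differ only through the percentile estimate, and
fixing one makes runs reproducible.

## Architecture

* **Image encoder.** One CNN shared by all channel slots (the batch is
  reshaped so every channel of every cell is an independent image). The
  reference configuration is 11 conv layers, kernel 3, padding 1,
  interleaved strides 1 and 2, each followed by SiLU and then batch
  normalization (in that order), widths doubling from 16 to 256, global
  average pooling, and a linear map to the model dimension. Because of the
  reshape, batch-norm statistics pool over all channel slots; they are
  frozen (running estimates) at evaluation.
* **Text encoder.** A pluggable provider produces a raw embedding per
  marker or cell-type name (`D_raw`, 8192 for a large language model;
  256 in the desk-scale default). One learnable linear map projects raw
  embeddings to the model dimension; it is trained jointly with the rest
  of the network, since it sits inside the gradient path of every loss.
  The default provider is deterministic and offline: it templates a
  description and hashes it to a seeded pseudo-random unit vector, so
  distinct terms are near-orthogonal and runs are reproducible without
  network access. It provides no biological semantics — swapping in a real
  language model changes the vectors but nothing else.
* **Channel-wise transformer.** Tokens are image + text embeddings per
  real channel, with a learnable [CLS] token prepended (it attends to
  itself; both conventions are defensible and this one is fixed here).
  There is deliberately no positional encoding: self-attention is then
  invariant to channel order and count, which is the property that lets
  one model serve every panel. Pre-norm blocks are used for small-scale
  stability, with a final layer norm.
* **Heads.** (i) Cell type: cosine similarity between the [CLS] embedding
  and projected type-name embeddings, scaled by a learnable temperature
  parameterized as `exp(log tau)` with initial value 0.07 (the common
  contrastive default). (ii) Marker positivity: the final layer's
  [CLS]-to-channel attention, averaged over heads and rescaled by the
  per-cell maximum so the top marker scores 1 (`pos_mode = "max"`; a
  sum-normalized variant is available — the normalization recipe is a
  documented choice, and any monotone rescaling leaves ranking metrics
  such as AUC unchanged). (iii) Modality: a 3-layer MLP behind a
  gradient-reversal layer.

## Losses and training

The objective is `w_cls * L_cls + w_pos * L_pos + lambda(e) * L_adv`.

* `L_cls` is a focal CLIP loss with focusing parameter gamma = 2: rows of
  the image- and text-embedding matrices are L2-normalized, the similarity
  matrix is softmaxed along both axes, and the negative log-likelihood of
  the matched diagonal is weighted by `(1 - p_t)^gamma`, averaging the two
  directions. `gamma = 0` recovers plain symmetric CLIP; one pair gives
  exactly zero. Batches pair each cell with its own type-name embedding,
  so same-type cells appear as mutual "negatives"; the type-level gradient
  still points the right way (it cancels only when same-type similarities
  are already equal), and this follows the loss as specified rather than
  de-duplicating.
* `L_pos` is binary cross-entropy between the attention positivity scores
  and expert gating labels with label smoothing 0.2, using the convention
  `t -> t(1 - s) + s/2`. Scores are clamped to `[1e-6, 1 - 1e-6]` because
  the max-rescaled top channel sits exactly at 1. Only real, labeled
  channels enter the mean; a batch with no labels contributes zero with a
  warning.
* `L_adv` is cross-entropy of the modality head with label smoothing 0.01.
  The head itself trains on the plain gradient; the trunk receives the
  gradient negated and scaled by `lambda(e) = w_adv * e^(1/4)` — the
  quartic-root ramp of the current (1-based) epoch index, read as
  "current epoch" because a constant would not ramp. Epochs 0, 1 and 16
  give weights 0, `w_adv` and `2 w_adv`.

Training uses RAdam (implemented here; reference settings learning rate
1e-4, 20 epochs), random flips and 90-degree rotations applied identically
to all three planes of every channel, dropout of `k = 8` marker channels
per cell per draw (clipped so at least one channel survives; dropped
channels lose their text token too), and Gaussian noise (sd 0.005) added
to marker and type embeddings at every batch draw — per draw, not per
term, since the stated purpose is stochastic regularization. Random
rescaling is not implemented; on 64x64 patches grid-preserving transforms
keep the mask semantics exact, and this is a known departure from the
full augmentation menu. A stratified 90/10 split per type provides
epoch-level validation, and the best-validation parameters are kept. The
weights `w_cls = w_pos = 1` and `w_adv = 0.1` are defaults; none of these
three values is prescribed by the reference description.

All randomness flows from explicit seeds through R's RNG; the compiled
core contains none, so a fixed seed reproduces corpora, initializations
and training histories bit-exactly.

## The synthetic benchmark

`default_benchmark_spec()` defines the simulation used throughout the
tests: 12 markers (CD45, CD3, CD4, CD8, CD20, CD68, CD11c, Pan-Keratin,
E-cadherin, Vimentin, CD31, aSMA), four types (T cell, B cell,
macrophage, epithelial) with disjoint on-marker sets, log-normal
intensities (on level 0.7, off 0.02, per-cell log-jitter sd 0.25 —
strictly positive and heavy-tailed like staining data), elliptical cells
placed by rejection sampling with some cells adjacent to the image
boundary, 5% blurred spillover between two spectrally plausible channel
pairs (CD4 to CD8, Pan-Keratin to E-cadherin), additive background noise
(sd 0.01), and two modalities differing in gain (1.0 vs 1.7), offset
(0.005 vs 0.03) and blur (0.5 vs 1.0 px). Three datasets carry panels of
12, 9 and 7 markers at ~500 cells each; the 7-marker dataset shares a
modality with the first and is held out of training entirely, so
evaluating on it is a zero-shot panel transfer.

What the generator does *not* emulate: real tissue architecture,
segmentation errors, cell-type-dependent morphology, autofluorescence
structure, or marker co-expression gradients. Passing the simulation
shows the machinery — panel-agnostic fusion, contrastive binding,
attention gating, adversarial invariance — works as designed; it does not
certify accuracy on real consortium data.

The desk-scale configuration (`benchmark_model_config()`,
`benchmark_train_config()`) is a faithful miniature: model dimension 64,
2 transformer layers, 4 heads, a 5-layer CNN (widths 8-64, all-stride-2
cascade) on a 2x average-pooled input, provider dimension 256, 20 epochs
of RAdam at learning rate 1e-2 with batch size 64 and 2-channel dropout.
The pooled input and hot learning rate are deliberate: at 0.5 micron
resolution a 2x pool still resolves cell-scale morphology, and a ~40k
parameter model that sees only a few hundred optimizer steps needs a far
larger step size than the full-scale setting. Problem sizes (1,500 cells,
64x64 patches, 20 epochs) were chosen as the smallest study at which
every mechanism is measurable.

On this benchmark the expected behavior (recomputed by
`benchmark_experiment()` and the test suite, not quoted from anywhere) is
near-ceiling held-out and zero-shot macro F1, attention positivity that
separates true-on from true-off markers, and a mean-intensity XGBoost
baseline that collapses under zero-shot panel transfer: markers never
missing in training have untrained missing-value routing, which is
precisely the failure mode a panel-agnostic model avoids. The linear
modality probe deserves a caveat: in this design panel identity, dataset
and modality coincide, so even a perfectly style-invariant representation
retains legitimately modality-predictive content (which markers exist),
and the probe should be read as a relative comparison between the
adversarial and ablated models, not against an absolute floor.

## Numerical choices

* Double precision throughout; analytic gradients for every parameter are
  validated against central finite differences in the tests.
* Percentiles use the linear-interpolation convention (R type 7).
* Ties in nearest-neighbor resampling resolve to the upper source pixel;
  ties in argmax classification resolve to the lowest candidate index.
* Batch-norm variance uses the population convention in the forward pass
  and the unbiased correction in the running estimate; epsilon 1e-5.
* Zero-norm embedding rows in the contrastive loss are guarded with an
  epsilon and a warning rather than an error, since they arise transiently
  during training.
* The corpus store keeps the chunked hierarchical layout
  (`datasets/<id>/{patches.bin, meta.json, cells.csv, positivity.csv}`)
  with raw little-endian doubles; round-trips are bit-exact.

## Limitations

The offline embedding provider carries no biology: results with it
measure the architecture, not the value of language priors. Training here
is in-memory and single-threaded; the reference-scale configuration (75
channel slots, 8192-dimensional embeddings, millions of cells) would need
an accelerator framework and out-of-core loading. Global tissue context
beyond the 64x64 neighborhood is out of scope, as are segmentation itself
and label consolidation maps, which are user-supplied inputs.
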