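---
title: "Cross-fusion of PPI networks and protein attributes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-fusion of PPI networks and protein attributes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfuseGO)
```

## The problem

Experimentally annotating protein function is slow and expensive, so most
proteins carry no curated Gene Ontology (GO) terms. Two genome-scale data
sources carry complementary functional signal: the weighted
protein–protein interaction (PPI) network (here in STRING style, with a
combined confidence score per edge) and binary biological attributes of
each protein (Pfam domains and subcellular locations). Graph neural
networks are the common way to combine them, but message passing can
propagate the noise of spurious edges and deep stacks over-smooth node
representations. This package instead *cross-fuses* the two sources with
multi-head self-attention over a two-token sequence — one token per
source — so each source's representation attends to the other without any
message passing on the graph itself.

## Model

For protein $i$, source 1 is the $i$-th column $x_i^{(1)} \in [0,1]^{N}$ of
the min–max normalized weighted adjacency matrix (global normalization over
all $N \times N$ entries, structural zeros included; the diagonal is 0 as
self-interactions are not modelled). Source 2 is the bag-of-words attribute
vector $x_i^{(2)} \in \{0,1\}^{d_2}$ over the domain vocabulary (terms
occurring fewer than 6 times are dropped) concatenated with the
subcellular-location vocabulary.

Each source is projected to a common dimension $d$ by a two-layer MLP

$$\mathrm{MLP}(x) = f(\mathrm{LN}(W_2\, f(\mathrm{LN}(W_1 x + b_1)) + b_2)),$$

with $f$ the GELU and $\mathrm{LN}$ layer normalization, exactly in this
order (normalize, then activate). The two projected tokens then pass
through $L$ multi-head attention layers. Each layer is a post-norm
transformer block: multi-head attention
$\mathrm{Concat}(\mathrm{head}_1,\dots,\mathrm{head}_n)W^O$ with
$\mathrm{head}_j = \mathrm{softmax}(QW_j^Q (KW_j^K)^\top/\sqrt{d_k})\,VW_j^V$
and $d_k = d/n$, followed by dropout, a residual connection and layer
normalization, then a position-wise feed-forward network
$W_2 f(W_1 h + b_1) + b_2$ with the same wrapping. With only two tokens,
self-attention *is* the cross-fusion: each source mixes in the other,
weighted by learned relevance.

**Pre-training.** An encoder–decoder reconstructs both sources for *every*
network protein (annotated or not). The decoder mirrors the encoder
($L$ attention layers, then one inverse MLP per source with a sigmoid
output layer) with independent, untied parameters. The objective is the
per-protein summed binary cross-entropy, averaged over proteins; the
normalized network column is a soft target in $[0,1]$, for which BCE is
well defined.

**Fine-tuning.** A two-layer predictor
$\sigma(W_o\,\sigma(W_h (h^{(1)} \| h^{(2)}) + b_h) + b_o)$ maps the
concatenated embedding tokens to $K$ GO-term scores. Both activations are
logistic sigmoids. Training minimizes the asymmetric loss

$$\mathrm{ASL} = \frac{1}{N_{tr} K}\sum_{i,k}
  -\big[y_{ik}(1-p_{ik})^{\gamma^+}\log p_{ik}
  + (1-y_{ik})\,p_{ik}^{\gamma^-}\log(1-p_{ik})\big],$$

with $\gamma^+ = 0$, $\gamma^- = 2$: easy negatives — the overwhelming
majority in multi-label GO prediction — are down-weighted quadratically.
With both exponents 0 the loss reduces exactly to mean BCE (asserted in
the tests). The schedule has two phases: the encoder is frozen while the
predictor trains, then both train jointly at much smaller learning rates.
The optimizer is AdamW throughout ($\beta = (0.9, 0.999)$, weight decay
0.01).

## Data preparation rules

* Only experimentally supported annotations are used; the accepted
  evidence codes are IDA, IPI, EXP, IGI, IMP, IEP, IC and TA. The set is
  an argument of `filter_evidence()`; "TA" is kept verbatim as the default
  (callers that use TAS-coded data can pass their own set).
* CAFA-style temporal split with cutoffs $t_0$ = 2018-01-01 and $t_1$ =
  2020-12-31: a protein with any annotation on or before $t_0$ is a
  training protein; otherwise, with any annotation in $(t_0, t_1]$, a
  validation protein; otherwise a test protein. Dates are compared at day
  resolution and both boundaries are inclusive on the earlier side.
* A GO term is retained only if it has at least 10 training, 5 validation
  and 1 test positives, and does not annotate more than 5% of the
  network's proteins (a term at exactly the cap is kept — the rule is
  "more than").
* Term and vocabulary orderings are lexicographic so matrices are
  bit-reproducible across runs. GO ancestry propagation is deliberately
  not performed: annotations are taken at their most granular term and
  high-frequency terms are removed by the 5% cap instead.
* For the final fit, training and validation sets are merged
  (`merge_train_val()`, the default in `finetune_config()`).

**The 5% cap at synthetic scale.** The minimum-positive thresholds
(10, 5, 1) require at least 16 annotated proteins per term, which is more
than 5% of any network smaller than 320 proteins — at the 200-protein
synthetic scale the two default rules are arithmetically incompatible.
The function defaults keep the full-scale values; every synthetic-scale
run in this package passes `max_network_fraction = 0.5` explicitly as a
data-scale parameter. The boundary semantics of the 5% rule are still
unit-tested at the default.

## Evaluation

`evaluate_predictions()` computes: micro-AUPR over the flattened
label/score matrices and macro-AUPR as the unweighted mean of per-term
AUPRs (zero-positive terms are excluded and counted), both as step-wise
average precision with tied scores grouped (no trapezoidal
interpolation — tie-safe and standard for PR curves); top-3 F1 (each
protein's three best-scored terms are predicted, ties at the cut broken by
term order for reproducibility, and the per-term confusion matrices are
summed before the harmonic mean); exact-match accuracy at threshold 0.5;
and the protein-centric Fmax, scanning thresholds 0.01–1.00 in steps of
0.01 (τ = 0 is excluded, where every protein is trivially covered), with
precision averaged only over proteins that have at least one score at or
above the threshold and thresholds with no such protein skipped.
Representation quality is measured by the Davies–Bouldin index (Euclidean
distances, arithmetic centroids) over clusters of proteins with exactly
identical GO-term sets; unannotated proteins have no cluster key and are
excluded from the index, but remain in Fmax's protein count.

## Synthetic data: what it emulates and what it does not

`synth_generate()` produces the three raw inputs the preparation stage
parses, with a planted module structure that makes recovery measurable:

* a planted-partition network: edge probability `p_in` (default 0.3)
  within modules, `p_out` (0.02) between, integer weights uniform on
  200–1000 and independent of module membership, so the weights carry no
  extra signal;
* module-linked attributes: each of the 4 modules has a characteristic
  template over 30 domain + 10 location terms (each term in a template
  with probability 0.4); a protein's attributes are its module's template
  with independent bit flips (`attribute_flip_rate`, default 0.1);
* module-linked labels: 2 of 8 GO terms per module, flipped
  per-(protein, term) at `label_noise_rate` (default 0.1);
* annotation records: each positive pair emits 2 records with independent
  dates and evidence codes drawn from a pool that mixes the eight
  experimental codes with IEA and ISS, so the evidence filter discards
  records without usually erasing labels. Dates are drawn around a
  per-protein center (uniform over 2015–2022) with ±60 days of
  record-level jitter: annotation campaigns cluster in time, and — more
  practically — fully independent record dates would send almost every
  protein to the training set, leaving the temporal split degenerate at
  n = 200.

Defaults were chosen once as the desk-scale study conditions. The
generator does **not** emulate scale-free degree distributions, hub
proteins, GO-DAG term dependence, aspect-specific signal, or the extreme
label sparsity of real annotation corpora; passing the recovery tests
therefore shows the pipeline is correct and can extract a planted
module-to-function signal, not that it matches published benchmark
figures on real STRING data.

## Numerical choices

* Probabilities are clipped to $[10^{-7}, 1 - 10^{-7}]$ before logs in
  both losses; gradients treat the clip as the identity.
* Layer normalization uses biased variance and $\epsilon = 10^{-5}$, with
  learnable gain and bias.
* Weights are Glorot-uniform, biases zero, all drawn from the seeded R
  RNG; every training function is a deterministic function of its config
  seed (shuffling and dropout included), which the tests assert bitwise.
* GELU is the exact form $x\,\Phi(x)$; the test oracles use the
  erf-based expression independently.
* Gradients are hand-derived (there is no automatic differentiation here)
  and validated against central finite differences at $10^{-4}$ relative
  tolerance on random parameter subsets.
* Degenerate inputs error early with named causes: all-equal adjacency
  weights, an empty attribute vocabulary after the frequency filter, no
  surviving GO terms (the message names the eliminating filter), labels
  without positives, a single term-set cluster.

## Design decisions where the architecture was open

* **Post-norm** sub-layer order (Add → Norm), matching the cited
  transformer architecture; dropout is applied to each sub-layer output
  before its residual add (rate 0.1 in encoder/decoder, 0.3 on the
  predictor hidden layer).
* **No positional encoding**: the two tokens are already distinguished by
  their source-specific MLPs, and the attention layer is deliberately
  permutation-equivariant (tested).
* **Decoder symmetry** is read as mirrored dimensions with independent
  parameters, not weight tying; the hidden inverse-MLP layer keeps
  normalize-then-activate, the output layer applies a plain sigmoid with
  no normalization.
* **Predictor activations** are logistic sigmoids in both layers — the
  predictor's printed formula is followed literally rather than
  substituting the GELU used elsewhere.
* At the **unfreeze boundary** the encoder gets a fresh AdamW state (its
  first-phase gradients were never computed); the predictor keeps its
  accumulated state and only changes learning rate.
* **Single-source ablations** drop the missing token and run attention
  over a length-1 sequence (the softmax of a singleton is the identity);
  the predictor concatenates the lone embedding with itself to keep its
  input width.

## Desk-scale problem sizes

The recovery experiments used by the test-suite and the acceptance script
run at sizes chosen for a laptop CPU: 200 proteins, embedding $d = 32$
($d_e = 24$, 4 heads, feed-forward width 64, $L = 2$, predictor hidden 16),
200 pre-training epochs (learning rate $10^{-3}$ halved-phase to
$10^{-4}$) and 60 fine-tuning epochs (30 frozen; predictor
$10^{-2}$ then $10^{-3}$, encoder $10^{-4}$). The published full-scale
settings ($d = 512$, $d_e = 1024$, 8 heads, $L = 6$, 5000 + 100 epochs at
learning rates $10^{-5}$/$10^{-6}$) remain the package defaults in
`model_config()`, `pretrain_config()` and `finetune_config()`; at a few
hundred epochs those learning rates would barely move the parameters, so
the desk-scale runs scale them up rather than silently under-train. The
ablation and null-signal comparisons use a further reduced setting
($d = 16$, $L = 1$, 100 + 40 epochs) so that multi-seed averages stay
cheap.

The "signal removed" null condition sets `p_in = p_out` and
`attribute_flip_rate = 0.5` (a flipped coin per attribute bit), so neither
source carries module information; the test then requires the model's
micro-AUPR to sit within three standard deviations (across five seeds) of
the prevalence baseline that scores every protein by the training-set
label frequencies.

## Known limitations

* Training is plain R matrix code: fine at desk scale, not meant for
  full STRING-scale networks (no GPU, no minibatch parallelism).
* No GO-DAG consistency post-processing, ontology-aware propagation,
  Smin-style semantic metrics, calibration or ensembling.
* The checkpoint format is R's native serialization; it is not
  interoperable with other frameworks.
* Proteins absent from the PPI network are dropped (with a warning): the
  network source is defined only for network proteins.

## A minimal run

```{r example, eval = FALSE}
ds <- synth_generate(synth_spec(attribute_flip_rate = 0,
                                label_noise_rate = 0, seed = 7))
prep <- preprocess_dataset(ds$network, ds$domain_annotations,
                           ds$location_annotations, ds$annotations,
                           aspect = "BPO", max_network_fraction = 0.5)
fit <- crossfuse(prep$network_features, prep$attributes, prep$split,
             model = model_config(d = 32, de = 24, n_heads = 4,
                                  d_ff = 64, L = 2, dh = 16),
             pretrain = pretrain_config(epochs = 200, phase1_epochs = 100,
                                        lr_phase1 = 1e-3, lr_phase2 = 1e-4,
                                        seed = 7),
             finetune = finetune_config(epochs = 60, freeze_epochs = 30,
                                        lr_predictor_phase1 = 1e-2,
                                        lr_encoder_phase2 = 1e-4,
                                        lr_predictor_phase2 = 1e-3,
                                        seed = 8))
summary(fit, split = prep$split)
```
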