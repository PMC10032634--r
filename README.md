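# crossfuseGO

Multi-label protein function prediction by **cross-fusing** a weighted
protein–protein interaction (PPI) network with binary protein attributes
(Pfam domains, subcellular locations) through multi-head self-attention.
The package is aimed at computational biologists who want a fully
self-contained, CPU-scale implementation of attention-based network +
attribute fusion for Gene Ontology (GO) term prediction — including the
CAFA-style data preparation rules, the evaluation suite, and a synthetic
planted-module generator so everything runs and is testable without any
external downloads.

## The model

Each protein contributes two feature vectors: its column
$x^{(1)} \in [0,1]^N$ of the globally min–max-normalized weighted
adjacency matrix, and its bag-of-words attribute vector
$x^{(2)} \in \{0,1\}^{d_2}$ (domain terms occurring < 6 times are
filtered out). Per source, a two-layer MLP
$f(\mathrm{LN}(W_2 f(\mathrm{LN}(W_1 x + b_1)) + b_2))$ (GELU $f$, layer
norm LN) projects into a shared $d$-dimensional space; the two resulting
tokens pass through $L$ post-norm transformer blocks whose self-attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ (with $n$ heads, $d_k = d/n$)
realizes the cross-fusion. Training has two stages:

1. **Self-supervised pre-training** — a mirrored decoder reconstructs both
   sources for every network protein under summed binary cross-entropy.
2. **Fine-tuning** — a two-layer sigmoid predictor on the concatenated
   embedding $(h^{(1)} \| h^{(2)})$ minimizes the asymmetric loss
   $-[\,y(1-p)^{\gamma^+}\!\log p + (1-y)p^{\gamma^-}\!\log(1-p)\,]$
   with $\gamma^+{=}0$, $\gamma^-{=}2$, encoder frozen for the first half
   of the epochs. Optimizer: AdamW.

Data preparation follows the CAFA temporal protocol (experimental
evidence codes only; proteins routed to train/validation/test by
annotation date around the cutoffs 2018-01-01 and 2020-12-31; GO terms
kept only with ≥ 10/5/1 positives per set and annotating ≤ 5% of network
proteins). Evaluation implements micro/macro AUPR, top-3 F1, exact-match
accuracy, protein-centric Fmax, and the Davies–Bouldin index over
identical-term-set clusters. Forward and backward passes are hand-written
base-R matrix code, validated against finite differences and loop-based
formula oracles in the test suite.

## Worked example

Generate a noise-free planted-module dataset (200 proteins, 4 modules,
2 GO terms each), prepare it, fit, and evaluate on the held-out temporal
test set:

```r
library(crossfuseGO)

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

which prints (about half a minute on one CPU):

```
Held-out (test set) performance:
Protein function prediction evaluation
  m-AUPR: 0.9771   M-AUPR: 0.9620   F1(top-3): 0.7870
  ACC: 0.9464   Fmax: 0.9864 (tau = 0.08)
  Davies-Bouldin: 0.9159
```

The model recovers the planted module → GO-term signal almost perfectly:
micro-AUPR 0.98 against a prevalence-baseline 0.25, exact-match accuracy
0.95, and tightly clustered embeddings (low Davies–Bouldin). Top-3 F1 is
lower by construction — every protein carries exactly two true terms, so
a forced third prediction is always a false positive.

`predict(fit)` returns the protein × term score matrix;
`plot(fit)` shows both loss histories. A thin command-line wrapper with
`simulate` / `run` / `ablate` / `evaluate` subcommands is installed at
`inst/scripts/crossfuse-go.R`.

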