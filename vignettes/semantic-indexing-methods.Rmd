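---
title: "Methods: hierarchical semantic indexing with a convolutional-Boltzmann network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical semantic indexing with a convolutional-Boltzmann network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biomedical citation databases index each article with several headings from a
controlled vocabulary (for PubMed, MeSH). For most articles only the title and
abstract are available, the label space is large and severely unbalanced, and
labels are correlated. `semindex` implements a complete, offline-testable
pipeline for this multi-label assignment problem: a fixed-length
word-sequence document representation enriched with category and entity
information, a small convolutional feature extractor, a two-hidden-layer deep
Boltzmann machine (DBM) with label units that fuses the convolutional features
with a global entity vector, and a coarse-to-fine classifier over clusters of
label embeddings, evaluated with the standard macro/micro multi-label metric
family.

## Document representation (DSE)

Documents are lowercased, split on non-alphanumeric characters, stop-worded
(list shipped in `inst/extdata/stopwords_en.txt`) and Porter-stemmed
(`porter_stem()`, a from-scratch implementation of the 1980 algorithm; words
of one or two characters are returned unchanged). Title and abstract are
concatenated, title first — nothing downstream distinguishes them.

Every document is then fitted to the corpus average token count
`L = max(1, floor(mean))`:

* shorter documents are padded with the reserved `UNKNOWN` token, whose
  embedding defaults to the zero vector;
* longer documents keep high-frequency words: distinct words ranked by
  in-document frequency (ties broken by earliest occurrence) are included
  whole until the next word would overflow `L`, which then contributes its
  earliest occurrences only. Kept tokens preserve their original order, so
  the result is always a subsequence of the input. These two tie/overflow
  rules are this package's choices; frequency-based truncation alone does
  not determine them.

Each position is widened to 4 words: the token itself plus three extension
slots filled from (in priority order) the token's entity class, then its
category terms, then the token itself. Entity-before-category priority is our
choice — entities are the domain's emphasised signal. Each of the 4 words is
replaced by its `d`-dimensional embedding, giving an `L x 4d` matrix (with
the conventional `d = 50`, rows of length 200).

## Category meta-features

With `n` words, `m` document classes and `t` categories, the package builds
`P1` (`n x m`, word-in-class probabilities, counted over all classes of
multi-label documents and row-normalised) and `P3` (`t x m`, category
occurrences of anchor words per class; empty categories get a uniform row and
are flagged). The word-category matrix `P2` (`n x t`) is recovered from
`P1 ≈ P2 P3`: anchor words are set to the uniform distribution over their
listed categories, and each non-anchor row solves the simplex-constrained
least-squares problem `min ||P1[i,] − p P3||²` by accelerated projected
gradient (FISTA with sort-based simplex projection). The estimation rule
itself is a design choice — a topic-model-style inference would also fit the
same data flow (`P1`, `P3` → `P2`) — but constrained least squares is
deterministic and recovers a planted `P2` exactly under full-rank `P3`,
which the tests exploit. Whether anchor rows should be re-estimated jointly is unknown; we
fix them and estimate the rest.

During training, non-anchor words whose estimated category probability
clearly exceeds uniform (`> 1.5/t`) receive their argmax category for
enrichment (`use_estimated_categories`).

## Entities

Entity recognition is a greedy longest-match lexicon tagger; production
systems typically use a trained CRF tagger here, and because the lexicon is
an input file, real tagger output can be dropped in. Spans never overlap. The
global entity feature `y_e` — required only to have the same length as the
CNN output `y_c` — is the bag of entity-class counts mapped through a fixed,
seeded random projection with unit-norm columns and rescaled to unit max-abs;
documents without entities get the zero vector. Both constructions are pure
functions of their inputs and a seed.

## Convolutional feature extractor

The first convolution stage uses kernels spanning `h` positions by `d`
feature columns, sliding with stride `d` across the 4 sub-vector slots and
stride 1 down positions (valid convolution, no padding) — windows therefore
never cut through a word embedding. Each feature map passes through k-max
pooling (the `k` largest values along the position axis, original order
preserved, ties to the earliest position), a per-map gain `β` and bias, and
the activation; the layer equations are

```
a1 = f(conv2(A, K) + b1)
a2 = f(β down(a1) + b2)
yc = f(w a2 + b)
```

with the activation applied *after* pooling, exactly as the second equation
is written. Hidden activations are ReLU; the final fully-connected layer is
sigmoid because its output feeds the Boltzmann fusion. Inverted dropout
(default rate 0.5) acts on convolutional and hidden fully-connected
activations in training mode only, so inference is the deterministic mean
network. Deeper stages see the flattened pooled maps (positions × channels)
with full-width kernels. All forward operators have brute-force oracle tests
and the backward pass is verified against central finite differences
(relative error < 1e-4); note `relu'(0) = 0` by convention, so gradient
checks probe generic points.

## Deep Boltzmann machine with label units

The visible layer fuses the two document views:
`V = sigmoid(C y_c + E y_e)`. Two hidden layers follow, with label units
attached to the top layer:

```
h1  = sigmoid(V W1)                      (2 W1 at test time)
h2  = sigmoid(h1 W2 + tar Wlab + bias1)
h1' = sigmoid(V W1 + h2 W2' + bias2)
h2' = sigmoid(h1' W2 + tar Wlab + bias3)
```

All states are mean-field activations in `[0, 1]`; no Bernoulli sampling is
used by default, making training and prediction deterministic (a `sample`
flag exists for fidelity experiments). The weight doubling `2 W1` is applied
only to the test-time bottom-up pass, compensating for the missing top-down
input when labels are unknown. The reconstruction `V' = sigmoid(h1 W1' +
visible bias)` is the standard undirected form; the contrastive update is the
pure CD-1 difference of outer products, so identical positive and negative
states give exactly zero updates — a property the tests assert. Layer-wise
RBM pretraining (CD-1, first `(V, h1)` then `(h1, h2)`) initialises the
stack; zero epochs returns the seeded random initialisation. `bias1` and
`bias3` both feed `h2` but are kept separate, as the equations are written.

At test time the chain `h1 (doubled) → h2 → h1' → h2' → scores =
sigmoid(h2' Wlab')` is a pure function of `(V, params)` and is fully
differentiable; `dbm_backward()` provides exact gradients for every
parameter (finite-difference-checked).

## Hierarchical coarse-to-fine classification

Label embeddings (word2vec text format) are clustered by seeded k-means
(k-means++ initialisation, Euclidean distance, Lloyd iterations, default
`C = 10` clusters). A document's coarse targets are the clusters containing
any of its labels. Squared-error losses drive both levels:

```
E    = 1/(N C)   Σ_C Σ_N (sigmoid(w x + b) − y)²      (coarse)
J_k  = 1/(n_k N) Σ       (sigmoid(w_k x + b_k) − y)²   (fine, per cluster)
```

Updates to different clusters' weights are independent. Prediction selects
clusters with coarse score ≥ `τ_coarse` (argmax fallback), then labels with
fine score ≥ `τ_fine` inside selected clusters, with a best-single-label
fallback; labels outside selected clusters are never returned. Both
thresholds default to 0.5, the natural midpoint for sigmoid scores. The
flat baseline (`dbc`) gives every label an independent two-node
(member/non-member) sigmoid output; a label is assigned iff its member node
strictly exceeds its non-member node, ties excluded.

## Training schedule and two numerical decisions

The full pipeline is: preprocess → meta-features → DSE matrices → RBM
pretraining → fine-tuning by SGD (forward CNN → fusion → Boltzmann chain →
coarse/fine losses; backward through heads, chain, fusion, CNN), with the
Fig-style contrastive step available as a weighted extra (`cd_weight`).
Implementing this exposed a real numerical property worth recording:

1. **The chain attenuates gradients.** Five stacked sigmoids (each derivative
   ≤ 1/4) between the loss and the convolution kernels make the end-to-end
   discriminative gradient vanish at any stable learning rate — measured
   directly, parameter motion was ~1e-2 per full run regardless of step
   size. The package therefore adds a **CNN warm-up stage**
   (`warmup_epochs`): before the chain is attached, the CNN is trained
   against a throwaway hierarchy head reading `y_c` directly. This is a
   training schedule, not an architecture change; the warm-up head is
   discarded.
2. **The chain contracts variance.** Document-to-document variation of the
   top-layer activations is small (per-dimension sd ~0.02) even though label
   information survives (nearest-centroid accuracy on `h2'` stays close to
   that on `y_c`). Head inputs are therefore **z-scored with statistics
   frozen after pretraining** (`feat_mu`, `feat_sd`, stored in the model and
   applied identically at prediction); the backward pass rescales gradients
   by `1/sd`, which also re-opens the path into the chain.

The hierarchy can read either the label-score vector (the default: the
classifier input is most naturally the network's label output) or the top
hidden representation `h2'` (`hierarchy_input = "h2"`). The `h2'` variant
carries measurably more document information through the chain and is what
the end-to-end acceptance run uses; the score variant remains the default
as the more literal reading of the architecture.

## Synthetic data: what it emulates and what it does not

`synthetic_spec()` states a small world once: 2 coarse clusters × 4 labels;
label embeddings on a radius-10 sphere with unit noise (recoverable by
clustering, as the planted-partition tests require); ~40-token documents
(Poisson lengths, floor 8); per-label Zipf word distributions over 25-word
sub-vocabularies plus 15% shared background words; mild imbalance
(most:least = 2); 30% multi-label documents (2–3 labels); 20% anchor words
carrying 1–3 cluster-tied categories; multi-token entity mentions at rate
0.2 with a lexicon containing 10% ambiguous single-token prefixes; word
embeddings equal to a label signature (norm 3) plus sd-0.3 noise, word
dimension 10. Token strings are consonant/digit sequences chosen to be
invariant under the Porter stemmer so generated text survives preprocessing
verbatim. Everything is a pure function of the spec and seed; file hashes
are identical across runs.

What a green test establishes: the pipeline learns label structure planted
in word distributions, recovers planted clusters and distributions exactly,
and beats its own flat baseline. What it does not establish: performance on
real abstracts — real vocabulary sizes (tens of thousands of headings),
genuinely ambiguous synonymy, non-Zipf terminology bursts, and real entity
recognition noise are all outside this generator.

## Command-line interface

`semindex_cli()` (launcher in `inst/cli/semindex.R`) exposes four commands:
`synth --spec FILE --out DIR` (JSON file with any `synthetic_spec()` field),
`train --config FILE --out MODEL`, `predict --model MODEL --corpus FILE
--out FILE` (JSON-lines of id/labels/scores) and `evaluate --model MODEL
--corpus FILE --out DIR` (JSON + TSV report). The train config is JSON with
a `paths` object (corpus, embeddings, label_embeddings, category_map,
entity_lexicon) plus any `run_config()` field; the model archive is a single
JSON file with a manifest and all parameters. Logs go to stderr.

## Numerical choices, degenerate inputs, limitations

* `0/0 → 0` in every metric ratio; micro-F1 is exactly the harmonic mean of
  micro-P and micro-R. Macro- and micro-similarity are both
  emitted — per-class mean and pooled-count versions of the same ratio;
  they coincide for `K = 1`.
* ROC sweeps distinct scores descending, groups ties into one step, anchors
  the curve at (0,0) and (1,1), trapezoid AUC; degenerate all-positive or
  all-negative truth is an error.
* `logistic()` is branch-stable for |x| ≥ 500; activations cannot overflow.
* Empty documents embed to `L` unknown rows; empty categories get uniform
  rows and a flag; unknown words get the `UNKNOWN` vector (zero by default).
* The FISTA stopping pair (max-abs change < 1e-14, ≤ 50k iterations) is far
  tighter than the 1e-6 recovery the tests demand.
* k-means is restarted only through its seed; with pathological label
  embeddings (coincident points) cluster recovery is not guaranteed.
* Training is minibatch SGD with fixed learning rates — no momentum or
  adaptive optimisers, deliberately, so every update rule stays the plain
  gradient form stated above.
* The three-hidden-layer energy form is documented but intentionally unused
  (two-layer machine); persistent-chain training and partition-function
  estimation are out of scope.
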