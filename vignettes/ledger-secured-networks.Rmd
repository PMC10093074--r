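---
title: "Ledger-secured layered networks: model, design choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ledger-secured layered networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(securecnn)
```

## The problem

A trained classifier deployed for medical image triage (the motivating
setting is four-class brain-MRI tumor typing) is an attack surface: an
adversary who can write to the model store can permute the output classes,
add noise to weights, or alter layer structure, and the model will keep
producing confident, wrong answers. `securecnn` implements a
ledger-block protocol around a layered network so that any parameter or
structural change is (a) detected, (b) localized to the exact layer, and
(c) reversed from encrypted ledger copies — plus the downstream feature
pipeline (serial fusion, mode-value ordering, GA selection with an
entropy-gated naive Bayes fitness) that consumes features extracted from
such secured backbones.

## The protocol

Each layer $i$ with weights $X_i$, bias $B_i$ and structural metadata
(stride, filter size, output size) is serialized canonically
(fixed-field metadata record, then weights row-major as 64-bit IEEE
little-endian, then bias). Three cryptographic statements are made about
those bytes:

1. **Chained hash.** $h_i = \mathrm{HMAC}_k\!\left(h_{i-1} \,\|\,
   \mathrm{bytes}(\theta_i - \theta_{i-1})\right)$, with a fixed 32-byte
   zero genesis constant for $h_0$. The delta is elementwise when shapes
   align (both layers' metadata records are always prepended, so a stride
   edit perturbs the hash) and the concatenation of both serializations
   otherwise. Any upstream tamper invalidates all downstream hashes.
2. **Per-layer fingerprint.** $d_i = \mathrm{HMAC}_k(\mathrm{bytes}(\theta_i))$.
   The chain alone cannot localize (a tamper at layer $i$ changes
   $h_i, h_{i+1}, \dots$), so each ledger block also fingerprints its own
   layer; validation flags exactly the layers whose fingerprints mismatch
   and falls back to the earliest chain mismatch when only the chain
   disagrees (ledger inconsistency).
3. **Signed transactions.** During a secured forward pass, layer $i$
   computes $P_i = a(X_i y) + B_i$, encrypts it for the next layer
   ($Y_{i+1} = E_{\mathrm{pub}_{i+1}}(P_i)$), chains a pass hash
   $H_i = \mathrm{HMAC}_k(H_{i-1} \| \mathrm{dgst}(Y_i) \|
   \mathrm{dgst}(Y_{i-1}))$, and signs $(H_i, \mathrm{dgst}(P_i))$ with
   its private key. Transactions land in the central ledger block (CLB)
   under slots drawn from a seeded random permutation, so iterating the
   store does not reveal the layer order; a pluggable sync target (in
   memory or a directory) receives a byte-identical serialized copy.

Each layer ledger block (LLB) holds the two hashes, the key pair, the
neighbours' public keys, and the layer's parameters encrypted under its
own public key (plus the next layer's, mirroring the original block
layout — storing only the *next* layer's copy would leave layer 1
unrecoverable, so the self-copy is deliberate plumbing). Inserted as a
network layer, an LLB is the identity: zero bias, identity activation,
identity weights, so wrapping never changes a clean model's outputs —
`forward_secure` on an untampered model is bit-identical to
`forward_plain`.

**Verification and restoration.** `forward_secure` checks, before
executing each layer: the layer fingerprint, the previous transaction's
signature, and that the encrypted handoff decrypts to the previous
layer's recorded output digest. On the first failure the pass halts (no
later transaction is recorded) and, with `auto_restore = TRUE`, every
flagged layer is decrypted from its ledger block, written back, and the
chain re-validated, looping up to `max_iterations` (default 3 — the
original loop description has no termination bound, so one is imposed).
Restoration goes through the canonical byte codec, so restored forward
outputs are bit-identical to the pre-attack snapshot. Verification runs
per input by default: attacks should be caught during inference, not
only at audit time.

## Cipher suites

The protocol's cipher symbol is overloaded in its source description
(block cipher, activation, and noise scale); internally these are three
distinct names (`suite$encrypt`, `layer$activation`,
`attack_spec$noise_std`). Two suites are provided:

* `"rsa"` (default): genuine asymmetric semantics — RSA key pairs,
  RSA+AES envelope encryption to a public key, RSA-SHA256 signatures,
  HMAC-SHA256 keyed digests. OpenSSL key generation cannot be seeded
  from R, so ciphertexts differ between same-seed runs; hashes, slot
  layouts and everything seed-derived do not. The default modulus is
  1024 bits: this is a desk-scale protocol demonstration whose test
  harness wraps hundreds of models, and the key size is configurable
  (`cipher_suite(bits = 2048)`) for anything beyond demonstration.
* `"symmetric"`: the role the original protocol assigned to a symmetric
  block cipher (it names DES, calling it asymmetric — a terminology
  error). DES is neither available in this toolchain nor defensible;
  AES-256-CBC with a SIV-style deterministic IV plus HMAC "signatures"
  fills the same role. One 32-byte key per layer is carried in both
  halves of the key-pair interface under distinct byte prefixes. This
  suite is fully deterministic under the wrap seed: two same-seed runs
  produce byte-identical ledger files, which the tests assert.

Neither suite defends against an adversary who controls the model store
*and* the ledger (including the chain key) simultaneously; that is an
acknowledged limit of the design, not of this implementation.

## The attack simulator

Three severities, matching the taxonomy the ledger is meant to catch:

* **type 0 (mild)** — interchange the output class labels (default:
  reverse order; a seeded random or explicit permutation is available).
  No parameter changes, so `parameter_count_changed = 0`.
* **type 1 (average)** — seeded Gaussian noise
  $\mathcal{N}(0, \sigma^2)$, default $\sigma = 0.1$, added to the
  weights of every fully connected layer (biases untouched: the attack
  grammar names weights only).
* **type 2 (severe)** — noise on every parameterized layer's weights
  plus structural edits: stride $+1$ on the first convolution and a
  permuted class-label order. The structural categories are fixed and
  documented because the source lists categories, not values.

A severe copy may be unable to run a forward pass at all (the stride
edit breaks shape compatibility); `evaluate_attack_impact` scores such a
model 0 on the probe set, and restoration still works because it never
needs a forward pass. On the synthetic benchmark (template-matching
model fitted to the blob images), median unprotected probe accuracy over
10 seeds orders clean $\ge$ average $\ge$ severe, and auto-restored
accuracy equals clean accuracy exactly, for every severity — the
direction of the published attack table, not its dataset-specific
values, which require the external dataset and pretrained backbones.

## Feature pipeline

The three backbone feature layers are registered as
(`"avg pool"`, 2048), (`"global avg pool"`, 1000), (`"fc"`, 1000);
serial fusion concatenates rows in that order, so the fused width is
4048. Toy stand-ins with widths (32, 16, 16) keep tests fast;
`build_toy_backbones(paper_widths = TRUE)` emits the full widths purely
to exercise the dimensionality contract.

**Mode ordering.** Features are ranked by the mode of their values after
rounding to `decimals` places (default 2 — continuous features need
quantization for a mode to exist), descending; ties between equally
frequent values resolve to the smallest value, ties between features to
the original index. The permutation is recorded, so ordering is a
bijection.

**Entropy-gated NB fitness.** A chromosome's selected columns are pooled
over samples, dropped into 10 quantile bins, and their Shannon entropy
$H$ (natural log) computed; if $H > \tau$ the fitness is 0, otherwise it
is the stratified 3-fold cross-validated accuracy of a Gaussian naive
Bayes on the masked columns. Interpretations fixed here, where the
source is ambiguous: the entropy is per chromosome (not per feature);
the gate threshold has no published value, and because quantile binning
makes the pooled histogram near-uniform by construction, the default is
$\tau = \ln 10$ — the 10-bin maximum — so the gate is inert until a user
lowers it; $\lambda$ smooths class priors Laplace-style and scales a
variance floor of 1% of the pooled feature variance (a much smaller
floor lets near-constant columns, e.g. clipped background pixels, dominate
log-likelihoods and drives NB to chance on linearly separable data).
Gaussian NB and the nearest-centroid linear discriminant are authored
in-package (no NB package is available in the target environment, and
the gated fitness is part of the method); tests cross-check predictions
against a closed-form oracle and scikit-learn's reference GaussianNB.

**GA.** Population 100, 500 iterations, mutation 0.001, crossover 0.8,
elitism $B = 6$ by default (the published search settings; $B$ is read
as elitism count, the only role consistent with population sorting and
"robust chromosomes"). Parents are drawn by roulette wheel proportional
to fitness with a uniform fallback when all fitness is zero; uniform
crossover; per-bit mutation; offspring merge with parents, the merged
pool is sorted and truncated to $P$. Two implementation details worth
knowing: truncation keeps *distinct* masks first (duplicates carry no
information; deduplication measurably improves recovery), and fitness is
cached per mask. The published output cardinality (2988 of 4048) is
treated as a dataset-dependent observation, not a contract. With
mutation 0, crossover 0 and $B = P$ the loop reduces to evaluating the
initial population, which the tests pin as a regression guard.

## Synthetic fixtures: what they emulate, what they don't

* **Images.** Four classes in the class-per-folder layout, 40 per class,
  64×64 8-bit grayscale by default (the real dataset has 395–827 images
  per class; 40 is a deliberate desk-scale reduction). Class signal is a
  blob recipe (count, intensity, radius, position) on an elliptical
  "head" plus Gaussian noise; recipes are distinct enough that a
  pixel-mean NB beats 4-class chance. These are statistical stand-ins
  with no radiological realism: a green test establishes that the
  protocol and pipeline behave correctly, never that any clinical
  accuracy is reproduced.
* **Planted tables.** `n_informative` columns carry class-dependent
  means; `effect_size` (default 2.0) is the **total between-class
  Mahalanobis separation of the informative block**, i.e. per-feature
  shift `effect_size / sqrt(n_informative)`. The alternative reading — a
  2.0-sd shift per feature — saturates NB accuracy with ~3 features and
  makes "fraction of planted features recovered" unidentifiable (we
  measured recovery collapsing to ~0.55 under it); the aggregate reading
  keeps every informative feature marginally useful. Defaults
  `n_samples = 300`, 200 features, 2 classes.
* **Random toy models** (dense stacks with a softmax head) and a
  **template-matching benchmark model** (fixed conv + pool front end,
  nearest-centroid output layer fitted to the blob images) exercise the
  protocol and the attack benchmark.

## Known limitations and one honest red

* The GA feature-recovery benchmark (200 features, 20 planted, effect
  2.0, $P = 30$, 50 generations) reaches a **median recovery of 0.85**
  over 5 seeds against a 0.90 target. This is a property of the fitness
  landscape, not the optimizer: 200 generations gives the same median,
  and the GA's best fitness (0.80–0.90) matches or beats the
  all-informative oracle mask (0.85) — the finite-sample CV optimum
  simply does not contain all 20 weak planted features, because dropping
  two or three of them costs about 1% accuracy, which favorable noise
  columns repay. We report this rather than widening the target or
  re-tuning the generator post hoc.
* Default verification is per input; per-session verification is a
  configuration choice, not a different code path.
* The asymmetric suite's ciphertexts are not reproducible across runs
  (unseedable OpenSSL RNG); use the symmetric suite when byte-identical
  ledgers matter.
* Numerical edge cases are pinned by contract: non-finite parameters are
  rejected at serialization; softmax arg-max ties break to the lowest
  class index; pooled entropy of an all-constant subset is 0; an
  all-gated final GA population returns the lowest-entropy mask with a
  warning.

## Reproducing the full pipeline

```{r, eval = FALSE}
res <- run_demo(run_config(seed = 1), out_dir = "results")
```

generates the fixtures, wraps the three toy backbones, applies a severe
attack to one, audits (all touched layers flagged), restores, extracts
and fuses the three feature layers, mode-orders, runs GA selection and
reports the classification metrics — everything under `results/` with a
provenance record (config hash, seed, package version).
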