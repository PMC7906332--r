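---
title: "Adversarial multi-label annotation of protein sequences: model, training and evaluation"
author: "pfpwgan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial multi-label annotation of protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Predicting Gene Ontology (GO) annotations from an amino-acid sequence is a
multi-label classification problem with heavily structured labels.  The GO is
a directed acyclic graph in three namespaces (biological process, molecular
function, cellular component); the *true-path rule* says that whenever a term
annotates a protein, every ancestor of that term annotates it too.  Beyond
the DAG itself, terms co-occur (or exclude each other) in ways the graph does
not encode: two functions may never be carried by the same protein even
though nothing in the hierarchy forbids it.  A per-term classifier trained
with independent binary cross-entropy (BCE) ignores all of this structure.

`pfpwgan` trains the annotating network inside a conditional Wasserstein GAN.
The annotator plays the generator, $G(\mathbf{x}) \in [0,1]^c$, mapping a
protein $\mathbf{x}$ to an assignment vector over $c$ terms.  A critic
$D(\mathbf{x}, \mathbf{y}) \in \mathbb{R}$ scores (protein, assignment)
pairs and is trained to separate real pairs (experimentally annotated) from
generated ones; because it observes whole assignment vectors next to the
protein, the only way it can separate them is by learning the joint structure
of the label distribution — including co-occurrence constraints.  Feeding its
score back to the generator as an auxiliary loss pushes the annotator toward
assignment vectors that respect that structure.

## Losses

The generator minimises

$$ \mathcal{L}_G \;=\; \mathrm{BCE}\!\left(\mathbf{y}, G(\mathbf{x})\right)
   \;-\; \lambda_1\, D\!\left(\mathbf{x}, G(\mathbf{x})\right), $$

averaged over the batch, where BCE is the element-mean of
$-y\log\hat y-(1-y)\log(1-\hat y)$ with $\hat y$ clipped to
$[10^{-7}, 1-10^{-7}]$.  The critic minimises

$$ \mathcal{L}_D \;=\; D\!\left(\mathbf{x}, G(\mathbf{x})\right)
   - D(\mathbf{x}, \mathbf{y})
   + \lambda_2 \left( \lVert \nabla_{\tilde{\mathbf{y}}}
     D(\mathbf{x}, \tilde{\mathbf{y}}) \rVert_2 - 1 \right)^2, $$

with $\tilde{\mathbf{y}} = \varepsilon\,\mathbf{y} +
(1-\varepsilon)\,G(\mathbf{x})$, $\varepsilon \sim U[0,1]$ per sample.  The
gradient penalty replaces the 1-Lipschitz constraint of the Wasserstein
formulation.  Two readings were fixed here and are worth stating:

* The generator's Tanh output lives in $[-1,1]$; BCE requires $(0,1)$.  The
  output is affinely rescaled, $\hat{y} = (t+1)/2$, and this rescaled vector
  is also what the critic sees as the "fake" assignment; real assignments
  are $\{0,1\}$.  This is the only reading that puts both loss terms on one
  scale.
* The penalty differentiates with respect to the assignment vector only.
  Real and fake pairs share the same condition $\mathbf{x}$, so "averaging
  real and fake pairs" collapses to interpolating the label vectors; the
  condition is not interpolated.

Setting $\lambda_1 = 0$ (or dropping the critic entirely) recovers the plain
BCE annotator, called **PFP-S** throughout; it is the built-in ablation
(`ablation_pfp_s`) against which the adversarial model is compared.

## Architectures

**Generator, sequence mode.**  A sequence is represented by its overlapping
amino-acid trigrams (overlap two), each mapped to one of $20^3 = 8000$ codes
by an alphabetical base-20 code; code 0 is reserved for padding.  The network
is: embedding (8000 + 1 rows) → dropout (rate 0.2 — this is what makes the
generator stochastic during adversarial training) → 32 one-dimensional
convolution filters (kernel 8) → LeakyReLU (slope 0.2) → average pooling
(window 64, stride 32) → two dense LeakyReLU layers (512, 256) → dense
$c$-unit Tanh output, rescaled to $[0,1]$.

**Generator, feature mode.**  For precomputed per-protein feature vectors
(e.g. the 258-dimensional hand-crafted encodings used with FFPred-style
data), the front end is unnecessary: three dense LeakyReLU layers
(512/256/128) and the same Tanh output.

**Critic.**  The assignment vector passes through one dense layer; the
condition branch repeats the generator front end (identical layer shapes,
separate parameters) followed by one dense layer; the two feature vectors
are concatenated and passed through five dense LeakyReLU layers
(512/256/128/64/32) to a single linear neuron — no final activation, as a
Wasserstein critic's output is an unbounded score.

Hidden widths, the convolution kernel size (8) and the LeakyReLU slope are
conventional defaults, exposed in `generator_config()` /
`discriminator_config()`; none of them is structurally special.

Three architecture decisions that were genuinely open:

* **The padding embedding is fixed at zero** rather than trained.  This
  makes predictions exactly invariant to the amount of right-padding, so a
  batch can be padded only to its own longest sequence (length-bucketed
  batching) while computing the identical function; it also means a
  sequence's score does not depend on the `max_positions` it was encoded
  with.  The one-hot-times-embedding product is realised as an index lookup,
  which is the same linear map without materialising 8000-long vectors.
* **The critic has no dropout.**  The gradient penalty constrains the critic
  as a deterministic function; a stochastic critic would blur the very
  Lipschitz surface the penalty shapes.  Only the generator is stochastic.
* **Average pooling in the condition branch.**  The critic's condition
  branch is specified as a copy of the generator front end, and the
  generator pools by averaging.

## Training

Optimisation alternates: for every generator update the critic takes
`critic_ratio` (default 10) updates, each on a freshly drawn minibatch.  An
*epoch* is defined so that each training batch drives one generator update
(with its ten critic updates around it); this keeps the number of generator
updates equal between PFP-WGAN and the PFP-S ablation, which is what makes
their comparison meaningful.  Each network has its own Adam optimiser
(β₁ = 0.9, β₂ = 0.999).  20% of the proteins are held out; validation
protein-centric Fmax is computed every epoch and the parameters of the best
epoch are kept.  All randomness — split, initialisation, dropout,
interpolation draws, batch order — flows from one master seed, so a run is
exactly reproducible.

The networks and both backward passes are implemented in the package (R
with RcppArmadillo kernels for the embedding/convolution/pooling hot path
and the Adam update).  The gradient penalty needs the gradient of the
critic's *input-gradient* with respect to the critic's weights.  Because
every activation is LeakyReLU, the critic is piecewise linear: activation
masks are locally constant, the input-gradient is a multilinear chain
through the label-branch and trunk weight matrices, and its derivative is
computed in closed form by a second reverse pass through that chain (biases
and the condition branch receive zero almost everywhere).  All backward
passes, including this double-backward, are verified against central finite
differences in the test suite.

**Learning rate.**  For full-scale corpora (hundreds of thousands of
proteins, hundreds of epochs on a GPU) the reference setting is Adam at
$10^{-5}$, and `train_config()` keeps that default.  The desk-scale
benchmark below trains for 10 epochs (~500 generator updates), where a step
size of $10^{-5}$ cannot move the network measurably; the benchmark
protocol (`synth_benchmark_control()`) therefore uses Adam's canonical
$10^{-3}$.  This is a property of the protocol's scale, chosen when the
protocol was designed, not a tuned quantity.  Likewise the benchmark uses
reduced widths (embedding 32, 8 filters, dense 128/64; critic branches 64,
trunk 128/64/64/32/32) — the architecture shrunk to the task's size, with
$\lambda_1 = 0.03$ and $\lambda_2 = 10$ kept at their raw-sequence values.

## Evaluation suite

* **Fmax** (protein-centric): precision and recall per protein at each of
  100 evenly spaced thresholds in $[0,1]$ (prediction positive iff score
  $\ge t$), averaged over proteins, then the maximum harmonic mean over the
  grid.  When a protein has no prediction above $t$, its 0/0 precision is
  counted as 0 and the protein stays in the average; the CAFA refinement
  (precision averaged only over proteins with at least one prediction) is
  available as `protein_average = "cafa"`.
* **Term-centric F1**: per term, maximum F1 over the same grid with counts
  over proteins.  Terms with no positive protein are undefined and excluded
  from macro averages (the exclusion count is reported).
* **AUPR**: trapezoidal area under the precision–recall points at the
  distinct score cut points, anchored at recall 0 with the first point's
  precision.
* **AUC**: the rank statistic (probability a positive outscores a negative,
  ties counted ½).  **MCC**: confusion matrix at threshold 0.5 (configurable),
  0 when a marginal is empty.
* **TPR score**: the expected number of true-path conflicts per protein —
  for every annotated term, the number of its ancestors (restricted to the
  evaluated term set) missing from the annotation.  Exactly 0 on any
  propagated matrix.
* **Co-occurrence heatmap MSE**: the $c \times c$ binary matrix marking term
  pairs that co-occur in at least one protein, computed from the thresholded
  predictions and compared with the ground-truth heatmap by mean squared
  error (for binary matrices, the disagreement fraction).  Predictions are
  binarised at the Fmax-maximising threshold of the same evaluation — the
  one threshold the pipeline has already distinguished; this is configurable.
* Reporting breakdowns: mean term F1 per DAG height (height = longest
  `is_a` path from the namespace root, root 0 — the convention under which
  a term's height is stable when shortcut edges exist), and term F1 against
  the number of positive training samples.

## The synthetic benchmark

`synth_spec()` defines a desk-scale dataset with exactly the statistical
structure the adversarial loss is meant to exploit:

* a random DAG (default 40 terms, depth 4, single root; every non-root term
  has one parent on the level above and, with probability 0.3, a second
  shallower parent, so diamonds exist);
* one exact 6-residue motif per leaf term, planted at a random
  non-overlapping position in a uniform-background sequence of length
  50–400 (sequences accidentally containing another leaf's motif are
  resampled).  Exact motifs keep the task solvable by convolution filters
  with kernel ≥ motif length, which is what makes the
  WGAN-versus-PFP-S comparison informative rather than noise-dominated;
* per protein, 1–3 leaf terms drawn honouring planted leaf pairs: three
  forced co-occurrence pairs (ρ = 1, partners always drawn together) and
  three mutual-exclusion pairs (ρ = −1, never together).  Correlations are
  planted at the leaves only; internal-node correlations arise through
  true-path propagation, mirroring how real GO co-occurrence exceeds the
  DAG;
* annotations are the true-path closure of the drawn leaves (the TPR score
  of the dataset is exactly 0); optional post-closure label noise exists
  for robustness tests only;
* a feature-vector variant sums leaf-specific Gaussian prototype vectors
  plus isotropic noise (default dimension 64, σ = 0.1), emulating
  hand-crafted-feature datasets.

What the generator does **not** emulate: realistic amino-acid composition,
homology between proteins, degenerate motifs, annotation incompleteness.
Results on it show that the machinery works and that the adversarial term
recovers planted correlation structure at this scale; they do not predict
absolute performance on SwissProt-scale data.

`run_benchmark()` is the benchmark protocol in one call: sample the dataset,
train PFP-WGAN and PFP-S under identical settings and seed, predict on the
full protein set, and evaluate both — in particular the heatmap MSE that
quantifies recovered co-occurrence structure.  Problem sizes throughout the
test suite (2000 proteins and 10 epochs for the benchmark comparison; tens
of proteins for unit-level training checks) are the package's desk-scale
protocol choices.

## Numerical conventions and degenerate inputs

* Prediction positive iff score ≥ threshold; the grid includes 0 (the
  all-positive prediction) and 1.
* 0/0 precision is 0; proteins and terms are never silently dropped except
  the documented undefined-term exclusion in macro averages.
* Scores are clipped only inside the BCE; predictions are reported
  unclipped.
* OBO parsing honours `id`, `name`, `namespace`, `is_a`, `is_obsolete` and
  nothing else; obsolete terms and edges to them are dropped; only `is_a`
  edges define the hierarchy (`part_of` and other relations are ignored, so
  the ancestor closure is unambiguous).  Acyclicity is verified at parse
  time via a topological sort, which is then reused for propagation and
  heights.
* Term filtering (defaults 250/50/50 positives for BP/MF/CC) operates on
  the *propagated* matrix, so a parent's count includes its descendants'
  proteins.
* Sequences longer than 1002 residues or containing non-standard letters
  are dropped with per-record reasons before encoding.
* Training aborts with an informative error at the first non-finite loss.

## Known limitations

* Inference is deterministic (dropout off).  Whether prediction-time
  stochasticity should be kept is a genuinely open modelling question; the
  deterministic choice makes evaluation reproducible.
* The critic is trained per run; no warm-starting or checkpoint-resume
  across runs.
* Per-namespace modelling is the intended use (one model per BP/MF/CC term
  set); nothing enforces it, but metrics such as the TPR score are only
  meaningful within a namespace's term set.
* CPU-only by construction; full SwissProt-scale training is out of reach
  of this implementation and out of scope for the package's tests.
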