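---
title: "Conditional generation of antibody light chains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional generation of antibody light chains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Therapeutic antibody discovery concentrates on the heavy chain (VH), which
carries most binding diversity, yet a functional antibody needs a light
chain (VL) that pairs well with it. `lcgen` implements a
sequence-to-sequence next-token model of the conditional distribution
\(p(\text{VL} \mid \text{VH})\): an encoder reads the heavy-chain residues,
a decoder emits light-chain residues autoregressively, and constrained
decoding lets a user pin down germline usage and graft binding loops (CDRs)
while the model fills in the frameworks.

## The model

The network is the standard transformer encoder-decoder: by default 6
encoder and 6 decoder layers, 8 attention heads, embedding and feed-forward
width 512, dropout 0.1, fixed sinusoidal positional encodings added to
\(\sqrt{d}\)-scaled token embeddings, post-layer-norm residual blocks with
ReLU feed-forward units, a final layer norm per stack, and a 24-token
vocabulary (padding, start, stop, the 20 amino acids, one reserved token).
Source and target embeddings are separate and the output projection is
untied with a bias. This layout is not arbitrary: it is the unique member
of the searched family (vocabulary 21–32, tied/untied embeddings and
projection, with/without projection bias and final norms;
`resolve_vocab_layout()`) whose trainable parameter count equals the
published total of 25,284,632 for the stated depth and width, and
`count_parameters()`/`param_count_formula()` reproduce that number exactly.

Weights are initialised Xavier-normal (variance \(2/(fan_{in}+fan_{out})\));
biases start at zero, layer-norm gains at one. Encoder attention is fully
bidirectional; decoder self-attention is strictly causal; padding is
excluded from attention and from the loss. Dropout is applied to the
embedding+position sums and after each sublayer output, not on attention
probabilities — the conventional placement is ambiguous at this point and
the simpler variant keeps the hand-derived backward pass auditable.

The numeric kernel (forward, backward, Adam-ready gradients, KV-cached
incremental decoding) is written in RcppArmadillo and runs in single
precision, the conventional training precision for this model family; a
double-precision instantiation of the same templated code exists solely so
the test suite can verify the analytic gradients against central finite
differences (relative agreement ~1e-7). Attention key biases receive
exactly zero gradient — a softmax shift invariance, not a defect — and the
tests account for that.

## Training protocol

Teacher-forced cross-entropy on light-chain tokens (mean over non-padding
positions), Adam with default moments, batch size 64, 4 epochs, and a
cosine learning-rate schedule with a 5% linear warm-up. The full-scale
protocol's maximum learning rate is 1e-4 (`train_config()` default). The
warm-up is linear and the cosine decays to exactly zero at the final step;
both ends are pinned by tests. Epoch-level shuffling and dropout masks
derive deterministically from the run seed, so a training run is exactly
reproducible; the final model is the last epoch's (no early stopping).

Dataset curation applies three rules in a documented order — conserved
cysteine anchors present in both chains, no characters outside the
20-letter alphabet, no exact duplicate (heavy, light) tuples — counting
each removed pair once under its first failing rule. The random 80/10/10
split afterwards excludes from the test set any pair whose heavy chain
occurs verbatim in train or validation. Framework-indel restoration is out
of scope: it requires an external masked language model, and the synthetic
data is indel-free by construction; real-data users plug a restorer in
before curation.

## Constrained decoding

Generation samples from the temperature-scaled (default 1.0),
nucleus-filtered (default top-p 0.9, smallest qualifying prefix, boundary
token included, ties by token id) next-token distribution, restricted to
residue and stop tokens. Constraints are hard:

* **Germline seeding.** A type restriction forces the first two residues, a
  V-family or V-gene restriction the first ten, drawn
  frequency-proportionally from the germline leading-residue table. When
  CDR1 and CDR2 are supplied without a type, the type is inferred by the
  best ungapped sliding-window BLOSUM62 score against germline CDRs (ties
  to kappa, the majority class).
* **CDR grafting.** CDR1 is grafted immediately after the first cysteine
  the model emits within the scheme's window (positions 21–26), followed by
  the forced conserved tryptophan; FR2 then has the scheme's fixed length
  (IMGT-style 17, Kabat-style 15), after which CDR2 is grafted; CDR3 is
  grafted after the first cysteine at a structurally plausible FR3-end
  position and is followed by the forced phenylalanine. The stop token is
  never forced. If a required anchor never appears the sample is flagged
  failed, not raised.

Forced tokens bypass temperature and the nucleus filter, but every emitted
token's raw (temperature-1, full-support) log-probability is recorded, so
constrained and free sequences are scored on one scale. Every output is
re-annotated; unannotatable outputs are flagged invalid rather than
silently returned.

Anchor-based annotation itself (`annotate_regions()`) is a numbering-lite
stand-in for external antibody numbering software: exact on indel-free
chains, deliberately conservative otherwise (it fails rather than guesses).
Scheme constants live in a versioned JSON table under `inst/extdata/`.
Coordinates are 1-based closed intervals throughout — the Bioconductor
convention — with seven regions tiling the chain exactly.

## Scoring and the pairing-preference statistic

`sequence_loglik()` is the teacher-forced sum of per-token log-softmax
values (residues plus stop); `perplexity()` is `exp(-mean per-token)`. The
"unconditional" probability of a light chain is operationalised as the same
model conditioned on an empty heavy chain (encoder input = start, stop):
the only construction that needs no second model. The pairing preference
between a native light chain and an alternative (typically its germline
reversion) is \((a-b)/(a+b)\) with \(a, b\) the unconditionally-normalised
conditional probabilities; it is computed as \(\tanh((\log a - \log b)/2)\)
because products of ~110 token probabilities underflow doubles. The
statistic is exactly zero for identical candidates, antisymmetric under
swap, and bounded in \([-1, 1]\).

Germline reversion picks the nearest V gene by ungapped identity over the
V-encoded span (FR1 through the second conserved cysteine) and the nearest
J gene over the trailing J span, then restores every mismatch in those
spans, leaving unencoded CDR3 junction residues untouched. Chains without
any germline above 50% identity are flagged rather than reverted.

## The synthetic repertoire

The desk-scale generator emulates the statistical structure the method
needs, with full ground truth for oracle tests: 8 heavy and 6 light
germline families (4 kappa-like with leading `DI`, 2 lambda-like with
leading `QS`, unique 10-residue signatures, two genes per light family);
indel-free ~105-residue light and ~114-residue heavy templates with the
conserved anchors at scheme-consistent positions; J segments contributing
the last three CDR3 residues plus FR4; a pairing matrix with one dominant
light family (probability 0.6) per heavy family; and correlated somatic
hypermutation via a shared per-antibody intensity
\(\lambda \sim \Gamma(\text{shape }2, \text{scale }3.5)\) with per-chain
Poisson counts at rates 1.2 (heavy) and 0.8 (light). These values — mean
~8.4 heavy and ~5.6 light substitutions with a long right tail — are
typical of matured human repertoires, and the shared intensity yields a
heavy/light mutation-count correlation around 0.7, with mutation positions
uniform over non-anchor sites and substitutions uniform over the 19
alternatives. Mutation placement is redrawn when a substitution would
create a spurious anchor that breaks annotation (~2–3% of draws), so
generated repertoires pass curation by construction. The generator does
not attempt real germline sequence content, indels, allelic nomenclature,
or realistic amino-acid substitution biases — so passing tests demonstrate
the machinery and the recoverable statistical structure, not performance
on real repertoires.

## The desk-scale reference run

Tests and the validation experiments use a scaled-down reference model:
2+2 layers, width 64, feed-forward width 256, 4 heads, dropout 0.1,
trained 4 epochs at batch 64 on a 20,000-pair synthetic repertoire
(16,000 train / 2,000 validation / 2,000 test after the split). Three
hyperparameters deviate from the full-scale protocol: the feed-forward
width is 4x the model width (the narrow d = 64 otherwise starves the
per-position template memory the task needs), the head count is 4 (head
dimension 16), and the maximum learning rate is 3e-3, since 1e-4 was tuned
for a ~25M-parameter model taking ~90,000 optimiser steps and this run
takes ~1,000 steps on a ~0.5M-parameter model. The learning rate and
feed-forward width were revised upward once after the first reference run
showed clear underfitting (validation loss far above the generative
entropy floor, near-flat per-position predictions).

What this reference run does and does not reproduce is itself informative.
It reliably reproduces the machinery-level claims: constrained decoding
satisfies every CDR and seed constraint; ~99% of freely generated
sequences are annotatable light chains; the native repertoire shows the
heavy/light germline-identity correlation and shuffling destroys it. It
does *not* recover the full-scale co-evolution transfer: the trained
model's predicted per-position mutation rate barely responds to the
heavy chain's mutation load (a few percent of the required dynamic range),
so generated light chains carry almost no load-matched mutations and the
generated-pairing correlation stays near zero, and the native-versus-
reverted pairing preference — whose sign hinges on exactly that load
response — does not come out reliably positive. An oracle analysis (a
perfect conditional model of the generator, decoded under the same
top-p 0.9 rule) shows the target correlation is achievable in principle
(r ~ 0.65), so the gap is a learning-budget effect: the coupling is worth
only ~1–2 nats per ~110-token sequence under uniform mutation placement
and uniform 1-of-19 substitutions, and the 4-epoch example budget does
not extract it. Running the identical pipeline for 20 epochs makes the
whole pattern emerge — the load response of the predicted mutation rate
grows steadily from epoch 8 onward, the median pairing preference turns
positive (+0.13) with a far stronger preference for chains carrying ten
or more mutations (+0.89 vs −0.17), and the generated-pairing correlation
reaches r ≈ 0.19 — while re-partitioning the same 4 epochs into smaller,
noisier batches does not help. The corresponding acceptance-level tests
assert the full-scale effect under the 4-epoch reference conditions and
are expected to fail there; they are retained deliberately rather than
weakened.

## Numerical choices and degenerate inputs

* Layer-norm epsilon 1e-5; softmax rows are max-shifted before
  exponentiation; log-softmax tolerates `-Inf` entries (analytic stubs).
* Nucleus ties are broken by token id; `top_p = 1` keeps exactly the
  nonzero-probability support; temperatures near zero reduce to argmax
  without overflow.
* Evenly spaced diversity selection is over ranks, not score values
  (`round(i(n-1)/(k-1))`), because rank spacing stays well defined for
  clustered scores; ties keep input order and the endpoints are always
  included for k >= 2.
* Empty sequences tokenize to `[start, stop]`; unconditional scoring is
  exactly that encoder input. Lowercase residues are upconverted with a
  warning; every other out-of-alphabet character is an error naming the
  offending position.
* Checkpoints (config plus named tensors, written per epoch) are validated
  tensor-by-tensor on load; shape mismatches are rejected.

## Known limitations

Real-data use depends on pluggable external tools that are deliberately
out of scope here: full IMGT/Kabat numbering with insertion codes,
humanness and developability classifiers, structure prediction, and
framework-indel restoration enter through the `filter_plugin()` interface
and the `germline_hint` argument rather than reimplementation. The
annotation heuristic assumes indel-free chains with canonical anchor
spacing; bispecific (two-heavy-chain) conditioning is not implemented; and
the synthetic repertoire's simplifications mean quantitative metrics here
do not transfer to real repertoires without retraining on real paired
data.
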