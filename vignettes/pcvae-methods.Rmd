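---
title: "Methods: conditional VAEs for protein sequence design"
author: "pcvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional VAEs for protein sequence design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model and the design
choices behind it: what is being estimated, under which assumptions, what
the tunable parameters mean, and what the tests do and do not demonstrate.

## The model

`pcvae` implements a conditional variational autoencoder over fixed-length
one-hot encodings of protein sequences. A sequence of up to `max_len`
residues (140 by default) becomes a `max_len x 22` one-hot array —
20 standard amino acids, a wildcard `X` for non-standard residues, and a
padding symbol filling positions past the end of the chain — flattened
position-major to a vector `x` (3080 entries at the default length). The
conditioning attribute `a` is concatenated to `x` at the encoder input and
to the latent sample `z` at the decoder input, so both the inference model
`q(z | x, a)` and the generative model `p(x | z, a)` see it.

Both networks are MLPs of *linear blocks* `LB(u) = ReLU(BN(Wu + b))`,
sized 512, 256, 128 in the encoder and reversed in the decoder. The
encoder ends in two affine heads: one for the posterior mean and one,
through a softplus, for the posterior variance, giving a diagonal Gaussian
in a 16-dimensional latent space against a standard-normal prior. The
decoder ends in an affine layer with a sigmoid, producing a soft tensor in
(0,1) that is decoded back to residues by per-block argmax.

The training objective is the negative evidence lower bound,

```
loss = BCE(x_hat, x)  +  beta_t * KL( N(mu, sigma^2) || N(0, I) ),
```

averaged over the minibatch, where `BCE` is the elementwise binary
cross-entropy summed over all tensor entries and `beta_t` ramps linearly
from 0 to 1 over `kl_burnin` optimiser steps. Optimisation is Adam with
learning rate `5e-4`, batch size 512, and both moment-decay constants set
to 0.9.

### Choices the architecture leaves open

* **Reconstruction likelihood.** A sigmoid output layer pairs naturally
  with a Bernoulli likelihood, so the reconstruction term is summed
  elementwise binary cross-entropy against the one-hot target. A
  per-position categorical (softmax over the 22 symbols) would also be
  defensible but would change the stated output layer; it is not used.
* **Adam's second beta.** Both moment-decay constants are 0.9. A second
  beta of 0.9 is unusually low, but it is the configured default and both
  constants are exposed in `adam_betas`.
* **Burn-in length and schedule.** The KL weight ramps per optimiser step
  (not per epoch), reaching 1 after `kl_burnin` steps; the default is 100
  epochs' worth of steps. The factor is exactly 0 at the first step and
  exactly 1 at and beyond `kl_burnin`.
* **Convergence.** Training stops at `epochs`, or earlier when the
  relative epoch-mean loss improvement stays below `tol` (1e-4) for
  `patience` (10) consecutive epochs — judged only after the burn-in has
  completed, since the ramping KL makes the loss non-comparable across
  the early epochs.
* **Initialisation.** Fan-in-scaled normal weights (sd `sqrt(2/fan_in)`),
  zero biases, unit batch-norm scale; fully determined by `seed`.
* **One-sample ELBO.** A single reparameterised draw per datum per step
  estimates the expectation term, the standard unqualified estimator.

### Numerical details

* Batch normalisation uses biased batch variance with epsilon 1e-5 in
  training mode and accumulated running statistics (momentum 0.1) in
  evaluation mode, so encoding or decoding a *single* sequence is
  deterministic and well-defined. Minibatches of size 1 (a possible
  ragged tail of a shuffled epoch) are skipped, as batch statistics are
  undefined there.
* The softplus posterior variance is floored at 1e-10 before the
  logarithm in the KL term.
* Binary cross-entropy is computed from logits in the numerically stable
  `softplus(o) - t*o` form during training; the standalone
  `weighted_bce()` clamps probabilities at 1e-7.
* Argmax decoding breaks ties toward the lowest symbol index; a padding
  argmax occurring before the end of the chain is mapped to the wildcard
  rather than deleted, preserving the position frame for motif analysis.
  Only the trailing padding run is stripped.
* All backward passes are hand-derived and are checked against central
  finite differences in `test-nn.R`, for every parameter class of both
  architectures.

## The topology grammar

Fold strings follow a context-free grammar with five nonterminals and 22
productions: two topology rules (recursive and terminating), one element
rule, two orientations (`+`, `-`), four layers (`A`–`D`), and thirteen
positions (`+0`…`+6`, `-1`…`-6`; `-0` does not exist). The grammar fixes
*what* the strings are but not how derivations are ordered or indexed, so
the package freezes both: rules are indexed 0–21 in the order above, and
the canonical derivation expands elements strictly left to right, emitting
for each element its topology rule, element rule, orientation, layer and
position rule — 5 rules per element, hence at most 11 elements in the
55-slot one-hot encoding (23 options per slot: 22 rules plus a padding
rule). `decode_rules()` validates that a decoded sequence is a replayable
canonical derivation rather than accepting any block pattern.

Parsing is deliberately forgiving about typography — whitespace is
ignored and Unicode minus signs are accepted — because published fold
strings mix both; output is always compact ASCII. Position tokens beyond
those observed in any particular dataset (e.g. `+6` with layer `A`) are
accepted: the grammar defines the legal set, not a corpus.

## Dataset construction rules

* **Negative examples.** A metal-binding record's negative twin resamples
  each annotated binding residue independently from the training-set
  amino-acid frequencies and zeroes all flags. The draw may redraw the
  original residue — the rule is "a random amino acid", not "a different
  amino acid" — so a negative can retain part of its site; this is
  documented behaviour, and the alignment-propagation rule (replace a
  homologue's residue only where it equals the native residue) is
  consistent with it.
* **Homologue filter.** A hit passes if its length is within 80–120% of
  the query and at most 140 residues.
* **Indexing.** Residue positions are 1-based everywhere in this package,
  matching R convention; manifests store 1-based positions. (PDB files
  already use 1-based author numbering, so no conversion happens at that
  boundary either.)
* **Multi-metal binders** carry a single attribute vector with several
  flags raised, not duplicated records.

## The discriminator

Six linear blocks sized 1024/512/256/128/64/8; the final block keeps its
batch normalisation but swaps the rectifier for a sigmoid, yielding eight
independent binding probabilities. The loss is binary cross-entropy with
per-class weights proportional to the inverse of each metal's positive
count in the training split, normalised to average 1 (the inverse ratio
fixes only the proportions; the normalisation is this package's choice and
keeps the loss scale comparable across weightings). Validation is
family-disjoint: families are atomic units packed greedily (largest first,
seeded tie-break) into the validation side until the target fraction is
reached, and designated hold-out sequences drag their whole family in.
Early stopping keeps the parameters from the epoch with minimum validation
loss, not the final epoch.

## Sampling procedures

The metalloprotein task encodes the input once with its (possibly edited)
flag vector and decodes many reparameterised posterior samples — variants
of the input with the requested binding character. The structure task
starts from the prior: round 1 decodes standard-normal latent draws under
the topology encoding (the "from across the space" round), each candidate
is scored by a pluggable scorer, and subsequent rounds sample the
posterior of the incumbent best sequence. Two details are made explicit
that the procedure otherwise leaves implicit:

* **Elitism.** The incumbent is carried into every round's comparison, so
  the best score is nonincreasing by construction — an invariant the
  tests assert on every run.
* **Round-1 source.** The first round samples the prior (not the
  posteriors of training sequences); with a conditioning attribute this
  is the natural reading of sampling "from across the space" and requires
  no access to training data at design time.

Scorer failures on individual candidates are logged and skipped rather
than fatal; only a round in which every candidate fails aborts the search.
The per-round top-5 shortlist is recorded for downstream structure
pipelines, while a single best sequence seeds the next round.

## Analysis metrics

* `find_hx3h()` scans for His-x3-His (two histidines four positions
  apart); an optional secondary-structure string restricts hits to
  helices.
* `close_histidines()` reports histidine pairs whose representative atoms
  lie within a cutoff on a template coordinate frame, requiring sequence
  separation of at least 2. The cutoff is **not** defined by any
  published number; the default of 7 Å is a typical metal-site screening
  distance and is a configurable argument, as is the choice of
  representative atom (coordinating side-chain atoms where the residue
  type has an obvious one, then CB, then CA).
* `jsd_conservation()` scores each alignment column by the Jensen-Shannon
  divergence (half-mixture, log base 2, bounded in [0,1]) between the
  column's residue distribution and a background. Gaps are excluded from
  the column distribution and columns over 50% gaps are flagged — gap
  handling is an implementation choice, made explicit here.
* `sequence_identity()` compares equal-length sequences position-wise;
  unequal lengths are globally aligned first (match +1, mismatch −1, gap
  open −2, extend −1) and identity is matches over alignment columns.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the method is
designed for, at desk scale: families of a native chain plus up to 50
homologues (mirroring the per-structure homologue cap of real data
harvesting), i.i.d. per-position mutation at per-position conservation
levels drawn from [0.6, 0.98], metal-binding families carrying a planted
coordination tripeptide whose positions are perfectly conserved while the
flag is on, negative twins built by the package's own
`make_negative_example()`, and topology labels drawn from a shared pool
(roughly one topology per three families, since real folds are shared
across many families). Two generator choices deserve justification:

* **Motif sites are metal-specific constants.** All families binding a
  given metal carry its motif at the same sequence position, the
  synthetic analogue of binding sites at structurally equivalent
  positions of a shared fold. This is what makes family-disjoint label
  recovery a fair test for a dense network operating on positional
  one-hot input; position-invariant motif detection would require a
  different architecture and is not what this model family does.
* **No covariation.** Mutations are independent across positions.
  Residue covariation is a known blind spot of this model class, so the
  generator deliberately does not emulate it.

Default sizes (24 families, 16 of them binders — two per metal — with 50
homologues each, sequences up to 60 residues, ≈2,000 records with the
negative twins) are the package's standing desk-scale study conditions;
the discriminator experiments use more, smaller families (48 × 11) so that
every metal has held-out positives under a family-disjoint split.

## What the tests show — and what they don't

The test suite trains reduced-width models on the synthetic conditions
above: a metal-mode CVAE (256/128/64, `max_len` 60, 250 epochs), a
grammar-mode CVAE (128/64/32, 50 epochs), a 2-dimensional-latent variant,
and the discriminator (256/128/64/32/16, 200 epochs). On these the suite
verifies, end to end:

* conditioning recovery — generating from a motif-ablated input with the
  metal flag on versus off changes the planted-motif frequency by well
  over 0.3 on average across all 16 flagged families;
* family-disjoint label recovery — held-out per-metal AUROC ≥ 0.9;
* latent structure — with 2 latent dimensions, same-family sequences lie
  closer together than cross-family pairs;
* search behaviour — three rounds of iterative search never worsen the
  best score (elitism) and strictly improve the median candidate score
  over prior-only sampling.

These are desk-scale analogues, not reproductions: passing them shows the
implementation learns the planted signals it was pointed at, under ideal,
i.i.d., covariation-free conditions, with deterministic flag–motif
coupling. Real sequence families are smaller in signal and larger in
nuisance structure; reconstruction identities and motif-recovery rates on
real data will be lower, and nothing here validates the external
structure-scoring stages (threading, relaxation, ab initio folding) that
a production design pipeline would plug into the scorer interface.

## Known limitations

* Fixed-length one-hot encoding: no alignment awareness, no indels in the
  latent geometry; interior padding in raw decoder output is wildcarded,
  not re-aligned.
* The grammar covers topology strings of at most 11 secondary-structure
  elements (55 rules); longer derivations are rejected rather than
  truncated.
* Dense positional input means the discriminator cannot generalise a
  motif to positions it has never seen.
* Batch-norm running statistics make generation deterministic but mean
  that a model's outputs depend (slightly) on the data order seen during
  training; all of it is reproducible from the training seed.
* Sequence covariation is neither modelled nor emulated.
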