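---
title: "Models and methods behind ampliclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampliclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ampliclass classifies 16S rRNA amplicon reads to a seven-rank taxonomy
(kingdom through species, Greengenes `k__`…`s__` notation) and measures
how close any trained classifier comes to the accuracy ceiling set by the
reference database itself. This vignette records the models, the tunable
parameters, the numerical choices, and the limits of what the package's
synthetic tests can show about real data.

## The assignment rule shared by all classifiers

Every classifier reduces a read to a probability vector over the
reference classes (species-level lineages, possibly truncated where the
reference itself stops above species). `assign_with_confidence()` then
applies one rule everywhere:

1. At species rank, if the maximum class probability is **strictly
   greater** than the confidence threshold `c`, report the argmax
   lineage. Ties among equal maxima are broken uniformly at random under
   the caller's seed.
2. Otherwise sum probabilities over classes sharing each genus prefix
   and repeat the test at genus, then family, order, class, phylum,
   kingdom.
3. If no rank clears the threshold, the read is Unassigned.

The achieved confidence reported with each call is the winning aggregate
probability. Because the rank-wise maximum aggregate is non-decreasing
toward the root, assignment depth is non-increasing in `c` — the
precision/recall trade-off that the tests assert. The strict `>`
comparison is used for every classifier; at `c = 0` every read is
therefore assigned at its full class depth. `c` defaults to 0.7
throughout, the operating point at which the tool family this package
belongs to is usually run; `c ≥ 1` is rejected since no probability can
exceed it.

## Class weights

`ClassWeights` are a normalized prior over the reference classes. Two
constructors exist: `uniform_weights()` (each of the S classes gets 1/S,
regardless of how many reference sequences it has) and
`weights_from_compositions()`, which pools (sums) per-species counts
across observed samples and renormalizes. Pooling by summation rather
than averaging per-sample proportions weights samples by observation
volume; the choice matters little for the skewed synthetic communities
used here and is declared rather than derived. Reference classes absent
from every sample receive a floor weight (default `1e-6`) before
renormalization so that no class has a zero prior — a zero prior would
make a class unreachable for the Bayes posterior no matter the evidence.

## Naive Bayes

`fit_nb()` is a multinomial naive Bayes over bags of overlapping k-mers
(default k = 7; windows containing non-ACGT characters are skipped).
For class *c* and k-mer *w*:

$$P(w \mid c) = \frac{n_{cw} + \alpha}{n_c + \alpha\,(V+1)}$$

with pooled class counts `n_cw`, class total `n_c`, vocabulary size `V`
(distinct k-mers observed at training), and smoothing `α = 0.001` by
default. One shared out-of-vocabulary column (the `+1`) absorbs query
k-mers never seen at training, so posteriors never hit exact zero.
Posteriors are computed in log space with max-subtraction before
exponentiation: a 150 nt read contributes 144 seven-mer factors and the
linear-space product underflows double precision. An empty bag (read
shorter than k, or all windows ambiguous) returns the prior — no
evidence, no update.

## Random forest

`fit_forest()` trains an ensemble of CART-style trees on the same k-mer
counts, delegating tree induction to `ranger`. The package fixes the
hyperparameter semantics rather than the implementation:
`max_features = "sqrt"` considers ⌊√p⌋ features per split, `"all"`
considers every feature; `max_depth = NULL` grows trees until leaves are
pure (`min.node.size = 1`), and integer depths cap growth. Because tree
induction has no prior slot, class weights enter as per-instance
training weights, weight(class)/n(class), which reproduces the prior's
effect on the training loss. Per-read probabilities are the normalized
mean of tree leaf distributions. With a single CPU thread and a fixed
seed, fits and predictions are bit-reproducible.

## Embedding and convolutional network

Architecture I converts each read (trimmed to 150 nt) into the ordered
sentence of its 144 overlapping 7-mers, embeds every token with a CBOW
word2vec table, and feeds the 144 × d matrix to a one-dimensional
convolution (f filters of width q over the token axis), ReLU, global max
pooling, and a softmax layer over the classes. Architecture II replaces
the embedding with per-nucleotide one-hot encoding (150 × 4) and keeps
the rest of the stack. Global max pooling makes the pre-softmax features
invariant to where a motif occurs along the read, which the tests verify
directly on a one-filter micro-network.

The CBOW embedding (default 300 dimensions, context window 5) is trained
by stochastic gradient descent with five negative samples per position,
drawn from the unigram distribution raised to 3/4, with a linearly
decaying learning rate; training is single-worker and deterministic
under its seed. The table is trained on reference sentences only, never
on query reads, to avoid leaking test sequence content into the
representation. Tokens absent from the table, and ambiguous windows, map
to a reserved OOV vector so sentence geometry is always preserved.

The network trains by minimizing class-weighted cross-entropy (instance
weights proportional to class weight over class count) with the Adam
optimizer. Defaults follow the conventional setting (learning rate
0.001, batch 128, 5 or 10 epochs). At the desk scale this package
targets — corpora of tens of reference reads — those defaults leave the
optimizer with only a handful of update steps, so the package's own toy
benchmarks declare `batch_size = 8` and `lr = 0.05` in the config, which
gives the separable-motif fixture a training F-measure ≥ 0.95 within 10
epochs. Both values are ordinary config fields recorded in the fitted
model; nothing about the architecture changes. Stochastic training
assertions in the test suite are averaged over at least three seeds.

## The exact-match ("perfect") classifier

`build_exact_index()` compiles, for every distinct reference sequence,
the list of classes carrying that exact sequence, with weights taken
from the class-weight distribution (or equal in uniform mode) and
renormalized per sequence. `perfect_classify()` hands that vector to the
same `assign_with_confidence()` rule as every other classifier. Lookup
is case-folded exact string matching on the trimmed sequence — by
construction the classifier can only err when two or more species share
an identical sequence, which makes its in-sample F-measure the accuracy
ceiling for the data. Queries absent from the index are a hard error
rather than Unassigned: the construct is explicitly in-sample, and a
silent fallback would corrupt the bound.

## Evaluation, cross-validation, statistics

`evaluate_assignments()` micro-averages over (optionally
abundance-weighted) reads at a chosen rank: a true positive reaches the
rank and matches the truth prefix; a false positive reaches the rank
without matching; a false negative has truth at the rank but a shallower
or wrong assignment (a wrong call counts in both FP and FN). Precision
with nothing assigned at the rank is reported as 0 with an explicit flag
instead of NaN. `mcc_score()` computes the multiclass Matthews
correlation in covariance form from the full species-level confusion
matrix, which includes an unassigned/truncated prediction category;
degenerate one-row/one-column matrices report 0 with a flag.

`crossvalidate()` partitions unique reference sequences into folds
(stratified by class where a class has at least `folds` sequences),
trains on the complement, and tests on reads drawn from the held-out
sequences according to the community weights. A held-out read whose
species is absent from training is scored against its deepest ancestor
present among the training lineages — novel species are otherwise
unscorable. The exact-match classifier is evaluated in-sample on the
same frozen folds, per its contract. `compare_classifiers()` wraps
two-tailed Wilcoxon tests — signed-rank for paired scores, rank-sum
where sample sets differ — with Hommel correction across the family of
comparisons; all-zero paired differences are flagged degenerate with
p = 1.

## The synthetic-data generator

`simulate_reference()` evolves a uniformly drawn root sequence down a
7-rank tree by per-rank substitution; `simulate_communities()` draws
per-sample species proportions from a symmetric Dirichlet and counts
from a multinomial; `simulate_reads()` samples reads by community
abundance as read-length prefixes with i.i.d. substitution errors. The
defaults describe the conditions the package is tested under, chosen
once on biological grounds:

* 250 nt references and 150 nt prefix reads — a V4-like amplicon and a
  short-read length at which species-level information is scarce;
* per-rank divergence 0.15/0.10/0.08/0.06/0.05/0.03/0.02 (kingdom →
  species): deep ranks well separated, sister species ~2% apart, the
  regime in which confidence truncation actually engages;
* read substitution error 0.001, a short-read-like error rate;
* Dirichlet concentration 0.1, giving strongly skewed communities in
  which one species typically dominates — the situation in which
  ecological weights carry real information;
* `p_share` — the probability that a species carries a byte-identical
  copy of a sister's sequence — defaults to 0. Sharing is the *only*
  sanctioned mechanism for identical sequences: a non-shared species
  sequence is redrawn until its read-length prefix is unique, so the
  exact-match classifier's defining property (F = 1 when `p_share = 0`
  and reads are error-free) holds by construction, not by luck of the
  seed. Weighted-vs-uniform experiments set `p_share = 0.5` because
  priors can only matter where sequence evidence is ambiguous.

Substitution-only evolution (no indels) keeps read geometry fixed, which
the sentence encoder's contract requires; prefix reads mirror the
150 nt trimming convention used throughout.

What the generator does **not** emulate: chimeras, PCR and primer bias,
length variation and indels, rank-dependent taxonomic label noise, and
the scale of real references (tens of thousands of species). Passing
tests therefore demonstrate correctness of the algorithms and the
direction of effects (weights help under skew and ambiguity; the
exact-match bound dominates trained classifiers; recall falls as
confidence rises), not absolute accuracy levels on real data.

## Problem sizes and numerical choices

The test and acceptance workloads use references of 12–48 species (up to
three sequences per species), communities of 3–5 samples at 60–150 reads
each, and network configurations of ≤ 16 filters, kernels 3–14, ≤ 10
epochs, embedding dimension 8–32 — sizes chosen so the full suite runs
in a few minutes on one CPU while still exercising every code path at
meaningful class counts.

Numerical details worth knowing: probability vectors are validated to
sum to 1 within 1e-6 (inputs) and renormalized to 1e-9 (models);
aggregate ties at the argmax are detected within 1e-12 and broken by a
seeded uniform draw; the Bayes posterior uses max-subtracted log-sums;
Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8; the forest always runs on one
thread so fixed seeds give identical fits. Seeded helpers restore the
caller's RNG state, so library calls do not perturb user-level
simulations.

## Known limitations

* The network classifiers are deliberately small; at desk scale they
  underperform naive Bayes on the synthetic references (diffuse
  softmax probabilities truncate most calls below species at
  confidence 0.7). This mirrors their relative standing at full scale
  but should not be read as a measurement of their capacity.
* Architecture II's published layer stack beyond its one-hot input is
  not fully specified in the sources available to this package; it is
  implemented as "the same stack with one-hot input", and its tests use
  wider kernels because a 3-wide per-nucleotide kernel spans only 3 nt.
* The exact-match classifier is in-sample by definition: it bounds what
  any classifier could achieve on the reference, not out-of-sample
  generalization.
* Whether the original weighting pipeline pooled sample counts or
  averaged proportions is unknown; this package declares pooling.
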