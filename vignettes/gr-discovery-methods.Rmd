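---
title: "Methods: GR discovery from embeddings, exact motif p-values, and regulon inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GR discovery from embeddings, exact motif p-values, and regulon inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grdiscover)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which tunables matter, what
the synthetic generator does and does not emulate, and where the numerics
require care. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The classification model

### Embeddings

The classifier never sees raw sequence. A frozen *embedding backend* maps a
protein of length L to an L × dim matrix of per-residue features; training
updates only the classifier head, never the backend. The shipped backend,
`kmer_stub_backend(k, dim, seed)`, embeds each residue as a fixed seeded
random projection of the one-hot k-mer window centred on it (boundary
positions padded with a sentinel letter). It is deterministic at the bit
level, cheap, and order-sensitive for k > 1 — enough positional structure
for the attention layers to be exercised meaningfully — while k = 1
degrades, by construction, to a pure composition encoder whose pooled
output is invariant to shuffling. A large protein language model can be
plugged in behind the same contract (`name`, `dim`, `embed`); no test
requires one, which keeps the package download-free and CPU-sized.

One genuinely open point in this design is where pooling happens: per-token
states could be pooled before or after the task-specific encoder. This
package feeds the full L × dim matrix to the head and pools *after* the
encoder (mean over positions), which is the symmetric, length-robust
default and lets attention operate on residues rather than on one summary
vector. No positional encodings are added beyond the stub's local-window
positionality; the head must rely on content features, which is consistent
with treating the backend as the sole feature extractor.

### The head

The head is a standard transformer encoder: input projection to
`model_dim`, then `n_layers` blocks of {multi-head self-attention, residual
add, layer norm, position-wise feed-forward (ReLU), residual add, layer
norm}, then mean pooling, then one linear unit with a logistic squash. The
reference configuration is 12 layers, `model_dim` 512, 8 heads × channel
dimension 64, feed-forward inner dimension 512, dropout 0.4. The task is
deliberately binary — GR versus non-GR — rather than multi-class over GR
types: the point is to learn features *shared* across regulator families so
that entire families never seen in training can still be recognized; type
assignment is a downstream comparative step, out of scope here.

Both passes are hand-written matrix algebra (`head_forward`,
`head_backward`), so the package has no deep-learning runtime dependency
and gradients are checkable: the test suite verifies analytic gradients
against central finite differences at relative tolerance 1e-3 on a
2-layer, dim-16 configuration, sampling ~1% of parameters. Eval-mode
scoring is a pure function of (parameters, embeddings); dropout draws only
in train mode from a seeded stream.

### Training protocol

`train_config()` defaults encode the reference protocol: learning rate
1e-6 with a linear warm-up over the first 1,000 batches (the ramp shape is
this package's choice; only "warm-up" is prescribed), gradient clipping at
global L2 norm 100, weight decay 0.1 (decoupled, AdamW-style — the
optimizer family is unstated upstream, and an adaptive method with
decoupled decay is the natural match for a stated weight-decay rate),
dropout 0.4, and a fivefold sample weight on transcription-factor hard
negatives. Class imbalance is handled by keeping *all* positives every
epoch and re-subsampling the negative pool afresh (ratio `neg_per_pos`,
default 1), so successive epochs see different negative draws from a
deterministic (seed, epoch) stream.

Desk-scale runs — the package's tests, the acceptance script, the pipeline
driver — use a scaled-down configuration chosen once: a 2-layer, dim-64
head (1-layer dim-32 for the quick demo), learning rate 1e-3, warm-up 20
batches, 15 epochs, batch size 16, dropout 0. At a few hundred training
sequences, the reference rate of 1e-6 would barely move the parameters in
any reasonable epoch budget; 1e-3 with a short warm-up is a standard
choice for AdamW at this size. Scores are clamped to [1e-7, 1 − 1e-7]
inside the loss for numeric safety. The decision threshold for calls is
0.5 and configurable; the TF weight applies to the training loss only, not
to validation metrics.

### Splitting and evaluation

`make_split()` reserves whole GR types as a generalization probe: held-out
types contribute nothing to training and split 50/50 between validation
and test (odd counts favour validation — a fixed tie-break so splits are
reproducible); types with fewer than 10 sequences are rejected as holdouts.
Seen types split 80/10/10 *within type*, negatives 8:1:1 *within each
negative category*, both via `round(n/10)` shares — `floor` would violate
the ±1-sequence proportion contract at, e.g., n = 19. Evaluation mirrors
the natural strata: {all, seen, held-out} positives × {all, TF-only}
negatives, each reported as precision/sensitivity/specificity/accuracy/F1
at a threshold plus a rank-statistic AUC (midranks for ties, so the value
equals P(s⁺ > s⁻) + ½P(tie)). Per-taxon AUC restricts *both* classes to
the taxon; the alternative (taxon positives against global negatives) is a
flag away but mixes taxon effects with negative-set composition. Metrics
with empty denominators are explicit `NA` markers, never silent zeros —
strata are legitimately empty at desk scale.

## 2. Exact motif p-values and the three-tier filter

Scanning uses integer-scaled log-odds matrices: probabilities are
regularized with a background-proportional pseudocount (0.1 by default),
scored in bits against the background, and divided by a granularity g
chosen so the widest column spans at most 1000 integer bins. The null
distribution of the total integer score of a background-drawn word is
built by column-wise convolution; p-values are exact tail sums on that
support. Two numerical details: the distribution warns if g is coarse
enough to merge column scores that differ by more than 0.01 (the
documented collision tolerance), and a score above the maximum achievable
clamps to the exact mass *at* the maximum so p-values stay in (0, 1]. The
test suite checks the convolution against exhaustive 4^w enumeration at
1e-12 for widths ≤ 6, and the acceptance script recomputes that error.

Windows are the 400 nt immediately 5′ of each gene start (a proxy for the
TSS), strand-corrected, truncated at contig edges and flagged; both strands
are scanned (strandedness of the upstream search is unstated upstream —
scanning both is the conservative choice, and strand symmetry is asserted
as a property). Ambiguous bases take the worst column score, so an N can
only hurt a hit. Adjacent genes' windows are not trimmed against each
other; in the rare overlapping-window geometry one physical site may
support two genes, the simplest consistent reading.

The filter has three tiers. Tier 1 is the scan threshold p ≤ 1e-4.
Tier 2 handles very short motifs: for width < 6 the minimum *achievable*
p-value (≈ 4⁻ʷ ≥ 2.4e-4) already exceeds the tier-1 threshold, so a
literal "threshold of zero" admits nothing; the operational rule — only
words attaining the maximum achievable score, i.e. exact
consensus-strength matches — preserves the evident intent (maximal
stringency for short motifs) while remaining non-vacuous, and it *replaces*
the p gate for those motifs. Tier 3 automates symmetry inspection:
`palindromicity()` scores the fraction of consensus positions that
complement their mirror position, and motifs under 0.6 are *flagged* in the
QC table rather than having hits deleted — manual judgment cannot be
faithfully automated as a hard filter, so the package annotates and leaves
the decision to the analyst.

## 3. Regulons, the putative-GR rule, and networks

Target calls aggregate surviving hits per (GR type, genome, gene), keeping
the hit count, the best p-value, and the number of consensus-strength hits.
Orthology is an *input*: genes correspond across genomes by their
`family_label`, and when annotations carry no family tag the gene ID is
used, which collapses prevalence to per-genome presence — honest, if
weaker. Genus prevalence divides by all genomes of the genus in the
analysed set, not just genomes with calls. The core-target hierarchy is:
(i) families at ≥ 50% prevalence within a genus (inclusive — exactly half
qualifies); (ii) families passing (i) in ≥ 2 genera are cross-genus cores;
(iii) only when (ii) is empty for a GR, the top five families by overall
genome prevalence, ties lexicographic. The fallback triggers on a globally
empty tier (ii), not per genus. A candidate regulator earns putative-GR
support with ≥ 10 *distinct* (genome, gene) targets spanning ≥ 2 genomes —
the most literal reading of the rule; a per-genome variant is available
behind the thresholds.

GR→GR edges connect a regulator to every GR type encoded by its called
target genes, with support counted in (genome, gene) events; self-loops are
meaningful (autoregulation, the LexA pattern). Network scope (species- or
phylum-level) is a genome filter on the same operation. Hubs rank by
support-weighted total degree with lexicographic ties.

## 4. The synthetic generator: what it emulates, and what it does not

The generator's defaults are the package's standard study conditions,
fixed once: 8 GR types × 30 sequences, 60 TF hard negatives, 120 random
negatives; proteins of length 80 containing a shared 24-residue GR core
(5% per-sequence point mutations) and a 12-residue type-specific block at
randomized positions and order; TF negatives carry the core with 50% of
positions randomized — hard negatives by construction, interpolating
between GR-like (degradation 0) and random (degradation 1); motifs of
width 10–14 with columns drawn from a symmetric Dirichlet at concentration
0.3 (information-rich but not degenerate); 3 genomes × 200 genes on single
contigs, genes spaced so 400-nt upstream windows never overlap (an overlap
mode exists to exercise the untrimmed-window rule); consensus sites
planted with probability 1 at uniform offsets; lineages spread over up to
4 genera in 2 phyla so prevalence and per-taxon logic have structure.
Sizes were chosen so the full pipeline runs in minutes on one CPU while
every stage still has statistical room (≈ 4,600 unplanted window–motif
pairs for the false-hit rate; ≈ 170 plants for recall).

Two generator-level constraints exist to keep the *ground truth
well-defined*, not to make any test easier. First, motifs are drawn
mutually non-cross-reactive: the consensus of one motif must not score
p < 1e-3 (10× the scan threshold) under any other motif, in either
orientation, else the draw is rejected and redrawn deterministically.
Without this, a site planted for regulator A can be a bona fide binding
site for regulator B, and "false positive" stops being the right word for
B's hit there. Second, two plants in one window never overlap (offsets are
rejection-sampled against occupied intervals), so the truth registry always
matches the emitted sequence.

What the generator does *not* emulate matters for interpreting green
tests: real genomes have operons, shared promoters, GC skew, repeat
families, and motif families that genuinely cross-react; real GR families
share structure rather than a literal conserved block; real negatives are
not uniform-random proteins. Passing the suite therefore demonstrates that
the machinery is correct and that the learning mechanism (shared-core
generalization to held-out families, hard-negative weighting) works under
controlled conditions — it does not certify performance on real proteomes,
which additionally depends on the embedding backend's quality.

End-to-end recovery of the planted cross-regulation uses
*consensus-strength* calls (`n_max_hits ≥ 1`): planted consensus sites
always attain the maximum achievable score, while background hits at
p ≈ 1e-4 essentially never do, so the recovered edge set is an exact match
to the design rather than a noisy superset. Raw calls keep every
support ≥ 1 edge, as the network contract requires — at the default
threshold a background false-hit rate of order 2·400·1e-4 per window is
*expected*, and those occasionally land on GR-encoding genes.

## 5. Determinism and degenerate inputs

Every stochastic component draws from a seed derived as a pure function of
a master seed and a component tag, and restores the caller's RNG state, so
fixtures are bit-identical across runs and processes and no stage perturbs
another's stream. Degenerate inputs are defined rather than accidental:
empty windows scan to empty hit tables; an empty prevalence table yields
empty core targets; zero-epoch training returns the initialized head with
empty history; empty networks have empty rankings; single-class strata
report undefined markers. Errors name the offending record (the empty
sequence in a batch, the gene outside its contig, the holdout type with
too few sequences) so pipeline failures are diagnosable from the message.
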