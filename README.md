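# grdiscover

Global regulators (GRs) are transcription factors that steer large,
multi-pathway regulons — CRP, Fur, LexA, CodY and their relatives — and
locating them across prokaryotic genomes is hard because deep homologs keep
the fold and function while losing recognizable sequence similarity.
`grdiscover` is an R implementation of a GR discovery pipeline for people
who want to study, extend, or stress-test that kind of machinery at desk
scale: computational biologists and method developers rather than cluster
operators. Every stage is a tested, seedable function, and a built-in
synthetic-data generator produces labelled protein families, binding
motifs, and annotated genomes with planted sites so the whole pipeline can
be exercised and scored against known ground truth without any downloads.

## What it computes

**Classifier.** A binary GR/non-GR classifier head over a frozen
per-residue protein-embedding backend. The head is a transformer encoder:
input projection, `n_layers` blocks of multi-head self-attention and a
position-wise feed-forward network (residual connections with layer
normalization throughout), mean pooling over positions, then a single
logistic unit. The reference architecture is 12 layers at hidden dimension
512 with 8 heads of channel dimension 64 and feed-forward inner dimension
512; tests and examples use reduced heads. Forward *and backward* passes
are written analytically in plain matrix algebra, so training runs on one
CPU and gradients are verifiable against finite differences. Training uses
weighted binary cross-entropy

  L = − Σᵢ wᵢ [ yᵢ log sᵢ + (1−yᵢ) log(1−sᵢ) ] / Σᵢ wᵢ,

with w = 5 on transcription-factor hard negatives, per-epoch random
subsampling of the negative pool, linear learning-rate warm-up, global
gradient-norm clipping, and AdamW-style decoupled weight decay. Entire GR
types can be held out of training to measure generalization to unseen
regulator families.

**Motif scanner.** Position weight matrices are converted to log-odds
scores s(b,j) = log₂(p̂(b,j)/bg(b)) with a background-proportional
pseudocount, integer-scaled, and the exact null distribution of the total
score under the background model is built by column-wise convolution. This
gives exact p-values P(S ≥ s) identical to exhaustive enumeration over all
4^w words. 400-nt strand-corrected windows upstream of each gene start are
scanned on both strands at p ≤ 1e-4, followed by a three-tier filter:
the p threshold, a consensus-score-only rule for motifs shorter than 6 bp
(whose minimum achievable p-value exceeds 1e-4), and an automated
symmetry/complementarity QC flag replacing manual palindrome inspection.

**Regulons and networks.** Genes downstream of surviving sites become
target calls; genus-level prevalence (fraction of a genus' genomes with a
call) feeds a hierarchical core-target rule — families at ≥50% prevalence
in a genus are genus cores, genus cores corroborated in ≥2 genera are
cross-genus cores, and a top-5-by-prevalence fallback applies when no
family qualifies. A candidate regulator is supported as a putative GR when
it has ≥10 distinct predicted targets across ≥2 genomes. Calls landing on
genes that encode other GRs become directed GR→GR edges with
per-(genome, gene) support counts, from which hub statistics are derived.

## Worked example

```r
library(grdiscover)

# a small fixture: 4 GR types, 2 genomes, planted consensus sites
cfg     <- synthetic_config(n_gr_types = 4, seqs_per_type = 12,
                            n_tf_neg = 16, n_random_neg = 24,
                            n_genomes = 2, genes_per_genome = 40,
                            targets_per_type = 4, seed = 2)
motifs  <- gen_motif_set(cfg)
genomes <- gen_genomes(cfg, motifs)

scan  <- scan_genome(genomes$contigs, genomes$genes, motifs)
calls <- call_targets(scan$hits, genomes$genes)
net   <- build_network(calls[calls$n_max_hits >= 1, ], genomes$gr_gene_map)
net$edges
```

```
  source target support
1 type01 type01       2
2 type01 type02       2
3 type02 type03       2
4 type03 type04       2
5 type04 type01       2
```

Each row is a directed regulatory edge: the `source` GR has a
consensus-strength binding site upstream of a gene encoding the `target`
GR, in `support` (genome, gene) instances — here every planted edge of the
fixture's regulon design (a ring plus one autoregulatory loop) is recovered
in both genomes, and nothing else. The same objects feed the regulon side:

```r
cores <- core_targets(genus_prevalence(calls, genomes$lineages))
head(as.data.frame(cores), 3)
```

```
  gr_type  family_label       tier genera prevalence
1  type01 fam_gr_type01 genus_core GenusA          1
2  type01 fam_gr_type02 genus_core GenusA          1
3  type01        fam001 genus_core GenusA          1
```

(the first two rows are autoregulation and ring-regulation targets — gene
families that themselves encode GRs; `fam001` is an ordinary target
family).

The full chain — simulate → train → predict → scan → regulon → network →
evaluate — is one call (`run_pipeline("out_dir", seed = 1)`) or one shell
command (`Rscript inst/cli/grdiscover.R pipeline --out out_dir --seed 1`).

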