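# Shared fixture builders. The default-scale synthetic bundle and its scan
# are expensive (~15 s), so they are built lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synthetic_config(seed = seed)
    motifs <- gen_motif_set(cfg)
    genomes <- gen_genomes(cfg, motifs)
    scan <- scan_genome(genomes$contigs, genomes$genes, motifs, window = cfg$window)
    .fixture_cache[[key]] <- list(config = cfg, motifs = motifs, genomes = genomes,
                                  scan = scan, proteins = gen_protein_families(cfg))
  }
  .fixture_cache[[key]]
}

tiny_head <- function(input_dim = 8L, n_layers = 2L) {
  head_config(input_dim = input_dim, model_dim = 16L, n_layers = n_layers,
              n_heads = 2L, head_dim = 8L, ffn_dim = 16L, dropout = 0,
              max_len = 64L)
}

# small labelled corpus: n_types GR types x n_per sequences, plus negatives
toy_corpus <- function(n_types = 4L, n_per = 20L, n_tf = 10L, n_rnd = 20L, seed = 7L) {
  cfg <- synthetic_config(n_gr_types = n_types, seqs_per_type = n_per,
                          n_tf_neg = n_tf, n_random_neg = n_rnd,
                          protein_len = 50L, gr_core_len = 16L,
                          type_block_len = 6L, seed = seed)
  gen_protein_families(cfg)
}

rand_motif_matrix <- function(width) {
  m <- matrix(stats::rexp(4 * width), 4, width)
  sweep(m, 2, colSums(m), "/")
}

# brute-force tail probabilities over all 4^w words, on the integer scale
enumerate_tails <- function(lom, scores_at) {
  w <- lom$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- apply(grid, 1, function(b) sum(lom$int_scores[cbind(b, seq_len(w))]))
  pr <- apply(grid, 1, function(b) prod(lom$background[b]))
  vapply(scores_at, function(t) sum(pr[sc >= t]), numeric(1))
}
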