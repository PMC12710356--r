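mk_lineages <- function(genomes, genera) {
  data.frame(genome_id = genomes, genus = genera, family = "F", order = "O",
             class_rank = "C", phylum = "P", domain = "B", stringsAsFactors = FALSE)
}

mk_hit <- function(genome, gene, gr, p = 1e-5, n = 1L, max_score = FALSE) {
  data.frame(window_id = gene, genome_id = genome, motif_id = paste0("M_", gr),
             gr_type = gr, offset = 0L, strand = "+", score = 10,
             score_int = 100L, pvalue = p, max_score = max_score,
             stringsAsFactors = FALSE)[rep(1, n), ]
}

mk_genes <- function(genome, ids, fams = ids) {
  data.frame(gene_id = ids, genome_id = genome, contig_id = "c1",
             start = seq_along(ids) * 1000L, end = seq_along(ids) * 1000L + 100L,
             strand = "+", family_label = fams, product = "",
             stringsAsFactors = FALSE)
}

test_that("target calls aggregate hits per (gr_type, genome, gene)", {
  genes <- mk_genes("G1", c("g1", "g2"))
  hits <- rbind(mk_hit("G1", "g1", "lexA", p = 1e-5, n = 3L),
                mk_hit("G1", "g2", "lexA", p = 1e-6))
  calls <- call_targets(hits, genes)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$n_hits[calls$gene_id == "g1"], 3L)
  expect_equal(calls$best_pvalue[calls$gene_id == "g2"], 1e-6)
  expect_equal(calls$family_label, c("g1", "g2"))
  expect_equal(nrow(call_targets(hits[0, ], genes)), 0L)
  expect_error(call_targets(mk_hit("G1", "nope", "lexA"), genes), "unknown gene")
})

test_that("adjacent genes sharing an intergenic region each get their own call", {
  # two genes face away from each other; one hit in each gene's own window
  contig <- paste(rep("ACGT", 300), collapse = "")
  genes <- data.frame(gene_id = c("left", "right"), genome_id = "G1",
                      contig_id = "c1", start = c(100L, 700L), end = c(200L, 800L),
                      strand = c("-", "+"), family_label = c("fL", "fR"),
                      product = "", stringsAsFactors = FALSE)
  hits <- rbind(mk_hit("G1", "left", "crp"), mk_hit("G1", "right", "crp"))
  calls <- call_targets(hits, genes)
  expect_equal(sort(calls$gene_id), c("left", "right"))
  expect_equal(calls$family_label[order(calls$gene_id)], c("fL", "fR"))
})

test_that("genus prevalence counts called genomes over all genus genomes", {
  lin <- mk_lineages(sprintf("G%d", 1:6), rep(c("gA", "gB"), each = 3))
  genes <- do.call(rbind, lapply(sprintf("G%d", 1:6), function(g)
    mk_genes(g, paste0(g, "_x"), "famX")))
  # famX called in 2 of 3 gA genomes, 1 of 3 gB genomes
  hits <- rbind(mk_hit("G1", "G1_x", "crp"), mk_hit("G2", "G2_x", "crp"),
                mk_hit("G4", "G4_x", "crp"))
  pv <- genus_prevalence(call_targets(hits, genes), lin)
  expect_equal(pv$fraction[pv$genus == "gA"], 2 / 3)
  expect_equal(pv$fraction[pv$genus == "gB"], 1 / 3)
  expect_equal(pv$n_genomes_genus, c(3L, 3L))
  # a genus of one genome with a call has prevalence 1
  lin1 <- mk_lineages("G9", "gSolo")
  pv1 <- genus_prevalence(call_targets(mk_hit("G9", "G9_x", "crp"),
                                       mk_genes("G9", "G9_x", "famX")), lin1)
  expect_equal(pv1$fraction, 1)
  expect_error(genus_prevalence(call_targets(hits, genes), mk_lineages("G1", "gA")),
               "missing from lineage")
})

test_that("core-target hierarchy applies its three tiers exactly", {
  # 2 GR types, 3 genera, 4 genomes each (manually derived expectations)
  pv <- data.frame(
    gr_type = c(rep("crp", 5), rep("fur", 3)),
    genus = c("gA", "gB", "gA", "gC", "gB", "gA", "gB", "gC"),
    family_label = c("famCore", "famCore", "famHalf", "famLow", "famSolo",
                     "famW1", "famW2", "famW3"),
    n_called = c(3L, 2L, 2L, 1L, 3L, 1L, 1L, 1L),
    n_genomes_genus = 4L,
    stringsAsFactors = FALSE)
  pv$fraction <- pv$n_called / pv$n_genomes_genus
  ct <- core_targets(pv, min_frac = 0.5, min_genera = 2L, fallback_k = 5L)

  crp <- ct[ct$gr_type == "crp", ]
  # famCore: 0.75 in gA, 0.5 in gB (inclusive boundary) -> cross-genus core
  cross <- crp[crp$tier == "cross_genus_core", ]
  expect_equal(cross$family_label, "famCore")
  expect_equal(cross$genera, "gA;gB")
  # famHalf (0.5, one genus) and famSolo (0.75, one genus) are genus cores only
  expect_setequal(crp$family_label[crp$tier == "genus_core"],
                  c("famCore", "famHalf", "famSolo"))
  # famLow at 0.25 is nowhere
  expect_false("famLow" %in% crp$family_label)

  # fur: no family reaches 0.5 anywhere -> top-5 fallback over overall
  # prevalence 1/12 each, ties broken lexicographically
  fur <- ct[ct$gr_type == "fur", ]
  expect_true(all(fur$tier == "top5_fallback"))
  expect_equal(fur$family_label, c("famW1", "famW2", "famW3"))

  expect_equal(nrow(core_targets(pv[0, ])), 0L)
})

test_that("every cross-genus core family is a genus core in >= 2 genera", {
  fx <- default_fixture()
  calls <- call_targets(fx$scan$hits, fx$genomes$genes)
  pv <- genus_prevalence(calls, fx$genomes$lineages)
  ct <- core_targets(pv)
  cross <- ct[ct$tier == "cross_genus_core", ]
  for (i in seq_len(nrow(cross))) {
    n_gen <- sum(ct$tier == "genus_core" & ct$gr_type == cross$gr_type[i] &
                   ct$family_label == cross$family_label[i])
    expect_gte(n_gen, 2L)
  }
})

test_that("putative-GR support needs >= 10 distinct targets across >= 2 genomes", {
  mk_calls <- function(n_targets, n_genomes) {
    g <- rep(sprintf("G%d", seq_len(n_genomes)), length.out = n_targets)
    data.frame(gr_type = "cand", genome_id = g,
               gene_id = sprintf("t%02d", seq_len(n_targets)),
               family_label = "f", n_hits = 1L, best_pvalue = 1e-5,
               n_max_hits = 1L, stringsAsFactors = FALSE)
  }
  expect_false(putative_gr_support(mk_calls(10, 1))$supported)
  expect_true(putative_gr_support(mk_calls(10, 2))$supported)
  expect_false(putative_gr_support(mk_calls(9, 1))$supported)
  expect_false(putative_gr_support(mk_calls(9, 3))$supported)
  expect_true(putative_gr_support(mk_calls(12, 3))$supported)
  # monotone: adding calls never flips TRUE -> FALSE
  base <- mk_calls(10, 2)
  expect_true(putative_gr_support(rbind(base, mk_calls(5, 1)))$supported)
  ev <- putative_gr_support(mk_calls(10, 2))
  expect_equal(ev$n_targets, 10L)
  expect_equal(ev$n_genomes, 2L)
})

test_that("network edges count regulation events on GR-encoding genes", {
  genes <- rbind(mk_genes("G1", c("gene_lexA", "gene_recA")),
                 mk_genes("G2", c("gene_lexA2", "gene_other")))
  map <- data.frame(genome_id = c("G1", "G2"), gene_id = c("gene_lexA", "gene_lexA2"),
                    gr_type = "lexA", stringsAsFactors = FALSE)
  hits <- rbind(mk_hit("G1", "gene_lexA", "lexA"),    # autoregulation
                mk_hit("G1", "gene_recA", "lexA"),    # non-GR target: no edge
                mk_hit("G2", "gene_lexA2", "lexA"))
  calls <- call_targets(hits, genes)
  net <- build_network(calls, map)
  expect_equal(net$edges$source, "lexA")
  expect_equal(net$edges$target, "lexA")
  expect_equal(net$edges$support, 2L)                 # self-loop in two genomes

  # no GR-encoding genes among targets: edgeless network over present types
  net0 <- build_network(call_targets(mk_hit("G1", "gene_recA", "crp"), genes), map)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(net0$nodes, "lexA")
})

test_that("a hand-planted three-genome fixture yields the exact edge list", {
  genomes <- sprintf("G%d", 1:3)
  genes <- do.call(rbind, lapply(genomes, function(g)
    mk_genes(g, paste0(g, c("_a", "_b", "_c")), c("encA", "encB", "plain"))))
  map <- do.call(rbind, lapply(genomes, function(g)
    data.frame(genome_id = g, gene_id = paste0(g, c("_a", "_b")),
               gr_type = c("A", "B"), stringsAsFactors = FALSE)))
  # A -> B in all genomes; B -> A in G1 only; A -> plain everywhere (no edge)
  hits <- do.call(rbind, c(
    lapply(genomes, function(g) mk_hit(g, paste0(g, "_b"), "A")),
    list(mk_hit("G1", "G1_a", "B")),
    lapply(genomes, function(g) mk_hit(g, paste0(g, "_c"), "A"))))
  calls <- call_targets(hits, genes)
  net <- build_network(calls, map)
  expect_equal(net$edges,
               data.frame(source = c("A", "B"), target = c("B", "A"),
                          support = c(3L, 1L), stringsAsFactors = FALSE))
  # support conservation: edge supports sum to calls landing on GR genes
  on_gr <- sum(paste(calls$genome_id, calls$gene_id) %in%
                 paste(map$genome_id, map$gene_id))
  expect_equal(sum(net$edges$support), on_gr)
  # scope restriction
  net1 <- build_network(calls, map, scope = "G1")
  expect_equal(net1$edges$support, c(1L, 1L))
})

test_that("network statistics rank hubs deterministically", {
  star <- structure(list(
    nodes = c("C", "x1", "x2", "x3", "x4", "x5"),
    edges = data.frame(source = "C", target = paste0("x", 1:5), support = 1L,
                       stringsAsFactors = FALSE),
    scope = "all"), class = "gr_network")
  ns <- network_stats(star, top_k = 1L)
  expect_equal(ns$hubs, "C")
  expect_equal(ns$stats$out_degree[ns$stats$node == "C"], 5L)

  empty <- structure(list(nodes = character(),
                          edges = data.frame(source = character(), target = character(),
                                             support = integer()),
                          scope = "all"), class = "gr_network")
  expect_length(network_stats(empty)$hubs, 0L)

  tie <- structure(list(
    nodes = c("b", "a"),
    edges = data.frame(source = c("a", "b"), target = c("b", "a"),
                       support = c(1L, 1L), stringsAsFactors = FALSE),
    scope = "all"), class = "gr_network")
  expect_equal(network_stats(tie, top_k = 2L)$hubs, c("a", "b"))
  expect_error(network_stats(tie, top_k = 0L), "top_k")
})

test_that("GR type counts are distinct-type unions per taxon", {
  lin <- mk_lineages(c("gA", "gB", "gC"), c("genus1", "genus1", "genus2"))
  presence <- data.frame(genome_id = c("gA", "gA", "gB", "gB"),
                         gr_type = c("X", "Y", "Y", "Z"), stringsAsFactors = FALSE)
  tab <- gr_type_counts(presence, lin, rank = "genus")
  expect_equal(tab$n_gr_types[tab$taxon == "genus1"], 3L)
  expect_equal(tab$n_gr_types[tab$taxon == "genus2"], 0L)   # empty genus
  lin2 <- lin; lin2$phylum <- c("P1", "P1", "P2")
  tab2 <- gr_type_counts(presence, lin2, rank = "phylum")
  expect_equal(tab2$n_gr_types, c(3L, 0L))
  expect_error(gr_type_counts(presence, lin, rank = "kingdom"), "unknown rank")
})
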