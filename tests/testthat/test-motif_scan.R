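uniform_motif <- function(width) {
  motif_model("u", matrix(0.25, 4, width))
}

test_that("log-odds scores match closed forms", {
  # degenerate column, uniform background, vanishing pseudocount: ~2 bits for A
  m <- motif_model("d", matrix(c(1, 0, 0, 0), 4, 1))
  lom <- make_log_odds(m, pseudocount = 1e-9)
  expect_equal(unname(lom$scores["A", 1]), 2, tolerance = 1e-6)
  # uniform column, uniform background: all zeros
  lom_u <- make_log_odds(uniform_motif(3), pseudocount = 0.1)
  expect_equal(max(abs(lom_u$scores)), 0, tolerance = 1e-12)
  expect_error(make_log_odds(m, pseudocount = 0), "> 0")
})

test_that("the consensus word attains the maximal achievable score", {
  set.seed(11)
  for (i in 1:10) {
    w <- sample(2:5, 1)
    m <- motif_model("r", rand_motif_matrix(w))
    lom <- make_log_odds(m)
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    all_scores <- apply(grid, 1, function(b) sum(lom$int_scores[cbind(b, seq_len(w))]))
    cons_idx <- match(strsplit(consensus(m), "")[[1]], c("A", "C", "G", "T"))
    cons_score <- sum(lom$int_scores[cbind(cons_idx, seq_len(w))])
    expect_equal(cons_score, max(all_scores))
    expect_equal(cons_score, sum(apply(lom$int_scores, 2, max)))
  }
})

test_that("score distribution equals exhaustive enumeration and normalizes", {
  set.seed(21)
  # width 1, distinct column scores, uniform background: mass 0.25 per score
  lom1 <- make_log_odds(motif_model("w1", matrix(c(0.4, 0.3, 0.2, 0.1), 4, 1)))
  d1 <- score_distribution(lom1)
  expect_equal(sum(d1$probs), 1, tolerance = 1e-12)
  expect_equal(unname(d1$probs[d1$probs > 0]), rep(0.25, 4))

  # width 4 vs probability-weighted brute force over all 256 words
  m4 <- motif_model("w4", rand_motif_matrix(4))
  lom4 <- make_log_odds(m4)
  d4 <- score_distribution(lom4)
  sup <- which(d4$probs > 0) + d4$min_score - 1
  expect_equal(pvalue(d4, sup, is_int = TRUE), enumerate_tails(lom4, sup),
               tolerance = 1e-12)

  # normalization for random widths up to 12
  for (w in c(6, 9, 12)) {
    d <- score_distribution(make_log_odds(motif_model("n", rand_motif_matrix(w))))
    expect_equal(sum(d$probs), 1, tolerance = 1e-9)
  }
})

test_that("p-values behave at the support boundaries and decrease in score", {
  # width-1 consensus A under uniform background: only A attains the max
  lom <- make_log_odds(motif_model("a", matrix(c(0.9, 0.05, 0.03, 0.02), 4, 1)))
  d <- score_distribution(lom)
  expect_equal(pvalue(d, max(lom$int_scores), is_int = TRUE), 0.25)
  expect_equal(pvalue(d, d$min_score - 50, is_int = TRUE), 1)
  expect_equal(pvalue(d, d$min_score, is_int = TRUE), 1)

  set.seed(5)
  m3 <- motif_model("w3", rand_motif_matrix(3))
  lom3 <- make_log_odds(m3)
  d3 <- score_distribution(lom3)
  ts <- seq(d3$min_score, d3$min_score + length(d3$probs) - 1L, by = 7L)
  expect_equal(pvalue(d3, ts, is_int = TRUE), enumerate_tails(lom3, ts),
               tolerance = 1e-12)
  ps <- pvalue(d3, seq(d3$min_score, d3$min_score + length(d3$probs)), is_int = TRUE)
  expect_true(all(diff(ps) <= 0))
})

test_that("upstream windows honor strand, truncation, and degenerate cases", {
  contig <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")  # 1000 bp
  gplus <- data.frame(gene_id = "g+", genome_id = "G", contig_id = "c",
                      start = 400L, end = 500L, strand = "+",
                      family_label = "f", product = "")
  w <- extract_upstream(gplus, contig, 400)
  expect_equal(w$sequence, substr(contig, 1, 400))
  expect_false(w$truncated)

  gminus <- data.frame(gene_id = "g-", genome_id = "G", contig_id = "c",
                       start = 900L, end = 990L, strand = "-",
                       family_label = "f", product = "")
  wm <- extract_upstream(gminus, contig, 400)
  expect_equal(wm$length, 10L)
  expect_true(wm$truncated)
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  expect_equal(wm$sequence, rc(substr(contig, 991, 1000)))

  gzero <- gplus; gzero$start <- 0L; gzero$end <- 10L
  expect_equal(extract_upstream(gzero, contig, 400)$length, 0L)
  gout <- gplus; gout$end <- 2000L
  expect_error(extract_upstream(gout, contig, 400), "outside")
})

test_that("scanning finds planted consensus sites and mirrors reverse complements", {
  set.seed(31)
  m <- gen_motif(10, concentration = 0.2, seed = 13, motif_id = "m10")
  lom <- make_log_odds(m)
  d <- score_distribution(lom)
  flank1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  win <- list(sequence = paste0(flank1, consensus(m), flank2),
              gene_id = "g1", genome_id = "G")
  hits <- scan_window(win, lom, d, p_threshold = 1e-4)
  expect_true(any(hits$offset == 60 & hits$strand == "+"))
  expect_true(hits$max_score[hits$offset == 60 & hits$strand == "+"])

  # window shorter than the motif: no hits
  short <- list(sequence = "ACGTACG", gene_id = "g2", genome_id = "G")
  expect_equal(nrow(scan_window(short, lom, d)), 0L)

  # reverse-complemented window: same hits with strand flipped, offset mirrored
  rc <- function(x) chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  win_rc <- list(sequence = rc(win$sequence), gene_id = "g1", genome_id = "G")
  h2 <- scan_window(win_rc, lom, d, p_threshold = 1e-4)
  L <- nchar(win$sequence)
  mirrored <- paste(L - lom$width - hits$offset,
                    ifelse(hits$strand == "+", "-", "+"), hits$score_int)
  expect_setequal(mirrored, paste(h2$offset, h2$strand, h2$score_int))

  expect_error(scan_window(list(sequence = "ACGTX", gene_id = "g", genome_id = "G"),
                           lom, d), "outside")
})

test_that("ambiguous bases take the worst column score", {
  m <- motif_model("nn", matrix(c(0.85, 0.05, 0.05, 0.05), 4, 6,
                                dimnames = list(c("A", "C", "G", "T"), NULL)))
  lom <- make_log_odds(m)
  d <- score_distribution(lom)
  win_n <- list(sequence = "NAAAAAA", gene_id = "g", genome_id = "G")
  h <- scan_window(win_n, lom, d, p_threshold = 1)
  # offset 0 starts with N: its score is the consensus score minus the gap
  # between the best and worst first-column score
  s0 <- h$score_int[h$offset == 0 & h$strand == "+"]
  s1 <- h$score_int[h$offset == 1 & h$strand == "+"]
  expect_equal(s0 - min(lom$int_scores[, 1]), s1 - max(lom$int_scores[, 1]))
})

test_that("tier-2 keeps only maximum-score words for short motifs", {
  m5 <- motif_model("w5", matrix(rep(c(0.91, 0.03, 0.03, 0.03), 5), 4, 5))
  lom <- make_log_odds(m5)
  d <- score_distribution(lom)
  # plant exact consensus and a single-mismatch word in one window
  mism <- sub("^A", "C", consensus(m5))
  win <- list(sequence = paste0("GGTTGG", consensus(m5), "TTGGTT", mism, "GGTTGG"),
              gene_id = "g", genome_id = "G")
  hits <- scan_window(win, lom, d, p_threshold = 2e-2)  # admits 1-mismatch words
  filtered <- tier_filter(hits, lom, m5)
  expect_true(all(filtered$hits$score_int == sum(apply(lom$int_scores, 2, max))))
  expect_true(6 %in% filtered$hits$offset)           # consensus plant retained
  expect_false(17 %in% filtered$hits$offset[filtered$hits$strand == "+"])
  expect_true(filtered$qc$tier2_applied)

  # width 8: tier 2 out of scope
  m8 <- motif_model("w8", matrix(rep(c(0.91, 0.03, 0.03, 0.03), 8), 4, 8))
  lom8 <- make_log_odds(m8)
  h8 <- scan_window(list(sequence = paste0("GGTTGGTT", sub("^A", "C", consensus(m8)),
                                           "GGTTGGTT"),
                         gene_id = "g", genome_id = "G"),
                    lom8, score_distribution(lom8), p_threshold = 1e-2)
  f8 <- tier_filter(h8, lom8, m8)
  expect_false(f8$qc$tier2_applied)
  expect_equal(nrow(f8$hits), nrow(h8))
})

test_that("palindromicity scores symmetry and drives the tier-3 QC flag", {
  pal <- function(cons) {
    w <- nchar(cons)
    m <- matrix(0.01, 4, w)
    idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
    m[cbind(idx, seq_len(w))] <- 0.97
    motif_model(cons, sweep(m, 2, colSums(m), "/"))
  }
  expect_equal(palindromicity(pal("ACGT")), 1)
  expect_equal(palindromicity(pal("AAAA")), 0)
  expect_equal(palindromicity(pal("AACGTT")), 1)
  expect_error(palindromicity(pal("A")), "width")

  lom <- make_log_odds(pal("AAAA"))
  f <- tier_filter(scan_window(list(sequence = "CCAAAACC", gene_id = "g", genome_id = "G"),
                               lom, score_distribution(lom), p_threshold = 1),
                   lom, pal("AAAA"))
  expect_true(f$qc$symmetry_flagged)                 # annotated, not deleted
  expect_gt(nrow(f$hits), 0)
  f2 <- tier_filter(data.frame(), make_log_odds(pal("AACGTT")),
                    pal("AACGTT"))
  expect_false(f2$qc$symmetry_flagged)
})
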