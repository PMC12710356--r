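# PWM scanning of promoter windows with exact p-values. Log-odds scores are
# integer-scaled at a granularity g; the null distribution of the total
# integer score under the background model (independent positions) is built
# by column-by-column convolution, giving exact tail probabilities. A
# three-tier filter then suppresses spurious matches: the p <= 1e-4
# threshold, a consensus-only rule for very short motifs (< 6 bp), and an
# automated symmetry/complementarity QC flag.

#' Build an integer-scaled log-odds matrix from a motif
#'
#' Probabilities are regularized with a background-proportional pseudocount,
#' \eqn{\hat p(b,j) = (p(b,j) + c\,bg(b)) / (1 + c)}, and scored as
#' \eqn{s(b,j) = \log_2(\hat p(b,j)/bg(b))}. Integer scores are
#' \code{round(s / g)}. The default granularity is chosen so the widest
#' column score range spans at most 1000 integer bins.
#'
#' @param motif A [motif_model()].
#' @param pseudocount Positive pseudocount weight (default 0.1).
#' @param granularity Positive bin width for integer scaling, or NULL for
#'   the automatic choice.
#' @return A \code{log_odds_matrix}: motif_id, width, scores (4 x width),
#'   int_scores, granularity, background, consensus.
#' @export
make_log_odds <- function(motif, pseudocount = 0.1, granularity = NULL) {
  stopifnot(inherits(motif, "motif_model"))
  if (pseudocount <= 0) stop_input("pseudocount must be > 0")
  bg <- motif$background
  if (any(bg <= 0)) stop_input("zero background entry for motif %s", motif$motif_id)
  phat <- sweep(motif$prob_matrix, 1, bg * pseudocount, "+") / (1 + pseudocount)
  scores <- log2(sweep(phat, 1, bg, "/"))
  if (is.null(granularity)) {
    ranges <- apply(scores, 2, function(col) diff(range(col)))
    granularity <- max(max(ranges) / 1000, 1e-9)
  }
  if (granularity <= 0) stop_input("granularity must be > 0")
  int_scores <- round(scores / granularity)
  storage.mode(int_scores) <- "integer"
  structure(list(motif_id = motif$motif_id, gr_type = motif$gr_type,
                 width = motif$width, scores = scores, int_scores = int_scores,
                 granularity = granularity, background = bg,
                 consensus = consensus(motif)),
            class = "log_odds_matrix")
}

#' Exact null distribution of the integer motif score
#'
#' Probability mass function of the total integer score of a random word
#' drawn from the background model (positions independent), built by
#' convolving the per-column score distributions. Warns when the granularity
#' is coarse enough to collapse clearly distinct column scores
#' (difference > 0.01) into one bin.
#'
#' @param lom A [make_log_odds()] result.
#' @return A \code{score_distribution}: \code{probs} (pmf), \code{min_score}
#'   (integer score of probs[1]), \code{granularity}.
#' @export
score_distribution <- function(lom) {
  stopifnot(inherits(lom, "log_odds_matrix"))
  for (j in seq_len(lom$width)) {
    s <- lom$scores[, j]; is <- lom$int_scores[, j]
    for (bin in unique(is)) {
      vals <- s[is == bin]
      if (length(vals) > 1L && diff(range(vals)) > 0.01) {
        warning(sprintf("motif %s: granularity %.3g collapses distinct scores in column %d",
                        lom$motif_id, lom$granularity, j))
        break
      }
    }
  }
  mins <- apply(lom$int_scores, 2, min)
  pmf <- 1
  for (j in seq_len(lom$width)) {
    shifted <- lom$int_scores[, j] - mins[j]
    width_j <- max(shifted)
    new <- numeric(length(pmf) + width_j)
    for (b in 1:4) {
      idx <- seq_along(pmf) + shifted[b]
      new[idx] <- new[idx] + pmf * lom$background[b]
    }
    pmf <- new
  }
  structure(list(probs = pmf, min_score = sum(mins), granularity = lom$granularity),
            class = "score_distribution")
}

#' Exact motif p-value
#'
#' Tail mass \eqn{P(S \ge s)} of the null [score_distribution()], using the
#' integer-rounded score. Scores below the minimum achievable give 1; scores
#' above the maximum clamp to the exact mass at the maximum, so the p-value
#' stays in (0, 1].
#'
#' @param dist A \code{score_distribution}.
#' @param score Real score (rounded to integer bins), or an integer score if
#'   \code{is_int}.
#' @param is_int Set when \code{score} is already on the integer scale.
#' @return P-value in (0, 1].
#' @export
pvalue <- function(dist, score, is_int = FALSE) {
  k <- if (is_int) as.numeric(score) else round(score / dist$granularity)
  tails <- rev(cumsum(rev(dist$probs)))
  idx <- k - dist$min_score + 1
  n <- length(dist$probs)
  out <- numeric(length(k))
  out[idx <= 1] <- 1
  out[idx > n] <- dist$probs[n]
  inb <- idx >= 1 & idx <= n
  out[inb] <- tails[idx[inb]]
  out
}

#' Extract the upstream promoter window of a gene
#'
#' The strand-corrected sequence immediately 5' of the gene start (the
#' proxy TSS): for a + strand gene the \code{window} bases before
#' \code{start}; for a - strand gene the \code{window} bases after
#' \code{end}, reverse-complemented. Windows truncated by a contig edge are
#' returned at their reduced length and flagged.
#'
#' @param gene One gene record row ([read_gff_genes()] conventions,
#'   0-based half-open).
#' @param contig_sequence Contig DNA string.
#' @param window Window length (default 400).
#' @return An \code{upstream_window}: gene_id, genome_id, sequence, length,
#'   truncated flag, genomic interval (0-based half-open) and strand.
#' @export
extract_upstream <- function(gene, contig_sequence, window = 400L) {
  L <- nchar(contig_sequence)
  if (gene$start < 0L || gene$end > L) stop_input("gene %s outside contig", gene$gene_id)
  if (gene$strand == "+") {
    from <- max(0L, gene$start - window)
    to <- gene$start
    seq <- if (to > from) substr(contig_sequence, from + 1L, to) else ""
  } else if (gene$strand == "-") {
    from <- gene$end
    to <- min(L, gene$end + window)
    seq <- if (to > from) revcomp(substr(contig_sequence, from + 1L, to)) else ""
  } else {
    stop_input("gene %s has invalid strand '%s'", gene$gene_id, gene$strand)
  }
  structure(list(gene_id = gene$gene_id, genome_id = gene$genome_id,
                 sequence = toupper(seq), length = nchar(seq),
                 truncated = nchar(seq) < window,
                 interval = c(from, to), strand = gene$strand),
            class = "upstream_window")
}

# integer scores at every offset of `enc` (encoded ints, 5 = N) for one
# strand of the matrix; ambiguous bases take the worst (minimum) column score
score_offsets <- function(enc, int_scores) {
  w <- ncol(int_scores)
  n_off <- length(enc) - w + 1L
  if (n_off < 1L) return(integer(0))
  col_min <- apply(int_scores, 2, min)
  total <- integer(n_off)
  for (j in seq_len(w)) {
    b <- enc[j:(j + n_off - 1L)]
    sc <- ifelse(b == 5L, col_min[j], int_scores[cbind(pmin(b, 4L), j)])
    total <- total + sc
  }
  total
}

#' Scan one upstream window for motif hits
#'
#' Scores every offset on both strands and returns hits with exact p-value
#' at or below the threshold, sorted by p-value then offset. Offsets are
#' 0-based within the window; a - strand hit at offset o means the motif
#' matches the reverse complement starting at window position o.
#'
#' @param window An [extract_upstream()] result (or any list with
#'   \code{sequence}, \code{gene_id}, \code{genome_id}).
#' @param lom A [make_log_odds()] matrix.
#' @param dist The matching [score_distribution()].
#' @param p_threshold Hit threshold (default 1e-4).
#' @return Data.frame of hits: window_id, genome_id, motif_id, gr_type,
#'   offset, strand, score, score_int, pvalue.
#' @export
scan_window <- function(window, lom, dist, p_threshold = 1e-4) {
  seq <- toupper(window$sequence)
  if (nchar(seq) > 0L && grepl("[^ACGTN]", seq)) {
    stop_input("window %s contains letters outside A,C,G,T,N", window$gene_id)
  }
  empty <- data.frame(window_id = character(), genome_id = character(),
                      motif_id = character(), gr_type = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), score_int = integer(), pvalue = numeric(),
                      max_score = logical(), stringsAsFactors = FALSE)
  w <- lom$width
  if (nchar(seq) < w) return(empty)
  enc_f <- encode_dna(seq)
  enc_r <- encode_dna(revcomp(seq))
  n_off <- nchar(seq) - w + 1L
  sc_f <- score_offsets(enc_f, lom$int_scores)
  sc_r <- score_offsets(enc_r, lom$int_scores)
  hits <- data.frame(offset = c(seq_len(n_off) - 1L, nchar(seq) - w - (seq_len(n_off) - 1L)),
                     strand = rep(c("+", "-"), each = n_off),
                     score_int = c(sc_f, sc_r), stringsAsFactors = FALSE)
  hits$pvalue <- pvalue(dist, hits$score_int, is_int = TRUE)
  hits <- hits[hits$pvalue <= p_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits$score <- hits$score_int * lom$granularity
  # consensus-strength flag: the hit attains the maximum achievable score
  hits$max_score <- hits$score_int == sum(apply(lom$int_scores, 2, max))
  hits$window_id <- window$gene_id
  hits$genome_id <- window$genome_id %||% "NA"
  hits$motif_id <- lom$motif_id
  hits$gr_type <- lom$gr_type
  hits <- hits[order(hits$pvalue, hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  hits[c("window_id", "genome_id", "motif_id", "gr_type", "offset", "strand",
         "score", "score_int", "pvalue", "max_score")]
}

#' Symmetry score of a motif consensus
#'
#' Fraction of positions j whose consensus base is the Watson-Crick
#' complement of the consensus base at the mirrored position w-1-j: 1 for a
#' perfectly palindromic (self reverse-complementary) consensus.
#'
#' @param motif A [motif_model()] of width >= 2.
#' @return Palindromicity in [0, 1].
#' @export
palindromicity <- function(motif) {
  if (motif$width < 2L) stop_input("palindromicity needs width >= 2")
  cons <- strsplit(consensus(motif), "")[[1]]
  comp <- chartr("ACGT", "TGCA", rev(cons))
  mean(cons == comp)
}

#' Apply the three-tier hit filter
#'
#' Tier 1 is the p <= 1e-4 scan threshold (already applied by
#' [scan_window()]). Tier 2: for motifs shorter than 6 bp, only hits
#' attaining the maximum achievable score (exact consensus-strength matches)
#' survive — the operational form of a "p-value threshold of zero". Tier 3:
#' motifs whose consensus [palindromicity()] falls below
#' \code{symmetry_threshold} are flagged for inspection in the QC output;
#' their hits are annotated, not deleted.
#'
#' @param hits Hit data.frame from [scan_window()].
#' @param lom The [make_log_odds()] matrix the hits came from.
#' @param motif The underlying [motif_model()].
#' @param symmetry_threshold Tier-3 QC threshold (default 0.6).
#' @return List with \code{hits} (surviving hits, plus a
#'   \code{symmetry_flagged} column) and \code{qc} (one-row data.frame:
#'   motif_id, width, palindromicity, tier2_applied, symmetry_flagged).
#' @export
tier_filter <- function(hits, lom, motif, symmetry_threshold = 0.6) {
  tier2 <- lom$width < 6L
  if (tier2 && nrow(hits) > 0L) {
    max_int <- sum(apply(lom$int_scores, 2, max))
    hits <- hits[hits$score_int == max_int, , drop = FALSE]
  }
  pal <- palindromicity(motif)
  flagged <- pal < symmetry_threshold
  if (nrow(hits) > 0L) hits$symmetry_flagged <- flagged
  qc <- data.frame(motif_id = lom$motif_id, width = lom$width,
                   palindromicity = pal, tier2_applied = tier2,
                   symmetry_flagged = flagged, stringsAsFactors = FALSE)
  list(hits = hits, qc = qc)
}

#' Scan all upstream windows of a genome set against a motif set
#'
#' Convenience driver: extracts the upstream window of every gene, scans it
#' against every motif on both strands, and applies [tier_filter()].
#'
#' @param contigs Named character vector of contig sequences.
#' @param genes Gene table ([read_gff_genes()]).
#' @param motifs List of [motif_model()] objects.
#' @param window Window length (default 400).
#' @param p_threshold Tier-1 threshold (default 1e-4).
#' @param pseudocount Pseudocount for [make_log_odds()].
#' @param symmetry_threshold Tier-3 QC threshold.
#' @return List with \code{hits} (all surviving hits across genes and
#'   motifs) and \code{qc} (one row per motif).
#' @export
scan_genome <- function(contigs, genes, motifs, window = 400L, p_threshold = 1e-4,
                        pseudocount = 0.1, symmetry_threshold = 0.6) {
  loms <- lapply(motifs, make_log_odds, pseudocount = pseudocount)
  dists <- lapply(loms, score_distribution)
  # motifs under 6 bp cannot reach p <= 1e-4 (minimum achievable p-value is
  # ~4^-width), so the tier-2 consensus-only rule replaces the p threshold
  p_thr <- vapply(loms, function(l) if (l$width < 6L) 1 else p_threshold, numeric(1))
  qc <- data.frame(); all_hits <- list(); k <- 0L
  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, , drop = FALSE]
    win <- extract_upstream(gene, contigs[[gene$contig_id]], window = window)
    for (mi in seq_along(motifs)) {
      h <- scan_window(win, loms[[mi]], dists[[mi]], p_threshold = p_thr[mi])
      tf <- tier_filter(h, loms[[mi]], motifs[[mi]], symmetry_threshold)
      if (gi == 1L) qc <- rbind(qc, tf$qc)
      if (nrow(tf$hits) > 0L) {
        k <- k + 1L
        all_hits[[k]] <- tf$hits
      }
    }
  }
  hits <- if (k > 0L) do.call(rbind, all_hits) else
    cbind(scan_window(list(sequence = "", gene_id = "x", genome_id = "x"),
                      loms[[1]], dists[[1]]),
          data.frame(symmetry_flagged = logical(0)))
  rownames(hits) <- NULL
  list(hits = hits, qc = qc)
}
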