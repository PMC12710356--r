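# Deterministic synthetic fixture generator. It emulates the statistical
# structure of a GR discovery corpus: GR protein families sharing a common
# learnable core plus type-specific blocks, TF-like hard negatives carrying
# a degraded copy of that core, fully random negatives, and genomes whose
# promoter windows contain motif instances planted at known positions. All
# ground truth (labels, planted sites, true regulons, cross-regulation
# edges) is recorded so every pipeline stage can be scored exactly.

#' Synthetic fixture configuration
#'
#' Defaults are the package's standard study conditions: 8 GR types x 30
#' sequences, 60 TF hard negatives, 120 random negatives, proteins of length
#' 80 with a 24-residue shared GR core (5% per-sequence point mutations) and
#' a 12-residue type-specific block, TF cores degraded at 50% of positions;
#' motifs of width 10-14 drawn from a Dirichlet with concentration 0.3
#' (information-rich columns); 3 genomes x 200 genes with 400 nt promoter
#' windows and consensus sites planted with probability 1.
#'
#' @param n_gr_types,seqs_per_type,n_tf_neg,n_random_neg Corpus sizes.
#' @param protein_len,gr_core_len,type_block_len Protein layout (residues).
#' @param core_mut_rate Per-position mutation rate of the shared core.
#' @param tf_core_degradation Fraction of core positions randomized in TF
#'   hard negatives.
#' @param motif_width_range Integer range of motif widths.
#' @param motif_concentration Dirichlet concentration for motif columns.
#' @param n_genomes,genes_per_genome,gene_len Genome layout.
#' @param targets_per_type Target gene families per GR type.
#' @param plant_prob Probability a designated site is actually planted.
#' @param plant_mode "consensus" plants the consensus word; "sample" draws
#'   each base from the motif columns.
#' @param window Promoter window length (nt).
#' @param overlap_windows If TRUE, genes are packed so adjacent upstream
#'   windows can overlap (default FALSE: windows never overlap).
#' @param seed Master seed; the whole bundle is a pure function of the
#'   config including this seed.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_gr_types = 8L, seqs_per_type = 30L, n_tf_neg = 60L,
                             n_random_neg = 120L, protein_len = 80L,
                             gr_core_len = 24L, type_block_len = 12L,
                             core_mut_rate = 0.05, tf_core_degradation = 0.5,
                             motif_width_range = c(10L, 14L),
                             motif_concentration = 0.3, n_genomes = 3L,
                             genes_per_genome = 200L, gene_len = 120L,
                             targets_per_type = 6L, plant_prob = 1,
                             plant_mode = c("consensus", "sample"),
                             window = 400L, overlap_windows = FALSE, seed = 1L) {
  plant_mode <- match.arg(plant_mode)
  cfg <- list(n_gr_types = as.integer(n_gr_types), seqs_per_type = as.integer(seqs_per_type),
              n_tf_neg = as.integer(n_tf_neg), n_random_neg = as.integer(n_random_neg),
              protein_len = as.integer(protein_len), gr_core_len = as.integer(gr_core_len),
              type_block_len = as.integer(type_block_len), core_mut_rate = core_mut_rate,
              tf_core_degradation = tf_core_degradation,
              motif_width_range = as.integer(motif_width_range),
              motif_concentration = motif_concentration,
              n_genomes = as.integer(n_genomes), genes_per_genome = as.integer(genes_per_genome),
              gene_len = as.integer(gene_len), targets_per_type = as.integer(targets_per_type),
              plant_prob = plant_prob, plant_mode = plant_mode, window = as.integer(window),
              overlap_windows = isTRUE(overlap_windows), seed = as.integer(seed))
  if (cfg$gr_core_len + cfg$type_block_len >= cfg$protein_len) {
    stop_input("gr_core_len + type_block_len must be < protein_len")
  }
  if (cfg$plant_prob < 0 || cfg$plant_prob > 1 ||
      cfg$tf_core_degradation < 0 || cfg$tf_core_degradation > 1) {
    stop_input("fractions must lie in [0, 1]")
  }
  structure(cfg, class = "synthetic_config")
}

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
rand_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

mutate_aa <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# symmetric Dirichlet draw via gammas
rdirichlet1 <- function(alpha, k = 4L) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(k, 1L)] <- 1
  g / sum(g)
}

#' Generate a random motif
#'
#' Columns are independent draws from a symmetric Dirichlet over the four
#' bases; low concentration yields information-rich (near-degenerate)
#' columns. Deterministic per seed.
#'
#' @param width Motif width (>= 4).
#' @param concentration Dirichlet concentration parameter.
#' @param seed Integer seed.
#' @param motif_id,gr_type Identifiers for the motif model.
#' @return A [motif_model()].
#' @export
gen_motif <- function(width, concentration = 0.3, seed = 1L,
                      motif_id = "motif", gr_type = motif_id) {
  if (width < 4L) stop_input("motif width must be >= 4")
  if (concentration <= 0) stop_input("concentration must be > 0")
  m <- with_seed(seed, vapply(seq_len(width), function(j) rdirichlet1(concentration),
                              numeric(4)))
  motif_model(motif_id, m, gr_type = gr_type)
}

#' Generate labelled synthetic protein families
#'
#' Every GR sequence carries the shared GR core (identical across types, 5%
#' per-sequence point mutations) at a random offset plus a type-specific
#' conserved block; TF hard negatives carry the core with
#' \code{tf_core_degradation} of its positions randomized; random negatives
#' are uniform filler. Deterministic per config seed.
#'
#' @param config A [synthetic_config()].
#' @return Data.frame with columns protein_id, sequence, label, genome_id.
#' @export
gen_protein_families <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, "proteins"), {
    core <- rand_aa(config$gr_core_len)
    type_blocks <- vapply(seq_len(config$n_gr_types), function(i) rand_aa(config$type_block_len),
                          character(1))
    filler_len <- config$protein_len - config$gr_core_len - config$type_block_len
    build_with_core <- function(core_seq, block) {
      # random layout: filler split around the two designed blocks, whose
      # order is itself randomized, so position carries no label signal
      fill <- sample(0:filler_len, 2L)
      f1 <- min(fill); f2 <- max(fill) - f1; f3 <- filler_len - f1 - f2
      pieces <- if (sample(c(TRUE, FALSE), 1L)) c(core_seq, block) else c(block, core_seq)
      paste0(rand_aa(f1), pieces[1], rand_aa(f2), pieces[2], rand_aa(f3))
    }
    rows <- list(); k <- 0L
    for (ty in seq_len(config$n_gr_types)) {
      for (i in seq_len(config$seqs_per_type)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          protein_id = sprintf("gr%02d_%03d", ty, i),
          sequence = build_with_core(mutate_aa(core, config$core_mut_rate),
                                     mutate_aa(type_blocks[ty], config$core_mut_rate)),
          label = sprintf("gr:type%02d", ty), stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(config$n_tf_neg)) {
      k <- k + 1L
      degraded <- mutate_aa(core, 1)  # fully random replacement at chosen positions
      chars_core <- strsplit(core, "")[[1]]
      chars_deg <- strsplit(degraded, "")[[1]]
      keep <- stats::runif(config$gr_core_len) >= config$tf_core_degradation
      chars_deg[keep] <- chars_core[keep]
      rows[[k]] <- data.frame(
        protein_id = sprintf("tf_%03d", i),
        sequence = build_with_core(paste(chars_deg, collapse = ""),
                                   rand_aa(config$type_block_len)),
        label = "tf", stringsAsFactors = FALSE)
    }
    for (i in seq_len(config$n_random_neg)) {
      k <- k + 1L
      rows[[k]] <- data.frame(protein_id = sprintf("rnd_%03d", i),
                              sequence = rand_aa(config$protein_len),
                              label = "other:random", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$genome_id <- sprintf("genome%02d", (seq_len(nrow(out)) %% max(config$n_genomes, 1L)) + 1L)
    out
  })
}

#' Default regulon design for a config
#'
#' Assigns each GR type \code{targets_per_type} target gene families (all
#' present in every genome), one gene family per genome encoding each GR
#' type, a ring of cross-regulation edges type_i -> type_{i+1}, and a
#' self-loop on type 1 (the autoregulation pattern canonical for regulators
#' such as LexA).
#'
#' @param config A [synthetic_config()].
#' @return List with \code{gr_types}, \code{targets} (list per type of
#'   family labels), \code{gr_gene_family} (family encoding each type), and
#'   \code{cross_edges} (data.frame source, target).
#' @export
default_regulon_design <- function(config) {
  gr_types <- sprintf("type%02d", seq_len(config$n_gr_types))
  gr_fams <- sprintf("fam_gr_%s", gr_types)
  names(gr_fams) <- gr_types
  n_plain <- config$genes_per_genome - config$n_gr_types
  plain_fams <- sprintf("fam%03d", seq_len(n_plain))
  targets <- list()
  ring_next <- c(seq_len(config$n_gr_types)[-1], 1L)
  for (i in seq_along(gr_types)) {
    own <- plain_fams[((i - 1L) * config$targets_per_type + seq_len(config$targets_per_type) - 1L) %%
                        n_plain + 1L]
    # cross-regulation: each type also targets the gene family encoding the
    # next type in the ring; type 1 additionally targets its own gene.
    extra <- gr_fams[ring_next[i]]
    if (i == 1L) extra <- c(extra, gr_fams[1L])
    targets[[gr_types[i]]] <- unique(c(own, unname(extra)))
  }
  cross <- data.frame(source = gr_types, target = gr_types[ring_next],
                      stringsAsFactors = FALSE)
  cross <- rbind(cross, data.frame(source = gr_types[1], target = gr_types[1]))
  cross <- cross[order(cross$source, cross$target), , drop = FALSE]
  rownames(cross) <- NULL
  list(gr_types = gr_types, targets = targets, gr_gene_family = gr_fams,
       cross_edges = cross)
}

#' Generate synthetic genomes with planted binding sites
#'
#' Lays non-overlapping genes (alternating strands) on one background
#' contig per genome, spaced so upstream windows never overlap by default,
#' and plants a motif instance (consensus or PWM-sampled, per config) at a
#' uniform random offset in the upstream window of every designated (GR,
#' target family) pair with probability \code{plant_prob}. All plants are
#' recorded in the returned truth.
#'
#' @param config A [synthetic_config()].
#' @param motifs Named list of [motif_model()] per GR type.
#' @param design Regulon design ([default_regulon_design()]).
#' @return List with \code{contigs} (named character), \code{genes} (gene
#'   table), \code{lineages}, \code{gr_gene_map} (genome_id, gene_id,
#'   gr_type), and \code{truth}: \code{plants} (genome_id, gene_id,
#'   gr_type, motif_id, offset, strand, site), \code{regulons} (gr_type,
#'   genome_id, gene_id, family_label), \code{cross_edges}.
#' @export
gen_genomes <- function(config, motifs, design = default_regulon_design(config)) {
  stopifnot(inherits(config, "synthetic_config"))
  # default spacing leaves room for a - strand window followed by a + strand
  # window in the same intergenic gap, so upstream windows never overlap
  gap <- if (config$overlap_windows) config$window %/% 4L else 2L * config$window + 40L
  stride <- config$gene_len + gap
  contig_len <- config$genes_per_genome * stride + config$window + 100L
  genera <- c("GenusA", "GenusB", "GenusC", "GenusD")
  phyla <- c("PhylumX", "PhylumY")
  with_seed(derive_seed(config$seed, "genomes"), {
    contigs <- character(0); gene_rows <- list(); plant_rows <- list()
    regulon_rows <- list(); map_rows <- list()
    fam_panel <- c(sprintf("fam%03d", seq_len(config$genes_per_genome - config$n_gr_types)),
                   unname(design$gr_gene_family))
    for (g in seq_len(config$n_genomes)) {
      genome_id <- sprintf("genome%02d", g)
      contig_id <- sprintf("%s_c1", genome_id)
      contig <- strsplit(rand_dna(contig_len), "")[[1]]
      fams <- sample(fam_panel)  # shuffle gene order per genome
      strands <- sample(c("+", "-"), config$genes_per_genome, replace = TRUE)
      starts <- config$window + 50L + (seq_len(config$genes_per_genome) - 1L) * stride
      genes <- data.frame(
        gene_id = sprintf("%s_g%03d", genome_id, seq_len(config$genes_per_genome)),
        genome_id = genome_id, contig_id = contig_id,
        start = starts, end = starts + config$gene_len, strand = strands,
        family_label = fams, product = "", stringsAsFactors = FALSE)
      # map gene families encoding GR proteins
      for (ty in design$gr_types) {
        idx <- which(genes$family_label == design$gr_gene_family[[ty]])
        map_rows[[length(map_rows) + 1L]] <- data.frame(
          genome_id = genome_id, gene_id = genes$gene_id[idx], gr_type = ty,
          stringsAsFactors = FALSE)
      }
      # plant sites; track occupied window intervals per gene so two motifs
      # planted in the same window never overwrite each other
      occupied <- list()
      for (ty in design$gr_types) {
        motif <- motifs[[ty]]
        for (fam in design$targets[[ty]]) {
          gi <- which(genes$family_label == fam)
          if (length(gi) == 0L) next
          gene <- genes[gi, ]
          regulon_rows[[length(regulon_rows) + 1L]] <- data.frame(
            gr_type = ty, genome_id = genome_id, gene_id = gene$gene_id,
            family_label = fam, stringsAsFactors = FALSE)
          if (stats::runif(1) > config$plant_prob) next
          site <- if (config$plant_mode == "consensus") consensus(motif) else {
            paste(DNA_BASES[vapply(seq_len(motif$width), function(j)
              sample.int(4L, 1L, prob = motif$prob_matrix[, j]), 1L)], collapse = "")
          }
          occ <- occupied[[gene$gene_id]] %||% integer(0)
          off <- NA_integer_
          for (try in 1:50) {
            cand <- sample.int(config$window - motif$width + 1L, 1L) - 1L
            span <- cand:(cand + motif$width - 1L)
            if (!length(intersect(span, occ))) { off <- cand; break }
          }
          if (is.na(off)) next
          occupied[[gene$gene_id]] <- c(occ, off:(off + motif$width - 1L))
          # window-space -> genomic coordinates
          if (gene$strand == "+") {
            gpos <- gene$start - config$window + off            # 0-based
            contig[(gpos + 1L):(gpos + motif$width)] <- strsplit(site, "")[[1]]
          } else {
            gpos <- gene$end + config$window - off - motif$width
            contig[(gpos + 1L):(gpos + motif$width)] <- strsplit(revcomp(site), "")[[1]]
          }
          plant_rows[[length(plant_rows) + 1L]] <- data.frame(
            genome_id = genome_id, gene_id = gene$gene_id, gr_type = ty,
            motif_id = motif$motif_id, offset = off, strand = "+",
            site = site, stringsAsFactors = FALSE)
        }
      }
      contigs[contig_id] <- paste(contig, collapse = "")
      gene_rows[[g]] <- genes
    }
    genes <- do.call(rbind, gene_rows)
    rownames(genes) <- NULL
    lineages <- data.frame(
      genome_id = sprintf("genome%02d", seq_len(config$n_genomes)),
      genus = genera[(seq_len(config$n_genomes) - 1L) %% 4L + 1L],
      family = paste0("Family", (seq_len(config$n_genomes) - 1L) %% 4L + 1L),
      order = paste0("Order", (seq_len(config$n_genomes) - 1L) %% 2L + 1L),
      class_rank = paste0("Class", (seq_len(config$n_genomes) - 1L) %% 2L + 1L),
      phylum = phyla[(seq_len(config$n_genomes) - 1L) %% 2L + 1L],
      domain = "Bacteria", stringsAsFactors = FALSE)
    bind_or_empty <- function(rows, cols) {
      if (length(rows)) do.call(rbind, rows) else
        stats::setNames(as.data.frame(replicate(length(cols), character(0),
                                                simplify = FALSE)), cols)
    }
    list(contigs = contigs, genes = genes, lineages = lineages,
         gr_gene_map = bind_or_empty(map_rows, c("genome_id", "gene_id", "gr_type")),
         truth = list(plants = bind_or_empty(plant_rows,
                        c("genome_id", "gene_id", "gr_type", "motif_id", "offset",
                          "strand", "site")),
                      regulons = bind_or_empty(regulon_rows,
                        c("gr_type", "genome_id", "gene_id", "family_label")),
                      cross_edges = design$cross_edges))
  })
}

#' Generate motifs for every GR type of a config
#'
#' Motifs are drawn independently per type and required to be mutually
#' non-cross-reactive: the consensus word of every motif (either
#' orientation) must not score a sub-threshold p-value (< 1e-3, a 10x
#' safety margin over the scan threshold) under any other motif's scoring
#' matrix. Without this constraint a site planted for one GR could be a
#' bona fide binding site for another, making the planted ground truth
#' ill-defined. Cross-reactive draws are rejected and redrawn
#' deterministically.
#'
#' @param config A [synthetic_config()].
#' @param cross_p Cross-reactivity p-value floor (default 1e-3).
#' @return Named list of [motif_model()], one per GR type.
#' @export
gen_motif_set <- function(config, cross_p = 1e-3) {
  gr_types <- sprintf("type%02d", seq_len(config$n_gr_types))
  widths <- with_seed(derive_seed(config$seed, "widths"),
                      sample(seq(config$motif_width_range[1], config$motif_width_range[2]),
                             config$n_gr_types, replace = TRUE))
  # best p-value of any alignment of `word` (and its reverse complement)
  # under the motif's scoring matrix
  best_cross_p <- function(lom, dist, word) {
    p <- 1
    for (w in c(word, revcomp(word))) {
      if (nchar(w) < lom$width) next
      sc <- score_offsets(encode_dna(w), lom$int_scores)
      if (length(sc)) p <- min(p, pvalue(dist, max(sc), is_int = TRUE))
    }
    p
  }
  motifs <- list(); loms <- list(); dists <- list()
  for (i in seq_along(gr_types)) {
    for (attempt in 0:100) {
      cand <- gen_motif(widths[i], config$motif_concentration,
                        seed = derive_seed(config$seed, paste0("motif", i, "_", attempt)),
                        motif_id = paste0("M_", gr_types[i]), gr_type = gr_types[i])
      lom <- make_log_odds(cand)
      dist <- score_distribution(lom)
      ok <- TRUE
      for (j in seq_along(motifs)) {
        if (best_cross_p(loms[[j]], dists[[j]], consensus(cand)) < cross_p ||
            best_cross_p(lom, dist, consensus(motifs[[j]])) < cross_p) {
          ok <- FALSE
          break
        }
      }
      if (ok) break
    }
    motifs[[i]] <- cand; loms[[i]] <- lom; dists[[i]] <- dist
  }
  names(motifs) <- gr_types
  motifs
}

#' Generate the full on-disk fixture bundle
#'
#' Writes proteins (FASTA + label TSV), motifs (MEME minimal), genomes
#' (FASTA + GFF3), lineages (TSV), the GR-gene map (TSV), and a JSON truth
#' manifest (config echo, planted sites, true regulons, cross-regulation
#' edges) into \code{out_dir}. The bundle is bit-identical across runs with
#' the same config.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the in-memory fixture (proteins, motifs, genomes
#'   object, file paths).
#' @export
gen_full_fixture <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    stop_input("output directory %s is not empty (use force = TRUE)", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  proteins <- gen_protein_families(config)
  motifs <- gen_motif_set(config)
  design <- default_regulon_design(config)
  genomes <- gen_genomes(config, motifs, design)
  paths <- list(
    proteins_fasta = file.path(out_dir, "proteins.fasta"),
    labels_tsv = file.path(out_dir, "labels.tsv"),
    motifs_meme = file.path(out_dir, "motifs.meme"),
    genomes_fasta = file.path(out_dir, "genomes.fasta"),
    genes_gff = file.path(out_dir, "genes.gff3"),
    lineages_tsv = file.path(out_dir, "lineages.tsv"),
    gr_gene_map_tsv = file.path(out_dir, "gr_gene_map.tsv"),
    truth_json = file.path(out_dir, "truth.json"))
  write_fasta(stats::setNames(proteins$sequence, proteins$protein_id), paths$proteins_fasta)
  utils::write.table(proteins[c("protein_id", "label")], paths$labels_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_meme_motifs(motifs, paths$motifs_meme)
  write_fasta(genomes$contigs, paths$genomes_fasta)
  write_gff_genes(genomes$genes, paths$genes_gff)
  write_lineages(genomes$lineages, paths$lineages_tsv)
  utils::write.table(genomes$gr_gene_map, paths$gr_gene_map_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(config = unclass(config),
                            plants = genomes$truth$plants,
                            regulons = genomes$truth$regulons,
                            cross_edges = genomes$truth$cross_edges),
                       paths$truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = config, proteins = proteins, motifs = motifs,
                 genomes = genomes, paths = paths))
}
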