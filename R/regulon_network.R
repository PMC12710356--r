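# From filtered motif hits to regulons and networks: target-gene calling,
# genus-level prevalence, the hierarchical core-target rules (genus core ->
# cross-genus core -> top-5 fallback), the putative-GR support rule (>= 10
# distinct targets across >= 2 genomes), and directed GR-GR network
# construction with hub statistics.

#' Aggregate motif hits into target-gene calls
#'
#' One call per (gr_type, genome, gene) with at least one surviving hit;
#' genes immediately downstream of a predicted binding site are the
#' candidate targets. Hit counts and the best p-value are aggregated.
#'
#' @param hits Hit data.frame (from [scan_genome()] / [tier_filter()]);
#'   \code{window_id} is the gene the window belongs to.
#' @param genes Gene table ([read_gff_genes()]).
#' @return Data.frame of calls: gr_type, genome_id, gene_id, family_label,
#'   n_hits, best_pvalue.
#' @export
call_targets <- function(hits, genes) {
  empty <- data.frame(gr_type = character(), genome_id = character(),
                      gene_id = character(), family_label = character(),
                      n_hits = integer(), best_pvalue = numeric(),
                      n_max_hits = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  gene_key <- paste(genes$genome_id, genes$gene_id)
  hit_key <- paste(hits$genome_id, hits$window_id)
  if (any(!hit_key %in% gene_key)) {
    stop_input("hit references unknown gene: %s",
               paste(utils::head(unique(hit_key[!hit_key %in% gene_key]), 3), collapse = "; "))
  }
  grp <- paste(hits$gr_type, hits$genome_id, hits$window_id, sep = "\r")
  agg_n <- tapply(rep(1L, nrow(hits)), grp, sum)
  agg_p <- tapply(hits$pvalue, grp, min)
  has_max <- if ("max_score" %in% names(hits)) hits$max_score else rep(FALSE, nrow(hits))
  agg_m <- tapply(as.integer(has_max), grp, sum)
  parts <- strsplit(names(agg_n), "\r", fixed = TRUE)
  out <- data.frame(gr_type = vapply(parts, `[`, "", 1L),
                    genome_id = vapply(parts, `[`, "", 2L),
                    gene_id = vapply(parts, `[`, "", 3L),
                    n_hits = as.integer(agg_n), best_pvalue = as.numeric(agg_p),
                    n_max_hits = as.integer(agg_m), stringsAsFactors = FALSE)
  out$family_label <- genes$family_label[match(paste(out$genome_id, out$gene_id), gene_key)]
  out <- out[order(out$gr_type, out$genome_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out[c("gr_type", "genome_id", "gene_id", "family_label", "n_hits", "best_pvalue",
        "n_max_hits")]
}

#' Genus-level prevalence of called target families
#'
#' For every (gr_type, genus, family) the fraction of the genus' genomes in
#' which that family is called. The denominator is the number of genomes of
#' the genus present in the input genome set, whether or not they have any
#' calls.
#'
#' @param calls Target calls ([call_targets()]).
#' @param lineages Lineage table covering every genome in \code{calls}.
#' @param genome_ids All genomes in the analysed set (defaults to the
#'   lineage table's genomes).
#' @return Data.frame: gr_type, genus, family_label, n_called,
#'   n_genomes_genus, fraction.
#' @export
genus_prevalence <- function(calls, lineages, genome_ids = lineages$genome_id) {
  missing <- setdiff(unique(calls$genome_id), lineages$genome_id)
  if (length(missing)) {
    stop_input("genome(s) missing from lineage table: %s", paste(missing, collapse = ", "))
  }
  genus_of <- stats::setNames(lineages$genus, lineages$genome_id)
  genus_sizes <- table(genus_of[intersect(genome_ids, names(genus_of))])
  if (nrow(calls) == 0L) {
    return(data.frame(gr_type = character(), genus = character(),
                      family_label = character(), n_called = integer(),
                      n_genomes_genus = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  calls$genus <- genus_of[calls$genome_id]
  # a family counts once per genome
  u <- unique(calls[c("gr_type", "genus", "family_label", "genome_id")])
  grp <- paste(u$gr_type, u$genus, u$family_label, sep = "\r")
  n_called <- tapply(rep(1L, nrow(u)), grp, sum)
  parts <- strsplit(names(n_called), "\r", fixed = TRUE)
  out <- data.frame(gr_type = vapply(parts, `[`, "", 1L),
                    genus = vapply(parts, `[`, "", 2L),
                    family_label = vapply(parts, `[`, "", 3L),
                    n_called = as.integer(n_called), stringsAsFactors = FALSE)
  out$n_genomes_genus <- as.integer(genus_sizes[out$genus])
  out$fraction <- out$n_called / out$n_genomes_genus
  out <- out[order(out$gr_type, out$genus, out$family_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchical core-target inference
#'
#' Per GR type: (i) families reaching \code{min_frac} prevalence within a
#' genus are genus-level core targets; (ii) families passing (i) in at least
#' \code{min_genera} genera are cross-genus core targets; (iii) if no family
#' passes (ii) for a GR, the \code{fallback_k} families with the highest
#' overall genome prevalence are selected instead (ties broken
#' lexicographically). The \code{min_frac} comparison is inclusive
#' (a family in exactly 50% of a genus' genomes qualifies).
#'
#' @param prevalence Output of [genus_prevalence()].
#' @param min_frac Genus-level prevalence threshold (default 0.5).
#' @param min_genera Minimum qualifying genera for a cross-genus core
#'   (default 2).
#' @param fallback_k Families selected by the fallback rule (default 5).
#' @return A \code{core_targets} object: data.frame with gr_type,
#'   family_label, tier (genus_core / cross_genus_core / top5_fallback),
#'   genera (";"-joined), prevalence (";"-joined per-genus fractions, or the
#'   overall prevalence for fallback rows).
#' @export
core_targets <- function(prevalence, min_frac = 0.5, min_genera = 2L, fallback_k = 5L) {
  out <- data.frame(gr_type = character(), family_label = character(),
                    tier = character(), genera = character(),
                    prevalence = character(), stringsAsFactors = FALSE)
  if (nrow(prevalence) == 0L) return(structure(out, class = c("core_targets", "data.frame")))
  for (ty in sort(unique(prevalence$gr_type))) {
    pv <- prevalence[prevalence$gr_type == ty, , drop = FALSE]
    tier1 <- pv[pv$fraction >= min_frac, , drop = FALSE]
    if (nrow(tier1) > 0L) {
      out <- rbind(out, data.frame(gr_type = ty, family_label = tier1$family_label,
                                   tier = "genus_core", genera = tier1$genus,
                                   prevalence = format_frac(tier1$fraction),
                                   stringsAsFactors = FALSE))
    }
    cross <- character(0)
    if (nrow(tier1) > 0L) {
      n_gen <- tapply(tier1$genus, tier1$family_label, function(g) length(unique(g)))
      cross <- sort(names(n_gen)[n_gen >= min_genera])
    }
    if (length(cross) > 0L) {
      for (fam in cross) {
        sub <- tier1[tier1$family_label == fam, , drop = FALSE]
        sub <- sub[order(sub$genus), , drop = FALSE]
        out <- rbind(out, data.frame(gr_type = ty, family_label = fam,
                                     tier = "cross_genus_core",
                                     genera = paste(sub$genus, collapse = ";"),
                                     prevalence = paste(format_frac(sub$fraction), collapse = ";"),
                                     stringsAsFactors = FALSE))
      }
    } else {
      # overall genome prevalence: called genomes over all genomes in the set
      n_total <- sum(tapply(pv$n_genomes_genus, pv$genus, function(x) x[1]))
      overall <- tapply(pv$n_called, pv$family_label, sum) / n_total
      ord <- order(-overall, names(overall), method = "radix")
      pick <- utils::head(ord, fallback_k)
      out <- rbind(out, data.frame(gr_type = ty, family_label = names(overall)[pick],
                                   tier = "top5_fallback", genera = NA_character_,
                                   prevalence = format_frac(as.numeric(overall[pick])),
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("core_targets", "data.frame"))
}

format_frac <- function(x) formatC(x, digits = 6, format = "fg")

#' Putative-GR support rule
#'
#' A candidate regulator is supported as a putative GR when it has at least
#' \code{min_targets} distinct (genome, gene) predicted targets spanning at
#' least \code{min_genomes} genomes.
#'
#' @param calls Target calls for a single candidate.
#' @param min_targets Minimum distinct targets (default 10).
#' @param min_genomes Minimum distinct genomes (default 2).
#' @return List: supported (logical), n_targets, n_genomes,
#'   per_genome (named target counts).
#' @export
putative_gr_support <- function(calls, min_targets = 10L, min_genomes = 2L) {
  u <- unique(calls[c("genome_id", "gene_id")])
  per_genome <- if (nrow(u)) table(u$genome_id) else table(character(0))
  list(supported = nrow(u) >= min_targets && length(per_genome) >= min_genomes,
       n_targets = nrow(u), n_genomes = length(per_genome),
       per_genome = per_genome)
}

#' Build the directed GR-GR regulatory network
#'
#' An edge A -> B with support s means A has target calls on s distinct
#' (genome, gene) pairs whose gene encodes a type-B GR within the scope's
#' genomes. Self-loops (autoregulation) are permitted. Nodes are all GR
#' types on an edge plus isolated GR types encoded in the scope.
#'
#' @param calls Target calls ([call_targets()]).
#' @param gr_gene_map Data.frame (genome_id, gene_id, gr_type): which genes
#'   encode which GR type.
#' @param scope Genome ids to restrict to (NULL = all).
#' @return A \code{gr_network}: list with \code{nodes}, \code{edges}
#'   (source, target, support), \code{scope}.
#' @export
build_network <- function(calls, gr_gene_map, scope = NULL) {
  if (!is.null(scope)) {
    calls <- calls[calls$genome_id %in% scope, , drop = FALSE]
    gr_gene_map <- gr_gene_map[gr_gene_map$genome_id %in% scope, , drop = FALSE]
  }
  key <- paste(gr_gene_map$genome_id, gr_gene_map$gene_id)
  hit <- match(paste(calls$genome_id, calls$gene_id), key)
  ev <- calls[!is.na(hit), , drop = FALSE]
  ev$target_type <- gr_gene_map$gr_type[hit[!is.na(hit)]]
  ev <- unique(ev[c("gr_type", "target_type", "genome_id", "gene_id")])
  if (nrow(ev)) {
    grp <- paste(ev$gr_type, ev$target_type, sep = "\r")
    supp <- tapply(rep(1L, nrow(ev)), grp, sum)
    parts <- strsplit(names(supp), "\r", fixed = TRUE)
    edges <- data.frame(source = vapply(parts, `[`, "", 1L),
                        target = vapply(parts, `[`, "", 2L),
                        support = as.integer(supp), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        support = integer(), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$source, edges$target, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$source, edges$target, gr_gene_map$gr_type)))
  structure(list(nodes = nodes, edges = edges,
                 scope = scope %||% "all"), class = "gr_network")
}

#' Node-level network statistics and hub ranking
#'
#' In/out degree and support-weighted degree per node (via igraph), with a
#' deterministic hub ranking by weighted total degree, ties broken
#' lexicographically.
#'
#' @param network A \code{gr_network}.
#' @param top_k Number of hubs to report.
#' @return List: \code{stats} (node, in_degree, out_degree, w_in, w_out,
#'   w_total) and \code{hubs} (top_k node names).
#' @export
network_stats <- function(network, top_k = 5L) {
  if (top_k < 1L) stop_input("top_k must be >= 1")
  nodes <- network$nodes
  if (length(nodes) == 0L) {
    return(list(stats = data.frame(node = character(), in_degree = integer(),
                                   out_degree = integer(), w_in = numeric(),
                                   w_out = numeric(), w_total = numeric()),
                hubs = character()))
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  st <- data.frame(
    node = nodes,
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out")),
    w_in = as.numeric(igraph::strength(g, mode = "in", weights = igraph::E(g)$support)),
    w_out = as.numeric(igraph::strength(g, mode = "out", weights = igraph::E(g)$support)),
    stringsAsFactors = FALSE)
  st$w_total <- st$w_in + st$w_out
  st <- st[order(-st$w_total, st$node, method = "radix"), , drop = FALSE]
  rownames(st) <- NULL
  list(stats = st, hubs = utils::head(st$node, top_k))
}

#' Count distinct GR types per taxon
#'
#' @param presence Data.frame (genome_id, gr_type): which GR types each
#'   genome encodes or was called with.
#' @param lineages Lineage table.
#' @param rank Taxonomic rank (genus, family, order, class, phylum, domain).
#' @return Data.frame (taxon, n_gr_types) with the distinct-type union per
#'   taxon.
#' @export
gr_type_counts <- function(presence, lineages, rank = "phylum") {
  col <- rank_column(rank)
  taxon <- lineages[[col]][match(presence$genome_id, lineages$genome_id)]
  if (anyNA(taxon)) stop_input("genome(s) missing from lineage table")
  u <- unique(data.frame(taxon = taxon, gr_type = presence$gr_type,
                         stringsAsFactors = FALSE))
  all_taxa <- sort(unique(lineages[[col]]))
  counts <- table(factor(u$taxon, levels = all_taxa))
  data.frame(taxon = all_taxa, n_gr_types = as.integer(counts),
             stringsAsFactors = FALSE)
}
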