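# Readers and writers for the plain-text formats the pipeline touches:
# FASTA, a GFF3 "gene" subset, MEME minimal motifs, and TSV tables.
# Internal coordinates are 0-based half-open everywhere; conversion from the
# 1-based inclusive file convention happens only here, at the file boundary.

#' Read a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Sequences
#' are uppercased; record order is preserved.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return A named character vector, one uppercased sequence per record;
#'   names are the full header lines (word up to first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file does not exist: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop_input("FASTA file is empty: %s", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Consumes only rows with feature type \code{gene}; all other rows are
#' ignored. 1-based inclusive GFF coordinates are converted to the package's
#' 0-based half-open convention, so \code{end - start} equals the gene length.
#' The orthology/gene-family key is taken from a \code{family} attribute and
#' defaults to the gene's \code{ID} when absent, so downstream prevalence
#' logic always has a comparable key.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame of gene records: \code{gene_id}, \code{genome_id},
#'   \code{contig_id}, \code{start} (0-based), \code{end} (exclusive),
#'   \code{strand}, \code{family_label}, \code{product}.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop_input("GFF file does not exist: %s", path)
  gr <- rtracklayer::import(con = path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop_input("gene rows with unknown strand symbol (only + and - are allowed): %s",
               paste(utils::head(gr$ID[bad], 3), collapse = ", "))
  }
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  if (any(is.na(ids) | !nzchar(ids))) stop_input("every gene row needs an ID attribute")
  fam <- if ("family" %in% names(md)) as.character(md$family) else rep(NA_character_, length(gr))
  genome <- if ("genome" %in% names(md)) as.character(md$genome) else rep(NA_character_, length(gr))
  prod <- if ("product" %in% names(md)) as.character(md$product) else rep("", length(gr))
  out <- data.frame(
    gene_id = ids,
    genome_id = ifelse(is.na(genome), "NA", genome),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    family_label = ifelse(is.na(fam) | !nzchar(fam), ids, fam),
    product = ifelse(is.na(prod), "", prod),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 0L | out$start >= out$end)) stop_input("gene with start > end in %s", path)
  if (anyDuplicated(paste(out$genome_id, out$gene_id))) {
    stop_input("duplicated gene_id within a genome in %s", path)
  }
  rownames(out) <- NULL
  out
}

#' Write gene records to a GFF3 file
#'
#' Inverse of [read_gff_genes()]: converts the 0-based half-open internal
#' coordinates back to 1-based inclusive.
#'
#' @param genes Data.frame as returned by [read_gff_genes()].
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  attrs <- sprintf("ID=%s;genome=%s;family=%s", genes$gene_id, genes$genome_id,
                   genes$family_label)
  has_prod <- nzchar(genes$product %||% "")
  if (any(has_prod)) attrs[has_prod] <- paste0(attrs[has_prod], ";product=", genes$product[has_prod])
  lines <- sprintf("%s\tgrdiscover\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$contig_id, genes$start + 1L, genes$end, genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Construct a motif model
#'
#' @param motif_id Motif identifier.
#' @param prob_matrix 4 x width probability matrix, rows A, C, G, T; every
#'   column must sum to 1.
#' @param background Length-4 background distribution over A, C, G, T.
#' @param gr_type GR type the motif belongs to.
#' @return An object of class \code{motif_model}.
#' @export
motif_model <- function(motif_id, prob_matrix, background = rep(0.25, 4), gr_type = motif_id) {
  prob_matrix <- as.matrix(prob_matrix)
  if (nrow(prob_matrix) != 4L || ncol(prob_matrix) < 1L) {
    stop_input("prob_matrix must be 4 x width with width >= 1")
  }
  if (any(prob_matrix < 0) || any(background < 0)) stop_input("negative probabilities in motif %s", motif_id)
  if (any(abs(colSums(prob_matrix) - 1) > 1e-3)) {
    stop_input("motif %s has a column not summing to 1", motif_id)
  }
  if (abs(sum(background) - 1) > 1e-6) stop_input("background must sum to 1")
  # renormalize residual rounding so invariants hold to 1e-6
  prob_matrix <- sweep(prob_matrix, 2, colSums(prob_matrix), "/")
  rownames(prob_matrix) <- DNA_BASES
  structure(list(motif_id = motif_id, gr_type = gr_type, width = ncol(prob_matrix),
                 prob_matrix = prob_matrix, background = background),
            class = "motif_model")
}

#' Consensus word of a motif
#'
#' Per-column argmax base; ties break towards the earlier base in A,C,G,T.
#'
#' @param motif A [motif_model()].
#' @return Character string of length \code{motif$width}.
#' @export
consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$prob_matrix, 2, which.max)], collapse = "")
}

#' Read motifs in MEME minimal format
#'
#' Parses \code{MOTIF <id> [<alt>]} blocks with their
#' \code{letter-probability matrix} sections. A missing
#' \code{Background letter frequencies} line yields the uniform background.
#' The second word on the MOTIF line (when present) is taken as the GR type.
#'
#' @param path Path to a MEME minimal format file.
#' @return List of [motif_model()] objects.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) stop_input("MEME file does not exist: %s", path)
  lines <- trimws(readLines(path))
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1L && bg_at < length(lines)) {
    toks <- strsplit(lines[bg_at + 1L], "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- suppressWarnings(as.numeric(toks[seq(2, 8, by = 2)]))
      lets <- toks[seq(1, 7, by = 2)]
      if (!anyNA(vals) && identical(lets, DNA_BASES)) background <- vals
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) stop_input("no MOTIF blocks in %s", path)
  out <- vector("list", length(motif_at))
  for (i in seq_along(motif_at)) {
    toks <- strsplit(lines[motif_at[i]], "\\s+")[[1]]
    motif_id <- toks[2]
    gr_type <- if (length(toks) >= 3L) toks[3] else motif_id
    block_end <- if (i < length(motif_at)) motif_at[i + 1L] - 1L else length(lines)
    hdr <- grep("^letter-probability matrix", lines[motif_at[i]:block_end]) + motif_at[i] - 1L
    if (length(hdr) != 1L) stop_input("motif %s lacks a letter-probability matrix", motif_id)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    if (is.na(w) || w < 1L) stop_input("motif %s has width 0 or missing w=", motif_id)
    rows <- lines[(hdr + 1L):(hdr + w)]
    vals <- lapply(strsplit(rows, "\\s+"), as.numeric)
    if (any(vapply(vals, length, 1L) != 4L) || anyNA(unlist(vals))) {
      stop_input("motif %s matrix rows malformed", motif_id)
    }
    m <- t(do.call(rbind, vals))  # 4 x width, rows A,C,G,T
    out[[i]] <- motif_model(motif_id, m, background = background, gr_type = gr_type)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of [motif_model()] objects (shared background assumed).
#' @param path Output path.
#' @export
write_meme_motifs <- function(motifs, path) {
  stopifnot(length(motifs) >= 1L)
  bg <- motifs[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]), "")
  for (m in motifs) {
    lines <- c(lines,
               sprintf("MOTIF %s %s", m$motif_id, m$gr_type),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width),
               apply(m$prob_matrix, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxonomy lineage table
#'
#' @param path TSV with columns genome_id, genus, family, order, class_rank,
#'   phylum, domain ("NA" allowed for unknown ranks).
#' @return Data.frame of lineages.
#' @export
read_lineages <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("genome_id", "genus", "family", "order", "class_rank", "phylum", "domain")
  if (!all(need %in% names(df))) {
    stop_input("lineage table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(!nzchar(df$genome_id)) || anyDuplicated(df$genome_id)) {
    stop_input("genome_id must be non-empty and unique in the lineage table")
  }
  df[need]
}

#' Write a taxonomy lineage table
#' @param lineages Data.frame as from [read_lineages()].
#' @param path Output path.
#' @export
write_lineages <- function(lineages, path) {
  utils::write.table(lineages, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein label table
#'
#' Labels follow the corpus convention: \code{gr:<type>}, \code{tf},
#' \code{other:<category>}, or \code{unknown}.
#'
#' @param path TSV with columns protein_id, label.
#' @return Data.frame with columns protein_id, label.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("protein_id", "label") %in% names(df))) {
    stop_input("label table must have columns protein_id, label")
  }
  df[c("protein_id", "label")]
}

#' Write a GR-GR network edge list
#'
#' Emits a TSV with header \code{source, target, support}, one row per edge,
#' deterministically sorted by (source, target).
#'
#' @param network A \code{gr_network} from [build_network()], or a data.frame
#'   with columns source, target, support.
#' @param path Output path.
#' @export
write_edges_tsv <- function(network, path) {
  edges <- if (inherits(network, "gr_network")) network$edges else network
  stopifnot(all(c("source", "target", "support") %in% names(edges)))
  edges <- edges[order(edges$source, edges$target, method = "radix"), , drop = FALSE]
  utils::write.table(edges[c("source", "target", "support")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GR-GR network edge list written by [write_edges_tsv()]
#' @param path Path to the edge TSV.
#' @return Data.frame with columns source, target, support.
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  stopifnot(identical(names(df), c("source", "target", "support")))
  df
}
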