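# Frozen protein-embedding backends. A backend maps an amino-acid sequence of
# length L to an L x dim matrix of per-residue features and is never updated
# by training. The deterministic k-mer stub below is the desk-scale stand-in
# for a large protein language model; a real pLM adapter can implement the
# same contract.

#' Create a deterministic k-mer stub embedding backend
#'
#' Each residue's vector is a fixed seeded random projection of the one-hot
#' encoded k-mer window centred at that residue (window positions falling off
#' the sequence are padded with a sentinel letter). The projection matrix is
#' drawn once per (k, dim, seed), so identical sequences always embed to
#' bitwise-identical matrices. With k = 1 the pooled embedding of a sequence
#' is a pure function of its residue composition; with k > 1 it is sensitive
#' to local order, giving the classifier positional signal to attend over.
#'
#' @param k Window length, 1..4.
#' @param dim Embedding dimension, >= 8.
#' @param seed Integer seed for the projection.
#' @return An \code{embedding_backend}: list with \code{name}, \code{dim},
#'   and \code{embed(sequence)}.
#' @export
kmer_stub_backend <- function(k = 3L, dim = 32L, seed = 1L) {
  k <- as.integer(k); dim <- as.integer(dim)
  if (dim <= 0L) stop_input("dim must be positive")
  if (dim < 8L) stop_input("dim must be >= 8")
  if (k < 1L || k > 4L) stop_input("k must be in 1..4")
  letters_ext <- c(AA_ALPHABET, "X", "*")  # "*" is the boundary sentinel
  n_letters <- length(letters_ext)
  # one row per (window offset, letter); residue vector = sum over the k
  # window slots of the matching rows => a linear projection of the
  # concatenated one-hot window.
  proj <- with_seed(seed, matrix(stats::rnorm(k * n_letters * dim, sd = 1 / sqrt(k)),
                                 nrow = k * n_letters, ncol = dim))
  embed <- function(sequence) {
    sequence <- toupper(sequence)
    L <- nchar(sequence)
    if (L < 1L) stop_input("cannot embed an empty sequence")
    chars <- strsplit(sequence, "")[[1]]
    idx <- match(chars, letters_ext)
    if (anyNA(idx)) {
      stop_input("sequence contains letters outside the amino-acid alphabet: %s",
                 paste(unique(chars[is.na(idx)]), collapse = ""))
    }
    half <- (k - 1L) %/% 2L
    out <- matrix(0, nrow = L, ncol = dim)
    # window slot o covers residue position i + (o - 1 - half)
    for (o in seq_len(k)) {
      pos <- seq_len(L) + (o - 1L) - half
      slot_idx <- rep.int(n_letters, L)           # sentinel "*"
      inside <- pos >= 1L & pos <= L
      slot_idx[inside] <- idx[pos[inside]]
      out <- out + proj[(o - 1L) * n_letters + slot_idx, , drop = FALSE]
    }
    out
  }
  structure(list(name = sprintf("kmer_stub(k=%d,dim=%d,seed=%d)", k, dim, seed),
                 dim = dim, k = k, embed = embed),
            class = "embedding_backend")
}

#' Mean-pool a residue embedding matrix
#'
#' @param embeddings L x dim numeric matrix (L >= 1).
#' @return Length-dim vector of column means.
#' @export
mean_pool <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 1L) stop_input("cannot pool an empty embedding matrix")
  colMeans(embeddings)
}

#' Embed a batch of sequences with a frozen backend
#'
#' @param backend An \code{embedding_backend}.
#' @param sequences Named character vector of sequences.
#' @return Named list of L x dim matrices.
#' @export
embed_sequences <- function(backend, sequences) {
  stopifnot(inherits(backend, "embedding_backend"))
  out <- lapply(sequences, backend$embed)
  names(out) <- names(sequences)
  out
}
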