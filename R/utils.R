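#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from (seed, tag) so each pipeline component
# draws from its own stream. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character DNA string (A/C/G/T/N).
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Encode a DNA string as integers A=1 C=2 G=3 T=4, N (or any other IUPAC
# ambiguity) = 5.
encode_dna <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], DNA_BASES)
  v[is.na(v)] <- 5L
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
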