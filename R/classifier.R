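# The GR classifier head: a transformer encoder over per-residue embeddings
# from a frozen backend, mean-pooled and squashed to a single GR probability.
# Forward and backward passes are written out analytically (plain matrix
# algebra), so the head trains on one CPU without any deep-learning runtime,
# and gradients can be verified against finite differences.

LN_EPS <- 1e-5

#' Configuration of the GR classifier head
#'
#' Defaults mirror the reference architecture: a 12-layer encoder with
#' 512-dimensional hidden states, 8 attention heads of channel dimension 64,
#' a position-wise feed-forward inner dimension of 512, and dropout 0.4.
#' Smaller heads (fewer layers, narrower model_dim) are used for desk-scale
#' training; \code{n_heads * head_dim} must always equal \code{model_dim}.
#'
#' @param input_dim Dimension of the backend embeddings.
#' @param model_dim Hidden dimension of the encoder.
#' @param n_layers Number of encoder layers.
#' @param n_heads Attention heads per layer.
#' @param head_dim Channel dimension per head.
#' @param ffn_dim Inner dimension of the feed-forward network.
#' @param dropout Dropout rate in [0, 1), active only in train mode.
#' @param max_len Maximum sequence length; longer inputs are truncated.
#' @return A \code{head_config} list.
#' @export
head_config <- function(input_dim, model_dim = 512L, n_layers = 12L, n_heads = 8L,
                        head_dim = model_dim %/% n_heads, ffn_dim = 512L,
                        dropout = 0.4, max_len = 1024L) {
  cfg <- list(input_dim = as.integer(input_dim), model_dim = as.integer(model_dim),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              head_dim = as.integer(head_dim), ffn_dim = as.integer(ffn_dim),
              dropout = dropout, max_len = as.integer(max_len))
  if (cfg$n_heads * cfg$head_dim != cfg$model_dim) {
    stop_input("n_heads (%d) x head_dim (%d) must equal model_dim (%d)",
               cfg$n_heads, cfg$head_dim, cfg$model_dim)
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop_input("dropout must be in [0, 1)")
  if (cfg$n_layers < 1L || cfg$input_dim < 1L) stop_input("invalid head config")
  structure(cfg, class = "head_config")
}

#' Initialize head parameters
#'
#' Seeded Gaussian initialization (sd 0.02) for projection weights, identity
#' initialization for layer norms, zero biases. The same (config, seed) pair
#' always yields identical parameters.
#'
#' @param config A [head_config()].
#' @param seed Integer seed.
#' @return A \code{head_params} object.
#' @export
init_head <- function(config, seed = 1L) {
  stopifnot(inherits(config, "head_config"))
  d <- config$model_dim
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  t <- with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(i) {
      list(Wq = rmat(d, d), bq = numeric(d), Wk = rmat(d, d), bk = numeric(d),
           Wv = rmat(d, d), bv = numeric(d), Wo = rmat(d, d), bo = numeric(d),
           ln1_g = rep(1, d), ln1_b = numeric(d),
           W1 = rmat(d, config$ffn_dim), b1 = numeric(config$ffn_dim),
           W2 = rmat(config$ffn_dim, d), b2 = numeric(d),
           ln2_g = rep(1, d), ln2_b = numeric(d))
    })
    list(W_in = rmat(config$input_dim, d), b_in = numeric(d),
         layers = layers, w_out = stats::rnorm(d, sd = 0.02), b_out = 0)
  })
  structure(list(config = config, t = t), class = "head_params")
}

# ---- tensor bookkeeping --------------------------------------------------

#' Flatten a nested list of parameter tensors into one numeric vector
#'
#' Used by the optimizer, gradient clipping, and finite-difference gradient
#' checks; [unflatten_params()] is its inverse given the original structure.
#'
#' @param x Numeric vector/matrix or nested list of them (e.g.
#'   \code{head_params$t} or a gradient structure).
#' @return Numeric vector of all entries in structure order.
#' @export
flatten_params <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  unlist(lapply(x, flatten_params), use.names = FALSE)
}

#' Rebuild a nested tensor structure from a flat vector
#'
#' @param vec Numeric vector, as produced by [flatten_params()].
#' @param template Structure (and dims) to rebuild into.
#' @return Nested list matching \code{template} with values from \code{vec}.
#' @export
unflatten_params <- function(vec, template) {
  pos <- 0L
  fill <- function(x) {
    if (is.numeric(x)) {
      n <- length(x)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(x)) dim(out) <- dim(x)
      return(out)
    }
    lapply(x, fill)
  }
  out <- fill(template)
  stopifnot(pos == length(vec))
  out
}

zero_like <- function(x) {
  if (is.numeric(x)) return(x * 0)
  lapply(x, zero_like)
}

# elementwise a + b over nested tensor lists
add_tensors <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  Map(add_tensors, a, b)
}

# ---- forward / backward --------------------------------------------------

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc / sd
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)), xhat = xhat, sd = sd)
}

layernorm_bwd <- function(dy, cache, g) {
  gdy <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(gdy)
  m2 <- rowMeans(gdy * cache$xhat)
  dx <- (gdy - m1 - cache$xhat * m2) / cache$sd
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

make_dropout_mask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  (stats::runif(n) >= rate) / (1 - rate)
}

apply_mask <- function(x, mask) {
  if (is.null(mask)) x else x * mask
}

# Full forward pass with caches for backprop. `emb` is an L x input_dim
# matrix. Dropout masks are drawn from the current RNG stream when
# train_mode is on and rate > 0.
head_forward <- function(params, emb, train_mode = FALSE) {
  cfg <- params$config
  t <- params$t
  emb <- as.matrix(emb)
  if (!all(is.finite(emb))) stop_input("non-finite values in embedding input")
  if (ncol(emb) != cfg$input_dim) {
    stop_input("embedding dim %d does not match head input_dim %d", ncol(emb), cfg$input_dim)
  }
  if (nrow(emb) > cfg$max_len) emb <- emb[seq_len(cfg$max_len), , drop = FALSE]
  L <- nrow(emb)
  drop <- if (train_mode && cfg$dropout > 0) cfg$dropout else 0
  inv_sqrt <- 1 / sqrt(cfg$head_dim)
  H <- emb %*% t$W_in + rep(t$b_in, each = L)
  caches <- vector("list", cfg$n_layers)
  for (li in seq_len(cfg$n_layers)) {
    ly <- t$layers[[li]]
    H_in <- H
    Q <- H %*% ly$Wq + rep(ly$bq, each = L)
    K <- H %*% ly$Wk + rep(ly$bk, each = L)
    V <- H %*% ly$Wv + rep(ly$bv, each = L)
    Ocat <- matrix(0, L, cfg$model_dim)
    Ps <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      idx <- ((h - 1L) * cfg$head_dim + 1L):(h * cfg$head_dim)
      S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) * inv_sqrt
      S <- S - apply(S, 1, max)
      P <- exp(S)
      P <- P / rowSums(P)
      Ps[[h]] <- P
      Ocat[, idx] <- P %*% V[, idx, drop = FALSE]
    }
    O <- Ocat %*% ly$Wo + rep(ly$bo, each = L)
    mask_attn <- make_dropout_mask(length(O), drop)
    O <- apply_mask(O, mask_attn)
    ln1 <- layernorm_fwd(H_in + O, ly$ln1_g, ly$ln1_b)
    H1 <- ln1$y
    Z1 <- H1 %*% ly$W1 + rep(ly$b1, each = L)
    F1 <- pmax(Z1, 0)
    F2 <- F1 %*% ly$W2 + rep(ly$b2, each = L)
    mask_ffn <- make_dropout_mask(length(F2), drop)
    F2 <- apply_mask(F2, mask_ffn)
    ln2 <- layernorm_fwd(H1 + F2, ly$ln2_g, ly$ln2_b)
    caches[[li]] <- list(H_in = H_in, Q = Q, K = K, V = V, Ps = Ps, Ocat = Ocat,
                         mask_attn = mask_attn, ln1 = ln1, H1 = H1, Z1 = Z1,
                         F1 = F1, mask_ffn = mask_ffn, ln2 = ln2)
    H <- ln2$y
  }
  pooled <- colMeans(H)
  logit <- sum(pooled * t$w_out) + t$b_out
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob, logit = logit, pooled = pooled,
       cache = list(emb = emb, caches = caches, H_final = H, L = L))
}

# Backward pass: gradient of (dlogit * logit) wrt every parameter tensor.
head_backward <- function(params, fwd, dlogit) {
  cfg <- params$config
  t <- params$t
  L <- fwd$cache$L
  inv_sqrt <- 1 / sqrt(cfg$head_dim)
  g <- zero_like(t)
  g$w_out <- fwd$pooled * dlogit
  g$b_out <- dlogit
  dH <- matrix(rep(t$w_out * dlogit / L, each = L), nrow = L)
  for (li in rev(seq_len(cfg$n_layers))) {
    ly <- t$layers[[li]]
    ca <- fwd$cache$caches[[li]]
    ln2b <- layernorm_bwd(dH, ca$ln2, ly$ln2_g)
    g$layers[[li]]$ln2_g <- ln2b$dg
    g$layers[[li]]$ln2_b <- ln2b$db
    dB <- ln2b$dx                       # grad of H1 + F2
    dF2 <- apply_mask(dB, ca$mask_ffn)
    g$layers[[li]]$W2 <- t(ca$F1) %*% dF2
    g$layers[[li]]$b2 <- colSums(dF2)
    dF1 <- dF2 %*% t(ly$W2)
    dZ1 <- dF1 * (ca$Z1 > 0)
    g$layers[[li]]$W1 <- t(ca$H1) %*% dZ1
    g$layers[[li]]$b1 <- colSums(dZ1)
    dH1 <- dB + dZ1 %*% t(ly$W1)
    ln1b <- layernorm_bwd(dH1, ca$ln1, ly$ln1_g)
    g$layers[[li]]$ln1_g <- ln1b$dg
    g$layers[[li]]$ln1_b <- ln1b$db
    dA <- ln1b$dx                       # grad of H_in + O
    dO <- apply_mask(dA, ca$mask_attn)
    g$layers[[li]]$Wo <- t(ca$Ocat) %*% dO
    g$layers[[li]]$bo <- colSums(dO)
    dOcat <- dO %*% t(ly$Wo)
    dQ <- matrix(0, L, cfg$model_dim)
    dK <- matrix(0, L, cfg$model_dim)
    dV <- matrix(0, L, cfg$model_dim)
    for (h in seq_len(cfg$n_heads)) {
      idx <- ((h - 1L) * cfg$head_dim + 1L):(h * cfg$head_dim)
      P <- ca$Ps[[h]]
      dOh <- dOcat[, idx, drop = FALSE]
      dP <- dOh %*% t(ca$V[, idx, drop = FALSE])
      dV[, idx] <- t(P) %*% dOh
      dS <- (dP - rowSums(dP * P)) * P
      dQ[, idx] <- (dS %*% ca$K[, idx, drop = FALSE]) * inv_sqrt
      dK[, idx] <- (t(dS) %*% ca$Q[, idx, drop = FALSE]) * inv_sqrt
    }
    g$layers[[li]]$Wq <- t(ca$H_in) %*% dQ
    g$layers[[li]]$bq <- colSums(dQ)
    g$layers[[li]]$Wk <- t(ca$H_in) %*% dK
    g$layers[[li]]$bk <- colSums(dK)
    g$layers[[li]]$Wv <- t(ca$H_in) %*% dV
    g$layers[[li]]$bv <- colSums(dV)
    dH <- dA + dQ %*% t(ly$Wq) + dK %*% t(ly$Wk) + dV %*% t(ly$Wv)
  }
  g$W_in <- t(fwd$cache$emb) %*% dH
  g$b_in <- colSums(dH)
  g
}

#' Score one residue-embedding matrix with the GR head
#'
#' Eval mode (the default) is a deterministic pure function of the parameters
#' and embeddings; dropout is applied only when \code{train_mode} is on,
#' drawn from the RNG stream seeded by \code{seed}.
#'
#' @param params A \code{head_params} from [init_head()] or [train_head()].
#' @param emb L x input_dim numeric matrix of residue embeddings.
#' @param train_mode Logical; enable dropout.
#' @param seed Seed for dropout masks (train mode only).
#' @return GR probability strictly in (0, 1).
#' @export
forward <- function(params, emb, train_mode = FALSE, seed = 1L) {
  stopifnot(inherits(params, "head_params"))
  if (train_mode && params$config$dropout > 0) {
    with_seed(seed, head_forward(params, emb, train_mode = TRUE)$prob)
  } else {
    head_forward(params, emb, train_mode = FALSE)$prob
  }
}

#' Score a batch of protein records
#'
#' Order-preserving map of [forward()] (eval mode) over records, embedding
#' each sequence with the frozen backend.
#'
#' @param params A \code{head_params}.
#' @param backend An \code{embedding_backend}.
#' @param records Data.frame with columns \code{protein_id}, \code{sequence}.
#' @return Data.frame with columns protein_id, score.
#' @export
score_batch <- function(params, backend, records) {
  stopifnot(nrow(records) >= 1L)
  empty <- !nzchar(records$sequence)
  if (any(empty)) {
    stop_input("empty sequence for record(s): %s",
               paste(records$protein_id[empty], collapse = ", "))
  }
  scores <- vapply(records$sequence, function(s) {
    head_forward(params, backend$embed(s), train_mode = FALSE)$prob
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(protein_id = records$protein_id, score = scores, stringsAsFactors = FALSE)
}

#' Weighted cross-entropy loss and analytic parameter gradients
#'
#' Mean weighted binary cross-entropy over a list of residue-embedding
#' matrices, with gradients for every head parameter computed by
#' backpropagation. Scores are clamped to [1e-7, 1 - 1e-7] inside the loss.
#' This is the gradient engine behind [train_head()] and the reference for
#' finite-difference verification.
#'
#' @param params A \code{head_params}.
#' @param embs List of L x input_dim embedding matrices.
#' @param labels 0/1 labels, one per matrix.
#' @param weights Positive sample weights.
#' @param train_mode Enable dropout (masks drawn from the current RNG).
#' @return List with \code{loss} (scalar) and \code{grads} (same structure
#'   as \code{params$t}).
#' @export
batch_loss_grads <- function(params, embs, labels, weights, train_mode = FALSE) {
  eps <- 1e-7
  wsum <- sum(weights)
  grads <- zero_like(params$t)
  loss <- 0
  for (i in seq_along(embs)) {
    fwd <- head_forward(params, embs[[i]], train_mode = train_mode)
    s <- min(max(fwd$prob, eps), 1 - eps)
    loss <- loss - weights[i] * (labels[i] * log(s) + (1 - labels[i]) * log(1 - s))
    dlogit <- weights[i] * (fwd$prob - labels[i]) / wsum
    grads <- add_tensors(grads, head_backward(params, fwd, dlogit))
  }
  list(loss = loss / wsum, grads = grads)
}

#' Save a head checkpoint
#'
#' Writes a versioned archive holding the head config, parameters, and the
#' backend identity, readable by [load_checkpoint()].
#'
#' @param params A \code{head_params}.
#' @param backend_name Name of the frozen backend the head was trained on.
#' @param path Output path.
#' @export
save_checkpoint <- function(params, backend_name, path) {
  stopifnot(inherits(params, "head_params"))
  saveRDS(list(format_version = 1L, backend_name = backend_name,
               config = params$config, tensors = params$t), path)
  invisible(path)
}

#' Load a head checkpoint written by [save_checkpoint()]
#' @param path Checkpoint path.
#' @return List with \code{params} (a \code{head_params}) and \code{backend_name}.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format_version, 1L)) stop_input("unsupported checkpoint version")
  list(params = structure(list(config = ck$config, t = ck$tensors), class = "head_params"),
       backend_name = ck$backend_name)
}
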