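# Training protocol for the GR head: type-aware dataset splitting with
# held-out GR types, per-epoch negative subsampling, fivefold weighting of
# transcription-factor hard negatives, linear learning-rate warm-up, global
# gradient clipping, and an adaptive-gradient optimizer with decoupled
# weight decay. The embedding backend stays frozen throughout.

#' Training configuration
#'
#' Defaults are the reference protocol: learning rate 1e-6 with a linear
#' warm-up over the first 1,000 batches, gradient clipping at global norm
#' 100, weight decay 0.1, and a fivefold sample weight on TF-labelled hard
#' negatives. Desk-scale runs typically raise \code{lr} and shorten
#' \code{warmup_batches}; see the methods vignette.
#'
#' @param lr Peak learning rate.
#' @param warmup_batches Batches over which the rate ramps linearly from 0.
#' @param clip_norm Maximum global L2 gradient norm.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param tf_weight Sample weight for TF hard negatives (>= 1).
#' @param neg_per_pos Negatives subsampled per positive each epoch.
#' @param batch_size Sequences per optimizer step.
#' @param epochs Training epochs.
#' @param threshold Decision threshold for calls.
#' @param seed Master seed for subsampling, shuffling, and dropout.
#' @return A \code{train_config} list.
#' @export
train_config <- function(lr = 1e-6, warmup_batches = 1000L, clip_norm = 100,
                         weight_decay = 0.1, tf_weight = 5, neg_per_pos = 1,
                         batch_size = 16L, epochs = 10L, threshold = 0.5, seed = 1L) {
  if (lr <= 0 || warmup_batches < 0 || clip_norm <= 0 || weight_decay < 0 ||
      neg_per_pos <= 0 || batch_size < 1L || epochs < 0L) {
    stop_input("train_config rates and sizes must be positive")
  }
  if (tf_weight < 1) stop_input("tf_weight must be >= 1")
  structure(list(lr = lr, warmup_batches = as.integer(warmup_batches),
                 clip_norm = clip_norm, weight_decay = weight_decay,
                 tf_weight = tf_weight, neg_per_pos = neg_per_pos,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 threshold = threshold, seed = as.integer(seed)),
            class = "train_config")
}

label_kind <- function(label) {
  ifelse(startsWith(label, "gr:"), "gr",
         ifelse(label == "tf", "tf",
                ifelse(startsWith(label, "other:"), "other", "unknown")))
}

gr_type_of <- function(label) ifelse(startsWith(label, "gr:"), sub("^gr:", "", label), NA_character_)

# deterministic n_val/n_test share for an 80/10/10 split of n items
tenth <- function(n) as.integer(round(n / 10))

#' Partition a labelled protein corpus into train/validation/test sets
#'
#' GR types named in \code{holdout_types} are excluded from training
#' entirely: their sequences are split 50/50 between validation and test
#' (odd counts put the extra sequence in validation). Every other GR type is
#' split 80/10/10 within type. Negative records (TF and each \code{other:}
#' category) are stratified within category and split 8:1:1. The split is
#' deterministic given \code{seed}.
#'
#' @param records Data.frame with columns \code{protein_id}, \code{label}
#'   (convention \code{gr:<type>}, \code{tf}, \code{other:<category>}).
#' @param holdout_types Character vector of GR types reserved for
#'   generalization testing; each must have >= 10 sequences.
#' @param seed Integer seed.
#' @return A \code{dataset_split}: list with \code{train_ids},
#'   \code{val_ids}, \code{test_ids}, \code{held_out_types}.
#' @export
make_split <- function(records, holdout_types = character(), seed = 1L) {
  stopifnot(all(c("protein_id", "label") %in% names(records)))
  kind <- label_kind(records$label)
  if (any(kind == "unknown")) {
    stop_input("unknown label(s): %s",
               paste(utils::head(unique(records$label[kind == "unknown"]), 3), collapse = ", "))
  }
  types <- gr_type_of(records$label)
  missing_holdout <- setdiff(holdout_types, stats::na.omit(unique(types)))
  if (length(missing_holdout)) {
    stop_input("holdout type(s) absent from corpus: %s", paste(missing_holdout, collapse = ", "))
  }
  train <- character(); val <- character(); test <- character()
  with_seed(seed, {
    for (ty in sort(unique(stats::na.omit(types)))) {
      ids <- sample(records$protein_id[!is.na(types) & types == ty])
      n <- length(ids)
      if (ty %in% holdout_types) {
        if (n < 10L) stop_input("holdout type '%s' has %d sequences (< 10)", ty, n)
        n_val <- ceiling(n / 2)                 # odd counts: extra to validation
        val <- c(val, ids[seq_len(n_val)])
        test <- c(test, ids[(n_val + 1L):n])
      } else {
        n_val <- tenth(n); n_test <- tenth(n)
        val <- c(val, ids[seq_len(n_val)])
        test <- c(test, ids[n_val + seq_len(n_test)])
        train <- c(train, ids[(n_val + n_test + 1L):n])
      }
    }
    for (cat in sort(unique(records$label[kind %in% c("tf", "other")]))) {
      ids <- sample(records$protein_id[records$label == cat])
      n <- length(ids)
      n_val <- tenth(n); n_test <- tenth(n)
      val <- c(val, ids[seq_len(n_val)])
      test <- c(test, ids[n_val + seq_len(n_test)])
      if (n > n_val + n_test) train <- c(train, ids[(n_val + n_test + 1L):n])
    }
  })
  structure(list(train_ids = train, val_ids = val, test_ids = test,
                 held_out_types = holdout_types), class = "dataset_split")
}

#' Learning rate at a given optimizer step
#'
#' Linear ramp from 0 at step 0 to \code{config$lr} at
#' \code{config$warmup_batches}, constant afterwards.
#'
#' @param step Non-negative optimizer step (batch counter).
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_at <- function(step, config) {
  if (any(step < 0)) stop_input("step must be >= 0")
  if (config$warmup_batches == 0L) return(rep(config$lr, length(step)))
  ifelse(step >= config$warmup_batches, config$lr, config$lr * step / config$warmup_batches)
}

#' Weighted binary cross-entropy
#'
#' \eqn{-\sum_i w_i (y_i \log s_i + (1-y_i)\log(1-s_i)) / \sum_i w_i}.
#' Scores are clamped to [1e-7, 1 - 1e-7] for numeric safety.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @param weights Positive sample weights (1 for positives and generic
#'   negatives, \code{tf_weight} for TF hard negatives).
#' @return Scalar loss.
#' @export
weighted_loss <- function(scores, labels, weights = rep(1, length(scores))) {
  stopifnot(length(scores) == length(labels), length(scores) == length(weights),
            all(weights > 0))
  eps <- 1e-7
  s <- pmin(pmax(scores, eps), 1 - eps)
  -sum(weights * (labels * log(s) + (1 - labels) * log(1 - s))) / sum(weights)
}

#' Subsample negative ids for one epoch
#'
#' Draws \code{n} ids without replacement; the draw depends on both
#' \code{seed} and \code{epoch}, so successive epochs see different negative
#' subsets while any (seed, epoch) pair is reproducible.
#'
#' @param pool Character vector of candidate ids.
#' @param n Number to draw (<= length(pool)).
#' @param epoch Epoch number.
#' @param seed Master seed.
#' @return Character vector of drawn ids.
#' @export
subsample_negatives <- function(pool, n, epoch, seed = 1L) {
  if (n > length(pool)) stop_input("cannot subsample %d from a pool of %d", n, length(pool))
  with_seed(derive_seed(seed, paste0("negsub", epoch)), sample(pool, n))
}

#' Clip gradients to a maximum global L2 norm
#'
#' @param grads Numeric vector, matrix, or nested list of gradient tensors.
#' @param max_norm Maximum global norm.
#' @return Gradients, rescaled by \code{max_norm / norm} when the global
#'   norm exceeds \code{max_norm}; unchanged otherwise.
#' @export
clip_gradients <- function(grads, max_norm = 100) {
  flat <- flatten_params(grads)
  if (!all(is.finite(flat))) stop_input("non-finite gradient entries")
  g <- sqrt(sum(flat^2))
  if (g <= max_norm || g == 0) return(grads)
  scale_nested <- function(x, s) if (is.numeric(x)) x * s else lapply(x, scale_nested, s = s)
  scale_nested(grads, max_norm / g)
}

# AdamW step on flat vectors. Returns updated (theta, m, v).
adamw_step <- function(theta, grad, m, v, step, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  mhat <- m / (1 - beta1^step)
  vhat <- v / (1 - beta2^step)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, m = m, v = v)
}

#' Train the GR head on a labelled corpus
#'
#' Each epoch rebuilds the batch pool from all positive training sequences
#' plus a freshly subsampled set of negatives
#' (\code{round(neg_per_pos * n_pos)} of them), optimizes the weighted
#' cross-entropy with AdamW (decoupled weight decay), the [lr_at()] warm-up
#' schedule, and [clip_gradients()]. TF-labelled negatives carry
#' \code{tf_weight}. The backend is frozen: it is only ever called to embed,
#' never updated. The best parameters by validation AUC are returned.
#'
#' @param records Data.frame with columns protein_id, sequence, label.
#' @param backend Frozen \code{embedding_backend}.
#' @param config A [train_config()].
#' @param split A [make_split()] result.
#' @param hconfig A [head_config()]; defaults to the reference architecture
#'   over the backend dimension.
#' @param verbose Emit one message per epoch.
#' @return List with \code{params} (best by val AUC), \code{history}
#'   (data.frame: epoch, n_pos, n_neg, train_loss, val_loss, val_auc), and
#'   \code{final_params}.
#' @export
train_head <- function(records, backend, config, split,
                       hconfig = head_config(input_dim = backend$dim),
                       verbose = FALSE) {
  stopifnot(inherits(config, "train_config"), inherits(split, "dataset_split"))
  rec <- records[match(unique(records$protein_id), records$protein_id), , drop = FALSE]
  rownames(rec) <- rec$protein_id
  kind <- label_kind(rec$label)
  names(kind) <- rec$protein_id
  is_pos <- kind == "gr"
  train_pos <- intersect(split$train_ids, rec$protein_id[is_pos])
  train_neg <- intersect(split$train_ids, rec$protein_id[!is_pos])
  if (length(train_pos) == 0L) stop_input("empty positive training set")
  if (length(split$val_ids) == 0L) stop_input("empty validation set")
  # embed everything once: the backend is frozen
  ids_all <- unique(c(split$train_ids, split$val_ids))
  embs <- lapply(rec[ids_all, "sequence"], function(s) {
    m <- backend$embed(s)
    if (nrow(m) > hconfig$max_len) m <- m[seq_len(hconfig$max_len), , drop = FALSE]
    m
  })
  names(embs) <- ids_all
  val_lab <- as.numeric(kind[split$val_ids] == "gr")

  params <- init_head(hconfig, seed = config$seed)
  nflat <- length(flatten_params(params$t))
  m <- numeric(nflat); v <- numeric(nflat)
  gstep <- 0L
  best <- list(auc = -Inf, params = params)
  hist <- data.frame()
  val_scores <- function(p) {
    vapply(split$val_ids, function(id) head_forward(p, embs[[id]])$prob, numeric(1))
  }
  for (epoch in seq_len(config$epochs)) {
    n_draw <- min(length(train_neg), round(config$neg_per_pos * length(train_pos)))
    negs <- subsample_negatives(train_neg, n_draw, epoch, config$seed)
    pool <- c(train_pos, negs)
    pool <- with_seed(derive_seed(config$seed, paste0("shuffle", epoch)), sample(pool))
    labels <- as.numeric(kind[pool] == "gr")
    weights <- ifelse(kind[pool] == "tf", config$tf_weight, 1)
    batch_starts <- seq(1L, length(pool), by = config$batch_size)
    ep_loss <- 0; ep_w <- 0
    for (b in batch_starts) {
      bi <- b:min(b + config$batch_size - 1L, length(pool))
      gstep <- gstep + 1L
      lg <- with_seed(derive_seed(config$seed, paste0("drop", gstep)),
                      batch_loss_grads(params, embs[pool[bi]], labels[bi], weights[bi],
                                       train_mode = hconfig$dropout > 0))
      grads <- clip_gradients(lg$grads, config$clip_norm)
      upd <- adamw_step(flatten_params(params$t), flatten_params(grads), m, v,
                        step = gstep, lr = lr_at(gstep, config),
                        weight_decay = config$weight_decay)
      params$t <- unflatten_params(upd$theta, params$t)
      m <- upd$m; v <- upd$v
      ep_loss <- ep_loss + lg$loss * sum(weights[bi])
      ep_w <- ep_w + sum(weights[bi])
    }
    vs <- val_scores(params)
    vloss <- weighted_loss(vs, val_lab)
    vauc <- if (length(unique(val_lab)) == 2L) roc_auc(vs, val_lab) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, n_pos = length(train_pos),
                                   n_neg = n_draw, train_loss = ep_loss / ep_w,
                                   val_loss = vloss, val_auc = vauc))
    if (verbose) {
      message(sprintf("epoch %d: n_pos=%d n_neg=%d loss=%.4f val_auc=%s",
                      epoch, length(train_pos), n_draw, ep_loss / ep_w,
                      ifelse(is.na(vauc), "NA", sprintf("%.3f", vauc))))
    }
    if (!is.na(vauc) && vauc > best$auc) best <- list(auc = vauc, params = params)
  }
  if (is.infinite(best$auc)) best$params <- params
  list(params = best$params, history = hist, final_params = params)
}
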