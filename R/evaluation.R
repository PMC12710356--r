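# ROC/AUC and confusion-matrix metrics with the evaluation stratifications
# used for GR classification: negative class (all negatives vs TF hard
# negatives only), seen vs held-out GR types, and per-taxon groupings.
# Metrics with a zero denominator are reported as NA ("undefined"), never as
# a silent 0: at desk scale strata can be legitimately empty.

#' Rank-based ROC AUC
#'
#' Computed from the Wilcoxon rank statistic; equals
#' \eqn{P(s_{pos} > s_{neg}) + \frac{1}{2} P(s_{pos} = s_{neg})} over all
#' positive-negative pairs (midranks handle ties).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop_input("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold-based confusion metrics
#'
#' Calls a positive when \code{score >= threshold} and reports precision,
#' sensitivity, specificity, accuracy and F1 alongside the raw counts.
#' Metrics with a zero denominator are \code{NA}.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold in (0, 1).
#' @return A \code{metric_report} list: TP, FP, TN, FN, precision,
#'   sensitivity, specificity, accuracy, f1.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) == 0L) stop_input("empty input")
  if (threshold <= 0 || threshold >= 1) stop_input("threshold must be in (0,1)")
  call <- scores >= threshold
  TP <- sum(call & labels == 1L); FP <- sum(call & labels == 0L)
  FN <- sum(!call & labels == 1L); TN <- sum(!call & labels == 0L)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- div(TP, TP + FP)
  sens <- div(TP, TP + FN)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else {
    2 * prec * sens / (prec + sens)
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 precision = prec, sensitivity = sens,
                 specificity = div(TN, TN + FP),
                 accuracy = div(TP + TN, length(scores)), f1 = f1),
            class = "metric_report")
}

rank_column <- function(rank) {
  cols <- c(genus = "genus", family = "family", order = "order",
            class = "class_rank", phylum = "phylum", domain = "domain")
  if (!rank %in% names(cols)) {
    stop_input("unknown rank '%s' (use one of: %s)", rank, paste(names(cols), collapse = ", "))
  }
  cols[[rank]]
}

#' Per-taxon AUC at a taxonomic rank
#'
#' Both classes are restricted to the taxon (genomes of that taxon only);
#' taxa missing either class are excluded and counted in the
#' \code{skipped_taxa} attribute, as are proteins with no lineage
#' (\code{skipped_proteins}).
#'
#' @param scores Named numeric vector (names are protein ids) or data.frame
#'   with columns protein_id, score.
#' @param labels Data.frame with columns protein_id, label, genome_id.
#' @param lineages Lineage table ([read_lineages()]).
#' @param rank One of genus, family, order, class, phylum, domain.
#' @return Data.frame (taxon, n_pos, n_neg, auc) with skip counts as
#'   attributes.
#' @export
auc_by_taxon <- function(scores, labels, lineages, rank = "phylum") {
  col <- rank_column(rank)
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$protein_id)
  df <- labels
  df$score <- scores[df$protein_id]
  df$taxon <- lineages[[col]][match(df$genome_id, lineages$genome_id)]
  skipped_proteins <- sum(is.na(df$taxon) | is.na(df$score))
  df <- df[!is.na(df$taxon) & !is.na(df$score), , drop = FALSE]
  df$y <- as.integer(label_kind(df$label) == "gr")
  out <- data.frame(); skipped_taxa <- character()
  for (tx in sort(unique(df$taxon))) {
    sub <- df[df$taxon == tx, , drop = FALSE]
    n_pos <- sum(sub$y == 1L); n_neg <- sum(sub$y == 0L)
    if (n_pos == 0L || n_neg == 0L) {
      skipped_taxa <- c(skipped_taxa, tx)
      next
    }
    out <- rbind(out, data.frame(taxon = tx, n_pos = n_pos, n_neg = n_neg,
                                 auc = roc_auc(sub$score, sub$y)))
  }
  attr(out, "skipped_taxa") <- skipped_taxa
  attr(out, "skipped_proteins") <- skipped_proteins
  out
}

#' Stratified metric report over seen/held-out types and negative classes
#'
#' Builds the six evaluation strata {all, seen, held-out GR types} x
#' {all negatives, TF negatives only}, and computes [confusion_metrics()]
#' plus [roc_auc()] on each. A stratum missing a class gets \code{NA}
#' metrics with \code{defined = FALSE}.
#'
#' @param scores Named numeric vector or data.frame (protein_id, score).
#' @param labels Data.frame with columns protein_id, label.
#' @param holdout_types Character vector of held-out GR type names.
#' @param threshold Decision threshold.
#' @return Named list of six strata (\code{all_all}, \code{all_tf},
#'   \code{seen_all}, \code{seen_tf}, \code{heldout_all}, \code{heldout_tf});
#'   each has counts, metrics, auc, defined.
#' @export
stratified_report <- function(scores, labels, holdout_types, threshold = 0.5) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$protein_id)
  kind <- label_kind(labels$label)
  type <- gr_type_of(labels$label)
  pos_sets <- list(all = labels$protein_id[kind == "gr"],
                   seen = labels$protein_id[kind == "gr" & !(type %in% holdout_types)],
                   heldout = labels$protein_id[kind == "gr" & type %in% holdout_types])
  neg_sets <- list(all = labels$protein_id[kind %in% c("tf", "other")],
                   tf = labels$protein_id[kind == "tf"])
  out <- list()
  for (p in names(pos_sets)) {
    for (n in names(neg_sets)) {
      ids <- c(pos_sets[[p]], neg_sets[[n]])
      y <- c(rep(1L, length(pos_sets[[p]])), rep(0L, length(neg_sets[[n]])))
      s <- scores[ids]
      keep <- !is.na(s)
      s <- s[keep]; y <- y[keep]
      nm <- paste(p, n, sep = "_")
      if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
        out[[nm]] <- list(defined = FALSE, n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                          metrics = NULL, auc = NA_real_)
      } else {
        out[[nm]] <- list(defined = TRUE, n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                          metrics = confusion_metrics(s, y, threshold),
                          auc = roc_auc(s, y))
      }
    }
  }
  out
}
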