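#' Sample negative miRNA-mRNA pairs
#'
#' Draws `n` distinct pairs uniformly without replacement from all
#' miRNA x mRNA combinations not present in `positives`. This balanced
#' negative set lets a classifier learn to separate validated interactions
#' from random pairings.
#'
#' @param positives data.frame with `mirna`, `mrna` (the known edges).
#' @param mirna_ids,mrna_ids the id universes to pair over; default = the ids
#'   appearing in `positives`.
#' @param n number of negatives (default `nrow(positives)`, balanced).
#' @param seed integer seed.
#' @return data.frame `mirna`, `mrna`, `label = 0`.
#' @export
sample_negatives <- function(positives, mirna_ids = NULL, mrna_ids = NULL,
                             n = nrow(positives), seed = 1L) {
  stopifnot(is.data.frame(positives))
  if (is.null(mirna_ids)) mirna_ids <- sort(unique(positives$mirna))
  if (is.null(mrna_ids)) mrna_ids <- sort(unique(positives$mrna))
  n_cells <- length(mirna_ids) * length(mrna_ids)
  pos_cells <- (match(positives$mrna, mrna_ids) - 1L) * length(mirna_ids) +
    match(positives$mirna, mirna_ids)
  pos_cells <- unique(pos_cells[!is.na(pos_cells)])
  avail <- n_cells - length(pos_cells)
  if (n > avail)
    stop("requested ", n, " negatives but only ", avail,
         " non-positive combinations exist", call. = FALSE)
  neg_cells <- with_seed(seed, {
    free <- setdiff(seq_len(n_cells), pos_cells)
    sample(free, n)
  })
  data.frame(
    mirna = mirna_ids[(neg_cells - 1L) %% length(mirna_ids) + 1L],
    mrna = mrna_ids[(neg_cells - 1L) %/% length(mirna_ids) + 1L],
    label = 0L, stringsAsFactors = FALSE)
}

#' Stratified k-fold split of a labeled pair set
#'
#' Test folds are disjoint, exhaustive, and per-class balanced (sizes differ
#' by at most one within each class).
#'
#' @param dataset data.frame with a `label` column of 0/1.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the within-class shuffles.
#' @return list of `folds` elements, each `list(train =, test =)` integer row
#'   indices into `dataset`.
#' @export
kfold_split <- function(dataset, folds = 5L, seed = 1L) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset), folds >= 2L)
  lab <- dataset$label
  if (min(table(lab)) < folds)
    stop("a class has fewer members than folds", call. = FALSE)
  assign_fold <- integer(nrow(dataset))
  with_seed(seed, {
    for (cl in unique(lab)) {
      idx <- sample(which(lab == cl))
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  lapply(seq_len(folds), function(f)
    list(train = which(assign_fold != f), test = which(assign_fold == f)))
}

#' Confusion counts at a threshold
#'
#' Scores at or above the threshold are called positive (a score of exactly
#' 0.5 is a positive call under the default).
#'
#' @param scores numeric in `[0,1]`.
#' @param labels 0/1 vector of the same length.
#' @param threshold decision threshold (default 0.5).
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (!length(scores) || length(scores) != length(labels))
    stop("scores/labels empty or of unequal length", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1L & labels == 1L),
       TN = sum(pred == 0L & labels == 0L),
       FP = sum(pred == 1L & labels == 0L),
       FN = sum(pred == 0L & labels == 1L))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Thresholded classification metrics from confusion counts
#'
#' ACC, F1, MCC, SEN (recall), PPV (precision) and TNR (specificity). Any
#' metric whose denominator is zero is reported as 0 and listed in the
#' `degenerate` attribute instead of propagating NaN.
#'
#' @param cm output of [confusion()].
#' @return named numeric vector with attribute `degenerate` (character vector
#'   of zero-denominator metrics, possibly empty).
#' @export
compute_metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion", call. = FALSE)
  degenerate <- character(0)
  flag <- function(name, den) {
    if (den == 0) degenerate <<- c(degenerate, name)
  }
  flag("SEN", TP + FN); flag("PPV", TP + FP); flag("TNR", TN + FP)
  sen <- safe_div(TP, TP + FN)
  ppv <- safe_div(TP, TP + FP)
  tnr <- safe_div(TN, TN + FP)
  flag("F1", ppv + sen)
  f1 <- safe_div(2 * ppv * sen, ppv + sen)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  flag("MCC", mcc_den)
  mcc <- safe_div(TP * TN - FP * FN, mcc_den)
  out <- c(ACC = (TP + TN) / total, F1 = f1, MCC = mcc,
           SEN = sen, PPV = ppv, TNR = tnr)
  attr(out, "degenerate") <- degenerate
  out
}

#' Ranking metrics: AUC and AUPR
#'
#' AUC is the rank-based (Mann-Whitney) probability that a random positive
#' outscores a random negative, with ties credited one half. AUPR is the area
#' under the precision-recall step curve in the average-precision convention,
#' with tied scores grouped so the curve does not depend on input order.
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector.
#' @return named numeric vector `c(AUC =, AUPR =)`.
#' @export
auc_aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0 || N == 0)
    stop("both classes must be present for AUC/AUPR", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)

  # AP over descending unique score groups: sum over groups of
  # (recall gain) * (precision at the group's cumulative cut)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  rec_gain <- tp_g / P
  aupr <- sum(prec * rec_gain)
  c(AUC = auc, AUPR = unname(aupr))
}

#' Assemble a per-fold metric report
#'
#' One row per fold plus `average` and `Std` rows (sample standard deviation).
#'
#' @param fold_metrics list of named numeric vectors (one per fold), each with
#'   ACC, F1, AUC, AUPR, MCC, SEN, PPV, TNR.
#' @return data.frame with a `fold` column.
#' @export
metric_report <- function(fold_metrics) {
  m <- do.call(rbind, fold_metrics)
  avg <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  out <- data.frame(fold = c(seq_len(nrow(m)), "average", "Std"),
                    rbind(m, avg, sdv), check.names = FALSE,
                    row.names = NULL)
  out
}
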