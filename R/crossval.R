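metric_order <- c("ACC", "F1", "AUC", "AUPR", "MCC", "SEN", "PPV", "TNR")

fold_metric_vector <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(scores, labels, threshold)
  thr <- compute_metrics(cm)
  rk <- auc_aupr(scores, labels)
  c(ACC = unname(thr["ACC"]), F1 = unname(thr["F1"]),
    AUC = unname(rk["AUC"]), AUPR = unname(rk["AUPR"]),
    MCC = unname(thr["MCC"]), SEN = unname(thr["SEN"]),
    PPV = unname(thr["PPV"]), TNR = unname(thr["TNR"]))
}

#' ROC curve points for exported plotting
#'
#' FPR/TPR at every distinct score threshold (descending), anchored at (0,0)
#' and (1,1).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE) | seq_along(s) == length(s)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / sum(y == 0)),
             tpr = c(0, tp / sum(y == 1)))
}

#' Stratified cross-validation of the full pipeline
#'
#' For each fold the interaction graph is rebuilt from the training fold's
#' positive edges only, so test edges never leak into the GraRep node
#' features (set `full_graph = TRUE` to embed the complete positive graph
#' instead); the model is trained on the training fold and scored on the held
#' out fold. Pretrained k-mer embeddings are shared across folds: they are
#' learned from sequences alone, never from labels.
#'
#' @param pairs labeled pair data.frame (`mirna`, `mrna`, `label`), both
#'   classes present.
#' @param records list of `seq_record` covering all ids.
#' @param model_cfg a [model_config()].
#' @param embedding a `kmer_embedding`, or `NULL` to pretrain one on the
#'   record corpus with `pretrain_cfg`.
#' @param pretrain_cfg a [skipgram_config()] used when `embedding` is `NULL`.
#' @param grarep_cfg a [grarep_config()].
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold split (model training uses
#'   `model_cfg$seed`, offset per fold).
#' @param full_graph embed the full positive graph instead of the leak-free
#'   per-fold graph.
#' @param val_fraction passed to [train_model()].
#' @param threshold decision threshold for the thresholded metrics.
#' @param verbose print per-fold progress.
#' @return A `cv_result`: list with `report` (per-fold metrics plus average
#'   and Std rows), `scores` (per-pair out-of-fold scores with fold ids),
#'   `roc` (list of per-fold ROC point data.frames), `folds`, `seed`.
#' @export
cross_validate <- function(pairs, records, model_cfg = model_config(),
                           embedding = NULL,
                           pretrain_cfg = skipgram_config(),
                           grarep_cfg = grarep_config(), folds = 5L,
                           seed = 1L, full_graph = FALSE,
                           val_fraction = 0.1, threshold = 0.5,
                           verbose = FALSE) {
  stopifnot(is.data.frame(pairs), "label" %in% names(pairs))
  if (is.null(embedding)) {
    corpus <- build_corpus(records, k = model_cfg$k,
                           frag = list(min_len = 200L, max_len = 400L,
                                       overlap = 100L,
                                       seed = pretrain_cfg$seed))
    embedding <- train_embeddings(corpus, pretrain_cfg,
                                  build_vocabulary(model_cfg$k))
  }
  splits <- kfold_split(pairs, folds = folds, seed = seed)
  fold_metrics <- list()
  roc <- list()
  all_scores <- list()
  for (f in seq_along(splits)) {
    tr <- pairs[splits[[f]]$train, , drop = FALSE]
    te <- pairs[splits[[f]]$test, , drop = FALSE]
    graph_edges <- if (full_graph) pairs[pairs$label == 1L, , drop = FALSE]
                   else tr[tr$label == 1L, , drop = FALSE]
    graph <- build_graph(graph_edges)
    emb_nodes <- grarep_embed(graph, grarep_cfg)
    cfg_f <- model_cfg
    cfg_f$seed <- model_cfg$seed + f
    ds_tr <- build_dataset(tr, records, emb_nodes, cfg_f)
    fit <- train_model(ds_tr, cfg_f, embedding = embedding,
                       val_fraction = val_fraction, verbose = verbose)
    ds_te <- build_dataset(te, records, emb_nodes, cfg_f)
    pred <- predict_pairs(fit, ds_te)
    fold_metrics[[f]] <- fold_metric_vector(pred$score, te$label, threshold)
    roc[[f]] <- roc_points(pred$score, te$label)
    pred$fold <- f
    all_scores[[f]] <- pred
    if (verbose)
      message(sprintf("fold %d: AUC %.4f ACC %.4f", f,
                      fold_metrics[[f]]["AUC"], fold_metrics[[f]]["ACC"]))
  }
  structure(list(report = metric_report(fold_metrics),
                 scores = do.call(rbind, all_scores),
                 roc = roc, folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$folds))
  print(x$report, digits = 4)
  invisible(x)
}

#' Write per-fold ROC points as CSV files
#'
#' One file per fold (`roc_fold<k>.csv`) under `dir`.
#' @param cv a `cv_result`.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
write_roc_csv <- function(cv, dir) {
  stopifnot(inherits(cv, "cv_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (f in seq_along(cv$roc)) {
    p <- file.path(dir, sprintf("roc_fold%d.csv", f))
    utils::write.csv(cv$roc[[f]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write cross-validation scores as TSV
#' @param cv a `cv_result`.
#' @param path output path (columns: mirna, mrna, label, score, fold).
#' @export
write_scores_tsv <- function(cv, path) {
  utils::write.table(
    cv$scores[, c("mirna", "mrna", "label", "score", "fold")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary row of a cross-validation report
#' @param cv a `cv_result`.
#' @param row `"average"` or `"Std"`.
#' @return named numeric vector of the eight metrics.
#' @export
cv_summary <- function(cv, row = "average") {
  r <- cv$report[cv$report$fold == row, metric_order]
  stats::setNames(as.numeric(r[1, ]), metric_order)
}
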