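ABLATIONS <- c(full = 0L, noatt = 1L, lstm = 2L, nolstm = 3L)
FUSIONS <- c(concat_bp = 0L, add = 1L, average = 2L, dnn = 3L, no_bp = 4L)

#' Model configuration for the sequence-pair encoder
#'
#' All architecture and training hyperparameters in one place. Token
#' capacities are in k-mer tokens: sequences are padded (with a masked pad
#' index) or truncated to the capacity; for mRNA the first `mrna_len` tokens
#' of the reversed sequence are kept, i.e. the 3' end of the original, where
#' miRNA binding sites concentrate.
#'
#' @param k k-mer length (must match the pretrained vocabulary).
#' @param embed_dim embedding dimension (rows of the pretrained table).
#' @param mirna_len,mrna_len token capacities (defaults 25 / 400).
#' @param cnn_filters,cnn_kernel,pool 1-D convolution width, odd kernel size,
#'   and non-overlapping max-pool size.
#' @param lstm_hidden hidden units per LSTM direction (BiLSTM output width is
#'   `2 * lstm_hidden`).
#' @param heads attention heads; the per-head dimension is the encoder output
#'   width divided by `heads`.
#' @param attention_mode `"mi_queries_m"` (miRNA supplies queries, mRNA keys
#'   and values; the mRNA sequence vector is then the pooled BiLSTM output)
#'   or `"bidirectional"` (a second, role-swapped attention pass produces
#'   the mRNA vector too).
#' @param mrna_summary how the mRNA encoder output is pooled into its
#'   sequence vector when no role-swapped attention pass exists: `"max"`
#'   (column-wise max over valid positions, the default: presence of a
#'   binding-site-like feature anywhere in a long transcript survives
#'   pooling) or `"mean"`.
#' @param ablation `"full"`, `"noatt"` (drop attention), `"lstm"`
#'   (unidirectional LSTM), or `"nolstm"` (CNN features straight into
#'   attention).
#' @param fusion `"concat_bp"` (concatenate the four feature vectors, one
#'   nonlinear hidden layer, sigmoid), `"add"`, `"average"`, `"dnn"` (three
#'   hidden layers), or `"no_bp"` (linear + sigmoid, no hidden nonlinearity).
#' @param fusion_hidden width of the fusion hidden layer (the `dnn` variant
#'   scales its three layers from this value).
#' @param node_dim GraRep node feature dimension.
#' @param dropout dropout rate on the fused feature vector during training.
#' @param augment_crop training-time augmentation: each epoch every mRNA is
#'   encoded from a random window covering at least this fraction of its
#'   tokens (1 disables). Random cropping destabilizes transcript-identity
#'   features across epochs while local binding-site content survives, which
#'   suppresses pair memorization on small training sets.
#' @param node_dropout probability of hiding the pair's node feature vectors
#'   during training. Node embeddings are transductive: every training-fold
#'   positive is an edge of the embedded graph, so undropped node features
#'   can shortcut the training labels without generalizing to held-out
#'   (non-edge) pairs; stochastic hiding forces the sequence encoder to
#'   carry the decision as well.
#' @param lr Adam learning rate.
#' @param epochs,batch training epochs and minibatch size.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(k = 6L, embed_dim = 64L, mirna_len = 25L,
                         mrna_len = 400L, cnn_filters = 64L, cnn_kernel = 5L,
                         pool = 2L, lstm_hidden = 32L, heads = 4L,
                         attention_mode = c("mi_queries_m", "bidirectional"),
                         mrna_summary = c("max", "mean"),
                         ablation = c("full", "noatt", "lstm", "nolstm"),
                         fusion = c("concat_bp", "add", "average", "dnn",
                                    "no_bp"),
                         fusion_hidden = 64L,
                         node_dim = 64L, dropout = 0.3, node_dropout = 0.5,
                         augment_crop = 0.5, lr = 1e-3, epochs = 30L,
                         batch = 64L, seed = 1L) {
  attention_mode <- match.arg(attention_mode)
  mrna_summary <- match.arg(mrna_summary)
  ablation <- match.arg(ablation)
  fusion <- match.arg(fusion)
  stopifnot(mirna_len >= k, mrna_len >= k, cnn_kernel %% 2 == 1,
            pool >= 1, lstm_hidden >= 1, heads >= 1,
            dropout >= 0, dropout < 1, node_dropout >= 0, node_dropout < 1,
            augment_crop > 0, augment_crop <= 1)
  d <- switch(ablation, nolstm = cnn_filters, lstm = lstm_hidden,
              2L * lstm_hidden)
  if (ablation != "noatt" && d %% heads != 0)
    stop("encoder width ", d, " not divisible by heads = ", heads,
         call. = FALSE)
  if (fusion %in% c("add", "average") && d != node_dim)
    stop("add/average fusion needs sequence width (", d,
         ") == node_dim (", node_dim, ")", call. = FALSE)
  structure(list(
    k = as.integer(k), vocab_size = 4L^as.integer(k),
    embed_dim = as.integer(embed_dim),
    mirna_len = as.integer(mirna_len), mrna_len = as.integer(mrna_len),
    cnn_filters = as.integer(cnn_filters),
    cnn_kernel = as.integer(cnn_kernel), pool = as.integer(pool),
    lstm_hidden = as.integer(lstm_hidden), heads = as.integer(heads),
    attention_mode = attention_mode, mrna_summary = mrna_summary,
    ablation = ablation, fusion = fusion,
    fusion_hidden = as.integer(fusion_hidden),
    ablation_code = ABLATIONS[[ablation]], fusion_code = FUSIONS[[fusion]],
    att_bidirectional = attention_mode == "bidirectional",
    node_dim = as.integer(node_dim), dropout = dropout,
    node_dropout = node_dropout, augment_crop = augment_crop, lr = lr,
    epochs = as.integer(epochs), batch = as.integer(batch),
    seed = as.integer(seed)), class = "model_config")
}

seq_width <- function(cfg) {
  switch(cfg$ablation, nolstm = cfg$cnn_filters, lstm = cfg$lstm_hidden,
         2L * cfg$lstm_hidden)
}

fusion_dims <- function(cfg) {
  d <- seq_width(cfg)
  h <- cfg$fusion_hidden
  zin <- if (cfg$fusion %in% c("add", "average")) d else 2L * d + 2L * cfg$node_dim
  switch(cfg$fusion,
         concat_bp = c(zin, h, 1L),
         add = c(zin, h, 1L),
         average = c(zin, h, 1L),
         dnn = c(zin, 2L * h, h, h %/% 2L, 1L),
         no_bp = c(zin, 1L))
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' The embedding table starts from the pretrained k-mer matrix (and is
#' fine-tuned during training); all other weights use seeded Glorot-uniform
#' initialization, LSTM forget-gate biases start at 1.
#'
#' @param cfg a [model_config()].
#' @param embedding pretrained `kmer_embedding` (see [train_embeddings()]) or
#'   a bare `4^k x embed_dim` matrix; `NULL` for random initialization.
#' @return named list of parameter matrices.
#' @export
init_model <- function(cfg, embedding = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  De <- cfg$embed_dim; F_ <- cfg$cnn_filters; H <- cfg$lstm_hidden
  d <- seq_width(cfg)
  with_seed(cfg$seed, {
    p <- list()
    if (is.null(embedding)) {
      p$emb <- matrix(stats::rnorm(cfg$vocab_size * De, sd = 0.05),
                      cfg$vocab_size, De)
    } else {
      W <- if (inherits(embedding, "kmer_embedding")) embedding$weights
           else embedding
      stopifnot(nrow(W) == cfg$vocab_size, ncol(W) == De)
      p$emb <- unname(as.matrix(W))
    }
    lstm_init <- function() {
      W <- glorot(F_ + H, 4L * H)
      b <- matrix(0, 1, 4L * H)
      b[1, (H + 1):(2L * H)] <- 1  # forget-gate bias
      list(W = W, b = b)
    }
    for (side in c("mi", "m")) {
      p[[paste0("conv_", side, "_W")]] <- glorot(cfg$cnn_kernel * De, F_)
      p[[paste0("conv_", side, "_b")]] <- matrix(0, 1, F_)
      if (cfg$ablation != "nolstm") {
        fw <- lstm_init()
        p[[paste0("lstm_", side, "_fw_W")]] <- fw$W
        p[[paste0("lstm_", side, "_fw_b")]] <- fw$b
        if (cfg$ablation != "lstm") {
          bw <- lstm_init()
          p[[paste0("lstm_", side, "_bw_W")]] <- bw$W
          p[[paste0("lstm_", side, "_bw_b")]] <- bw$b
        }
      }
    }
    if (cfg$ablation != "noatt") {
      for (nm in c("att_Wq", "att_Wk", "att_Wv")) p[[nm]] <- glorot(d, d)
      if (cfg$att_bidirectional)
        for (nm in c("att2_Wq", "att2_Wk", "att2_Wv")) p[[nm]] <- glorot(d, d)
    }
    dims <- fusion_dims(cfg)
    for (l in seq_len(length(dims) - 1L)) {
      p[[paste0("fus_W", l)]] <- glorot(dims[l], dims[l + 1L])
      p[[paste0("fus_b", l)]] <- matrix(0, 1, dims[l + 1L])
    }
    p
  })
}

# Pack sequences into a 0-based token index matrix (-1 = pad) plus lengths.
# mRNA records are reversed first, then truncated to the token capacity.
pack_side <- function(records, ids, cfg, side) {
  cap <- if (side == "miRNA") cfg$mirna_len else cfg$mrna_len
  vocab <- build_vocabulary(cfg$k)
  by_id <- stats::setNames(records, vapply(records, function(r) r$id, ""))
  uids <- unique(ids)
  X <- matrix(-1L, length(uids), cap)
  len <- integer(length(uids))
  for (i in seq_along(uids)) {
    rec <- by_id[[uids[i]]]
    if (is.null(rec)) stop("no sequence for id '", uids[i], "'",
                           call. = FALSE)
    if (rec$role != side)
      stop("id '", uids[i], "' has role ", rec$role, ", expected ", side,
           call. = FALSE)
    if (side == "mRNA") rec <- reverse_orientation(rec)
    tok <- kmer_index(vocab, tokenize_kmers(rec$residues, cfg$k))
    n <- min(length(tok), cap)
    X[i, seq_len(n)] <- tok[seq_len(n)]
    len[i] <- n
  }
  rownames(X) <- uids
  list(X = X, len = len)
}

#' Assemble a model dataset from pairs, sequences, and node embeddings
#'
#' Tokenizes each unique sequence once (mRNAs reversed before tokenization so
#' the encoder sees the antisense orientation), looks up node features with a
#' zero-vector fallback for nodes outside the embedded graph, and packs
#' everything into the index matrices the training core consumes.
#'
#' @param pairs data.frame with `mirna`, `mrna`, and (for training) `label`.
#' @param records list of `seq_record` covering every id in `pairs`.
#' @param node_emb a `node_embedding` from [grarep_embed()].
#' @param cfg a [model_config()].
#' @return A `model_dataset` list.
#' @export
build_dataset <- function(pairs, records, node_emb, cfg) {
  stopifnot(is.data.frame(pairs), inherits(cfg, "model_config"))
  mi <- pack_side(records, pairs$mirna, cfg, "miRNA")
  m <- pack_side(records, pairs$mrna, cfg, "mRNA")
  Nmi <- node_features(node_emb, pairs$mirna)
  Nm <- node_features(node_emb, pairs$mrna)
  stopifnot(ncol(Nmi) == cfg$node_dim)
  # sequences stored once; pairs reference them through 0-based index maps
  structure(list(
    pairs = pairs,
    Xmi = mi$X, lmi = mi$len,
    Xm = m$X, lm = m$len,
    imi = match(pairs$mirna, rownames(mi$X)) - 1L,
    im = match(pairs$mrna, rownames(m$X)) - 1L,
    Nmi = Nmi, Nm = Nm,
    y = if ("label" %in% names(pairs)) as.numeric(pairs$label) else NULL,
    cfg = cfg), class = "model_dataset")
}

#' Train the interaction model
#'
#' Minimizes binary cross-entropy with Adam over seeded minibatches. A
#' stratified validation split (`val_fraction`) is held out to select the
#' best-epoch parameters; with `val_fraction = 0` the final-epoch parameters
#' are returned.
#'
#' @param dataset a `model_dataset` with labels.
#' @param cfg a [model_config()]; defaults to the dataset's.
#' @param embedding pretrained embedding passed to [init_model()].
#' @param val_fraction fraction of the training pairs held out per class for
#'   epoch selection (default 0.1).
#' @param verbose print per-epoch losses.
#' @return A `model_fit`: list with `params`, `cfg`, `history` (per-epoch
#'   train/validation loss), `best_epoch`.
#' @export
train_model <- function(dataset, cfg = dataset$cfg, embedding = NULL,
                        val_fraction = 0.1, verbose = FALSE) {
  stopifnot(inherits(dataset, "model_dataset"))
  y <- dataset$y
  if (is.null(y)) stop("dataset has no labels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training needs both classes present", call. = FALSE)
  n <- length(y)
  val <- integer(0)
  if (val_fraction > 0) {
    val <- with_seed(cfg$seed + 1L, {
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(length(idx) * val_fraction)))
      }))
    })
  }
  train <- setdiff(seq_len(n), val)
  params <- init_model(cfg, embedding)
  out <- cpp_nn_train(params, unclass(cfg), dataset$Xmi, dataset$Xm,
                      dataset$lmi, dataset$lm, dataset$imi, dataset$im,
                      dataset$Nmi, dataset$Nm,
                      y, train - 1L, val - 1L, cfg$seed, verbose)
  history <- data.frame(epoch = seq_len(cfg$epochs),
                        train_loss = out$history[, 1],
                        val_loss = out$history[, 2])
  structure(list(params = out$params, cfg = cfg, history = history,
                 best_epoch = out$best_epoch),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("interaction model (%s encoder, %s fusion), %d epochs, best %d\n",
              x$cfg$ablation, x$cfg$fusion, x$cfg$epochs, x$best_epoch))
  invisible(x)
}

#' Score miRNA-mRNA pairs with a trained model
#'
#' @param fit a `model_fit`.
#' @param dataset a `model_dataset` built with the same config.
#' @return data.frame: the dataset pairs plus `score` in `[0,1]` and
#'   `label_at_0.5`.
#' @export
predict_pairs <- function(fit, dataset) {
  stopifnot(inherits(fit, "model_fit"), inherits(dataset, "model_dataset"))
  s <- cpp_nn_forward(fit$params, unclass(fit$cfg), dataset$Xmi, dataset$Xm,
                      dataset$lmi, dataset$lm, dataset$imi, dataset$im,
                      dataset$Nmi, dataset$Nm,
                      seq_len(nrow(dataset$pairs)) - 1L)
  out <- dataset$pairs
  out$score <- as.numeric(s)
  out$label_at_0.5 <- as.integer(out$score >= 0.5)
  out
}

#' Encode one sequence through embedding, CNN and BiLSTM
#'
#' Exposes the per-side encoder: embedding lookup of the padded token ids,
#' 1-D convolution with ReLU and max-pooling, then the (Bi)LSTM. Output has
#' `floor(capacity/pool)` rows; only the first `n_valid` correspond to real
#' sequence positions.
#'
#' @param tokens integer vector of 0-based vocabulary indices.
#' @param side `"miRNA"` or `"mRNA"` (selects capacity and encoder weights).
#' @param params parameter list from [init_model()] or a `model_fit`.
#' @param cfg a [model_config()].
#' @return matrix `T' x width` with attribute `n_valid`.
#' @export
encode_sequence <- function(tokens, side = c("miRNA", "mRNA"), params, cfg) {
  side <- match.arg(side)
  if (inherits(params, "model_fit")) params <- params$params
  tokens <- as.integer(tokens)
  if (any(tokens < 0L | tokens >= cfg$vocab_size))
    stop("token index out of vocabulary range", call. = FALSE)
  cap <- if (side == "miRNA") cfg$mirna_len else cfg$mrna_len
  X <- matrix(-1L, 1L, cap)
  n <- min(length(tokens), cap)
  X[1, seq_len(n)] <- tokens[seq_len(n)]
  out <- cpp_nn_encode(params, unclass(cfg), X, n, side == "miRNA")
  H <- out$H[[1]]
  attr(H, "n_valid") <- out$n_valid[1]
  H
}

#' Multi-head mutual attention between two encoded sequences
#'
#' The query-side matrix attends over the key/value side: per head,
#' `Q = H_q W_Q`, `K = H_kv W_K`, `V = H_kv W_V`, scores `Q K' / sqrt(d_k)`
#' are row-softmaxed into weights that are applied to `V`; head outputs are
#' concatenated.
#'
#' @param H_mi query-side matrix (`T_mi x d`).
#' @param H_m key/value-side matrix (`T_m x d`).
#' @param params parameter list holding `att_Wq`, `att_Wk`, `att_Wv`.
#' @param cfg a [model_config()] (supplies `heads`).
#' @param n_valid_m number of valid `H_m` rows (default all).
#' @return matrix `T_mi x d` with attribute `alpha`, the list of per-head
#'   attention weight matrices (each row sums to 1).
#' @export
mutual_attention <- function(H_mi, H_m, params, cfg,
                             n_valid_m = nrow(H_m)) {
  if (inherits(params, "model_fit")) params <- params$params
  out <- cpp_attention(H_mi, H_m, params$att_Wq, params$att_Wk,
                       params$att_Wv, cfg$heads, n_valid_m)
  H <- out$O
  attr(H, "alpha") <- out$alpha
  H
}

#' Masked mean pooling over the time dimension
#'
#' Averages the first `n_valid` rows; an all-masked input yields a zero
#' vector.
#'
#' @param H feature matrix (time in rows).
#' @param n_valid rows to include (default all).
#' @return numeric vector of `ncol(H)`.
#' @export
pool_features <- function(H, n_valid = nrow(H)) {
  if (n_valid <= 0) return(numeric(ncol(H)))
  colMeans(H[seq_len(n_valid), , drop = FALSE])
}

#' Fuse sequence and node feature vectors into an interaction score
#'
#' Runs the configured fusion head: `concat_bp` concatenates the four vectors
#' and applies one nonlinear hidden layer before the sigmoid; `add`/`average`
#' combine element-wise first; `dnn` uses three hidden layers; `no_bp` is a
#' single linear layer + sigmoid.
#'
#' @param seq_mi,seq_m pooled sequence feature vectors.
#' @param node_mi,node_m GraRep node feature vectors.
#' @param params parameter list with the fusion layers.
#' @param cfg a [model_config()].
#' @return scalar score in `[0,1]`.
#' @export
fuse_and_classify <- function(seq_mi, seq_m, node_mi, node_m, params, cfg) {
  if (inherits(params, "model_fit")) params <- params$params
  if (cfg$fusion %in% c("add", "average")) {
    lens <- c(length(seq_mi), length(seq_m), length(node_mi), length(node_m))
    if (length(unique(lens)) != 1L)
      stop("add/average fusion needs equal-length vectors", call. = FALSE)
    z <- seq_mi + seq_m + node_mi + node_m
    if (cfg$fusion == "average") z <- z / 4
  } else {
    z <- c(seq_mi, seq_m, node_mi, node_m)
  }
  as.numeric(cpp_fusion(params, unclass(cfg), matrix(z, 1L)))
}

#' Save / load a model checkpoint as portable text
#'
#' The checkpoint is a JSON file holding the config and every parameter
#' matrix (format version 1); loading validates shapes by rebuilding the
#' config.
#'
#' @param fit a `model_fit`.
#' @param path file path.
#' @return `save_model`: the path, invisibly. `load_model`: a `model_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  obj <- list(format = 1L,
              cfg = unclass(fit$cfg)[setdiff(names(fit$cfg),
                c("vocab_size", "ablation_code", "fusion_code",
                  "att_bidirectional"))],
              best_epoch = fit$best_epoch,
              params = lapply(fit$params, function(m)
                list(dim = dim(m), x = as.numeric(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != 1L)
    stop("unrecognized checkpoint format", call. = FALSE)
  cfg <- do.call(model_config, obj$cfg)
  params <- lapply(obj$params, function(p) matrix(p$x, p$dim[1], p$dim[2]))
  structure(list(params = params, cfg = cfg, history = NULL,
                 best_epoch = obj$best_epoch),
            class = "model_fit")
}
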