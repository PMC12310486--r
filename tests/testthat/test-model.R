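make_tiny_data <- function(n_pairs = 6, seed = 1) {
  set.seed(seed)
  cfg <- tiny_model_cfg()
  recs <- random_records(3, 4, len_mi = 6, len_m = 9, seed = seed)
  pairs <- data.frame(
    mirna = paste0("mi", sample(3, n_pairs, TRUE)),
    mrna = paste0("g", sample(4, n_pairs, TRUE)),
    label = rep_len(c(1L, 0L), n_pairs))
  pairs <- pairs[!duplicated(pairs[1:2]), ]
  g <- build_graph(pairs[pairs$label == 1, ])
  ne <- grarep_embed(g, grarep_config(K = 2, d = 2))
  ds <- suppressWarnings(build_dataset(pairs, recs, ne, cfg))
  list(cfg = cfg, ds = ds, recs = recs, pairs = pairs)
}

test_that("config validation catches inconsistent dimensions", {
  expect_error(model_config(heads = 3, lstm_hidden = 32), "divisible")
  expect_error(model_config(cnn_kernel = 4), "cnn_kernel")
  expect_error(model_config(fusion = "add", node_dim = 32,
                            lstm_hidden = 32), "node_dim")
  cfg <- model_config(ablation = "lstm", lstm_hidden = 32, heads = 4)
  expect_equal(mirtarnet:::seq_width(cfg), 32L)
})

test_that("encoder output has floor(capacity/pool) rows and is deterministic", {
  cfg <- tiny_model_cfg()
  p <- init_model(cfg)
  tokens <- c(3L, 7L, 1L, 0L, 9L)
  H <- encode_sequence(tokens, "mRNA", p, cfg)
  expect_equal(dim(H), c(4L, 4L))  # 8/2 rows, 2*lstm_hidden cols
  expect_equal(attr(H, "n_valid"), 2L)  # floor(5/2)
  H2 <- encode_sequence(tokens, "mRNA", p, cfg)
  expect_identical(H, H2)
  Hmi <- encode_sequence(tokens, "miRNA", p, cfg)
  expect_equal(dim(Hmi), c(3L, 4L))  # miRNA capacity 6
  expect_error(encode_sequence(c(1L, 99L), "miRNA", p, cfg), "vocabulary")

  # without the recurrent layer the encoder is the pooled CNN map
  cfg_nl <- tiny_model_cfg(ablation = "nolstm")
  p_nl <- init_model(cfg_nl)
  Hnl <- encode_sequence(tokens, "mRNA", p_nl, cfg_nl)
  expect_equal(ncol(Hnl), cfg_nl$cnn_filters)
})

test_that("attention weights are row-stochastic and reproduce hand cases", {
  cfg <- tiny_model_cfg()
  p <- init_model(cfg)
  set.seed(3)
  for (i in 1:100) {
    Hmi <- matrix(rnorm(3 * 4), 3)
    Hm <- matrix(rnorm(5 * 4), 5)
    O <- mutual_attention(Hmi, Hm, p, cfg)
    for (al in attr(O, "alpha"))
      expect_true(all(abs(rowSums(al) - 1) < 1e-6))
    expect_equal(dim(O), c(3L, 4L))
  }

  # single head, identity projections, zero query, identical value rows
  cfg1 <- tiny_model_cfg(heads = 1L)
  pid <- list(att_Wq = diag(4), att_Wk = diag(4), att_Wv = diag(4))
  v <- c(1, 2, 3, 4)
  O <- mutual_attention(matrix(0, 1, 4), rbind(v, v), pid, cfg1)
  expect_equal(attr(O, "alpha")[[1]], matrix(0.5, 1, 2),
               ignore_attr = TRUE)
  expect_equal(as.numeric(O), v)
})

test_that("pre-softmax scores carry the 1 / sqrt(d_k) factor", {
  # same Q.K' dot products embedded at d_k = 1 and d_k = 4 (zero padding):
  # the log-odds between two keys must halve when d_k quadruples
  q <- 0.8; k1 <- 1.2; k2 <- -0.4
  cfg1 <- tiny_model_cfg(heads = 1L, lstm_hidden = 1L, cnn_filters = 2L)
  O1 <- mutual_attention(matrix(q, 1, 1) * diag(1),
                         matrix(c(k1, k2), 2, 1),
                         list(att_Wq = diag(1), att_Wk = diag(1),
                              att_Wv = diag(1)), cfg1)
  a1 <- attr(O1, "alpha")[[1]]
  cfg4 <- tiny_model_cfg(heads = 1L)
  pad <- function(x) cbind(x, 0, 0, 0)
  O4 <- mutual_attention(pad(matrix(q, 1, 1)), pad(matrix(c(k1, k2), 2, 1)),
                         list(att_Wq = diag(4), att_Wk = diag(4),
                              att_Wv = diag(4)), cfg4)
  a4 <- attr(O4, "alpha")[[1]]
  lo1 <- log(a1[1, 1] / a1[1, 2])   # = q(k1 - k2) / sqrt(1)
  lo4 <- log(a4[1, 1] / a4[1, 2])   # = q(k1 - k2) / sqrt(4)
  expect_equal(lo1, q * (k1 - k2), tolerance = 1e-9)
  expect_equal(lo4, lo1 / 2, tolerance = 1e-9)
})

test_that("temporal pooling averages valid rows only", {
  H <- matrix(c(1, 3, 3, 1), 2, byrow = TRUE)
  expect_equal(pool_features(H), c(2, 2))
  expect_equal(pool_features(H[1, , drop = FALSE]), c(1, 3))
  expect_equal(pool_features(H, n_valid = 1), c(1, 3))
  expect_equal(pool_features(H, n_valid = 0), c(0, 0))
})

test_that("fusion heads score in [0,1] with the documented structure", {
  cfg <- tiny_model_cfg()
  p <- init_model(cfg)
  d <- 4
  s <- fuse_and_classify(rnorm(d), rnorm(d), rnorm(d), rnorm(d), p, cfg)
  expect_true(s >= 0 && s <= 1)
  # concat fusion input width = 2 * seq width + 2 * node width
  expect_equal(nrow(p$fus_W1), 2L * 4L + 2L * cfg$node_dim)
  # no_bp is a single linear layer straight to the sigmoid
  cfg_nb <- tiny_model_cfg(fusion = "no_bp")
  p_nb <- init_model(cfg_nb)
  expect_equal(ncol(p_nb$fus_W1), 1L)
  expect_false("fus_W2" %in% names(p_nb))
  # concat_bp has exactly one nonlinear hidden layer before the sigmoid
  expect_equal(ncol(p$fus_W2), 1L)
  expect_false("fus_W3" %in% names(p))
  # dnn carries three hidden layers
  p_dnn <- init_model(tiny_model_cfg(fusion = "dnn"))
  expect_true(all(c("fus_W1", "fus_W2", "fus_W3", "fus_W4") %in%
                  names(p_dnn)))
  # add/average require matching dimensions
  cfg_add <- tiny_model_cfg(fusion = "add")
  p_add <- init_model(cfg_add)
  expect_error(fuse_and_classify(rnorm(4), rnorm(4), rnorm(3), rnorm(4),
                                 p_add, cfg_add), "equal-length")
})

test_that("training overfits a small separable dataset and is deterministic", {
  spec <- synthetic_spec(n_mirna = 8, n_mrna = 15, n_pos = 25,
                         noise_rate = 0, seed = 5)
  fx <- generate_fixture(spec)
  cfg <- model_config(mrna_len = 200, pool = 2, epochs = 30, batch = 16,
                      dropout = 0, lr = 5e-3, seed = 3)
  ne <- grarep_embed(build_graph(fx$pairs[fx$pairs$label == 1, ]))
  ds <- suppressWarnings(build_dataset(fx$pairs, fx$records, ne, cfg))
  fit <- train_model(ds, cfg, embedding = NULL, val_fraction = 0)
  pred <- predict_pairs(fit, ds)
  expect_gte(mean(pred$label_at_0.5 == fx$pairs$label), 0.98)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(nrow(fit$history), 30L)
  expect_true(all(diff(fit$history$train_loss[c(1, 30)]) < 0))

  fit2 <- train_model(ds, cfg, embedding = NULL, val_fraction = 0)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("training rejects degenerate datasets", {
  td <- make_tiny_data()
  ds1 <- td$ds
  ds1$y <- rep(1, length(ds1$y))
  expect_error(train_model(ds1, td$cfg), "both classes")
  ds2 <- td$ds
  ds2$y <- NULL
  expect_error(train_model(ds2, td$cfg), "labels")
})

test_that("checkpoints round-trip through JSON with identical scores", {
  td <- make_tiny_data()
  fit <- train_model(td$ds, td$cfg, val_fraction = 0)
  tmp <- tempfile(fileext = ".json")
  save_model(fit, tmp)
  back <- load_model(tmp)
  expect_equal(predict_pairs(back, td$ds)$score,
               predict_pairs(fit, td$ds)$score, tolerance = 1e-7)
  expect_equal(back$cfg$ablation, fit$cfg$ablation)
})

test_that("dataset packing reverses and truncates mRNA to the 3' end", {
  cfg <- tiny_model_cfg()
  rec <- list(normalize_sequence("g1", "AACCGGUUA", "mRNA"))
  pk <- mirtarnet:::pack_side(rec, "g1", cfg, "mRNA")
  rev_toks <- tokenize_kmers(reverse_orientation(rec[[1]])$residues, 2)
  v <- build_vocabulary(2)
  expect_equal(pk$X[1, 1:8], kmer_index(v, rev_toks)[1:8])
  expect_equal(pk$len, 8L)  # 8 of 8 token capacity
})
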