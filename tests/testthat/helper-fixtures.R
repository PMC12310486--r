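# Small shared fixtures, built in code at test time.

tiny_model_cfg <- function(...) {
  # miniature but structurally complete network for fast tests
  args <- list(k = 2L, embed_dim = 4L, mirna_len = 6L, mrna_len = 8L,
               cnn_filters = 4L, cnn_kernel = 3L, pool = 2L,
               lstm_hidden = 2L, heads = 2L, node_dim = 4L, dropout = 0,
               lr = 1e-3, epochs = 2L, batch = 4L, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

random_records <- function(n_mi = 3, n_m = 4, len_mi = 10, len_m = 30,
                           seed = 1) {
  set.seed(seed)
  c(lapply(seq_len(n_mi), function(i)
      normalize_sequence(paste0("mi", i),
                         paste(sample(c("A", "C", "G", "U"), len_mi, TRUE),
                               collapse = ""), "miRNA")),
    lapply(seq_len(n_m), function(i)
      normalize_sequence(paste0("g", i),
                         paste(sample(c("A", "C", "G", "U"), len_m, TRUE),
                               collapse = ""), "mRNA")))
}

# Dense brute-force re-implementation of the GraRep recipe, kept deliberately
# naive and independent of the package internals.
brute_grarep <- function(S, K, d, beta, eps) {
  deg <- rowSums(S)
  A <- S
  for (i in seq_len(nrow(S)))
    A[i, ] <- if (deg[i] > 0) S[i, ] / deg[i] else 0
  blocks <- list()
  for (k in seq_len(K)) {
    Ak <- diag(nrow(A))
    for (s in seq_len(k)) Ak <- Ak %*% A
    X <- matrix(0, nrow(A), ncol(A))
    for (i in seq_len(nrow(A)))
      for (j in seq_len(ncol(A))) {
        gam <- sum(Ak[, j])
        pr <- if (gam > 0) Ak[i, j] / gam else 0
        X[i, j] <- max(0, log(pr + eps) - log(beta))
      }
    sv <- svd(X)
    U <- sv$u[, seq_len(d), drop = FALSE]
    for (j in seq_len(d)) {
      m <- which.max(abs(U[, j]))
      if (U[m, j] < 0) U[, j] <- -U[, j]
    }
    blocks[[k]] <- U %*% diag(sqrt(sv$d[seq_len(d)]), d, d)
  }
  do.call(cbind, blocks)
}
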