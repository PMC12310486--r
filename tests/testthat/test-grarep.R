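test_that("graph construction is symmetric, deduplicated, and role-checked", {
  g <- build_graph(data.frame(mirna = "mi1", mrna = "g1"))
  expect_equal(unname(g$S), matrix(c(0, 1, 1, 0), 2))
  g2 <- build_graph(data.frame(mirna = c("mi1", "mi1"), mrna = c("g1", "g2")))
  expect_equal(sum(g2$S["mi1", ]), 2)
  dup <- build_graph(data.frame(mirna = c("mi1", "mi1"), mrna = c("g1", "g1")))
  expect_equal(dup$S, g$S)
  # same id on both sides is rejected
  expect_error(build_graph(data.frame(mirna = c("a", "x"), mrna = c("x", "b"))),
               "both")
  # node order: sorted miRNAs then sorted mRNAs
  g3 <- build_graph(data.frame(mirna = c("mi2", "mi1"), mrna = c("gB", "gA")))
  expect_equal(g3$nodes$id, c("mi1", "mi2", "gA", "gB"))
})

test_that("transition matrix divides rows by degree", {
  g <- build_graph(data.frame(mirna = c("mi1", "mi2"), mrna = c("g1", "g1")))
  A <- transition_matrix(g)
  # path mi1 - g1 - mi2: g1 has degree 2
  expect_equal(A["mi1", "g1"], 1)
  expect_equal(unname(A["g1", c("mi1", "mi2")]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(A) - 1) < 1e-12))
  single <- transition_matrix(build_graph(data.frame(mirna = "m", mrna = "g")))
  expect_equal(unname(single), matrix(c(0, 1, 1, 0), 2))
})

test_that("log-shifted k-step matrix matches the hand-worked case and clips", {
  g <- build_graph(data.frame(mirna = "mi1", mrna = "g1"))
  A <- transition_matrix(g)
  cfg <- grarep_config(K = 2, d = 1, beta = 0.5, eps = 1e-12)
  X1 <- kstep_log_matrix(A, 1, cfg)
  expect_equal(unname(X1), matrix(c(0, log(2), log(2), 0), 2),
               tolerance = 1e-9)
  expect_true(all(X1 >= 0))
  # probability 0.25 with beta = 1 -> log 0.25 < 0 -> clipped to 0
  cfg1 <- grarep_config(K = 1, d = 1, beta = 1, eps = 1e-12,
                        normalize_gamma = FALSE)
  A4 <- matrix(0.25, 4, 4)
  expect_true(all(kstep_log_matrix(A4, 1, cfg1) == 0))
  # A^1 is A itself: recover it through the log transform
  cfgng <- grarep_config(K = 1, d = 1, beta = 1e-6, eps = 1e-15,
                         normalize_gamma = FALSE)
  X <- kstep_log_matrix(A, 1, cfgng)
  expect_equal(exp(X[1, 2] + log(1e-6)), 1, tolerance = 1e-6)
})

test_that("k-step representation is a deterministically signed scaled SVD", {
  expect_equal(kstep_representation(matrix(0, 3, 3), 2), matrix(0, 3, 2))
  W <- kstep_representation(diag(c(2, 1)), 1)
  expect_equal(W, matrix(c(sqrt(2), 0), 2, 1))
  # rank-complete SVD reconstructs X
  set.seed(8)
  X <- abs(matrix(rnorm(30), 5, 6))
  sv <- svd(X)
  W5 <- kstep_representation(X, 5)
  expect_equal(abs(W5), abs(sv$u %*% diag(sqrt(sv$d[1:5]))),
               tolerance = 1e-8)
  expect_error(kstep_representation(matrix(c(1, NA, 1, 1), 2), 1))
})

test_that("full embedding equals the naive dense recipe on random graphs", {
  set.seed(13)
  for (rep in 1:5) {
    n_mi <- sample(2:5, 1); n_m <- sample(3:7, 1)
    pairs <- unique(data.frame(
      mirna = paste0("mi", sample(n_mi, 14, TRUE)),
      mrna = paste0("g", sample(n_m, 14, TRUE))))
    g <- build_graph(pairs)
    K <- sample(2:4, 1)
    cfg <- grarep_config(K = K, d = 2, beta = 1 / nrow(g$S), eps = 1e-9)
    W <- grarep_embed(g, cfg)$W
    W_ref <- brute_grarep(g$S, K, 2, 1 / nrow(g$S), 1e-9)
    expect_equal(unname(W), W_ref, tolerance = 1e-7)
  }
})

test_that("K = 1 embedding equals its first block and shapes are N x K*d", {
  pairs <- data.frame(mirna = c("mi1", "mi2", "mi1"),
                      mrna = c("g1", "g2", "g2"))
  g <- build_graph(pairs)
  cfg1 <- grarep_config(K = 1, d = 3)
  cfg3 <- grarep_config(K = 3, d = 3)
  W1 <- grarep_embed(g, cfg1)$W
  W3 <- grarep_embed(g, cfg3)$W
  expect_equal(dim(W1), c(4L, 3L))
  expect_equal(dim(W3), c(4L, 9L))
  expect_equal(W3[, 1:3], W1)
})

test_that("relabeling nodes permutes embedding rows identically", {
  # an asymmetric graph so the singular values are distinct and the
  # factorization is unique up to the fixed sign convention
  pairs <- data.frame(mirna = c("mi1", "mi2", "mi3", "mi1", "mi1"),
                      mrna = c("g1", "g2", "g1", "g3", "g2"))
  cfg <- grarep_config(K = 2, d = 2)
  W <- grarep_embed(build_graph(pairs), cfg)$W
  # rename so the sorted node order changes but topology does not
  ren <- c(mi1 = "miZ", mi2 = "miA", mi3 = "miM",
           g1 = "gQ", g2 = "gB", g3 = "gK")
  pairs2 <- data.frame(mirna = unname(ren[pairs$mirna]),
                       mrna = unname(ren[pairs$mrna]))
  W2 <- grarep_embed(build_graph(pairs2), cfg)$W
  # compare Gram matrices, which are invariant to the residual sign
  # ambiguity of (near-)tied singular directions
  G1 <- W %*% t(W)
  G2 <- W2 %*% t(W2)
  expect_equal(unname(G2[ren[rownames(W)], ren[rownames(W)]]),
               unname(G1), tolerance = 1e-9)
})

test_that("isolated and unseen nodes fall back to zero features", {
  g <- build_graph(data.frame(mirna = "mi1", mrna = "g1"))
  emb <- grarep_embed(g, grarep_config(K = 2, d = 2))
  expect_warning(f <- node_features(emb, c("mi1", "ghost")), "absent")
  expect_equal(unname(f["ghost", ]), rep(0, 4))
  expect_equal(unname(f["mi1", ]), unname(emb$W["mi1", ]))
})
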