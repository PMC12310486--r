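test_that("negative sampling avoids positives and is exhaustive when forced", {
  pos <- data.frame(mirna = c("mi1", "mi2"), mrna = c("g1", "g2"))
  neg <- sample_negatives(pos, n = 2, seed = 1)
  expect_equal(nrow(neg), 2L)
  expect_setequal(paste(neg$mirna, neg$mrna),
                  c("mi1 g2", "mi2 g1"))  # the only two non-edges
  expect_error(sample_negatives(pos, n = 3, seed = 1), "2")

  # property: no overlap with positives across seeds
  set.seed(3)
  pos2 <- unique(data.frame(mirna = paste0("mi", sample(6, 25, TRUE)),
                            mrna = paste0("g", sample(10, 25, TRUE))))
  for (s in 1:10) {
    neg2 <- sample_negatives(pos2, n = nrow(pos2), seed = s)
    expect_equal(nrow(merge(neg2, pos2)), 0L)
    expect_false(anyDuplicated(neg2[c("mirna", "mrna")]) > 0)
  }
  expect_identical(sample_negatives(pos2, n = 10, seed = 42),
                   sample_negatives(pos2, n = 10, seed = 42))
})

test_that("stratified folds are balanced, disjoint and exhaustive", {
  ds <- data.frame(mirna = paste0("mi", 1:100), mrna = paste0("g", 1:100),
                   label = rep(c(0L, 1L), 50))
  sp <- kfold_split(ds, folds = 5, seed = 2)
  test_idx <- lapply(sp, `[[`, "test")
  expect_equal(sort(unlist(test_idx)), 1:100)
  expect_equal(lengths(test_idx), rep(20L, 5))
  for (f in sp) {
    expect_equal(sum(ds$label[f$test] == 1), 10L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_equal(sort(c(f$train, f$test)), 1:100)
  }
  expect_error(kfold_split(ds[1:6, ], folds = 5), "fewer")
})

test_that("confusion counts follow the >= threshold convention", {
  cm <- confusion(c(0.9, 0.6, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(cm, list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  expect_equal(confusion(0.5, 1)$TP, 1L)  # tie at threshold is positive
  expect_equal(confusion(0.5, 0)$FP, 1L)
  # flipping all labels swaps TP<->FP and TN<->FN
  set.seed(4)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  a <- confusion(s, y); b <- confusion(s, 1 - y)
  expect_equal(a$TP, b$FP); expect_equal(a$FN, b$TN)
  expect_error(confusion(numeric(0), integer(0)))
})

test_that("thresholded metrics match the hand-worked case and extremes", {
  m <- compute_metrics(list(TP = 3, TN = 2, FP = 1, FN = 0))
  expect_equal(unname(m["ACC"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(m["PPV"]), 0.75)
  expect_equal(unname(m["SEN"]), 1)
  expect_equal(unname(m["TNR"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m["F1"]), 6 / 7, tolerance = 1e-12)
  expect_equal(unname(m["MCC"]), 6 / sqrt(72), tolerance = 1e-12)
  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(perfect[1:6]), rep(1, 6), tolerance = 1e-12)
  inverted <- compute_metrics(list(TP = 0, TN = 0, FP = 5, FN = 5))
  expect_equal(unname(inverted["MCC"]), -1)
  # zero denominators are reported as 0 and flagged
  deg <- compute_metrics(list(TP = 0, TN = 4, FP = 0, FN = 4))
  expect_equal(unname(deg["PPV"]), 0)
  expect_true("PPV" %in% attr(deg, "degenerate"))
})

test_that("metrics agree with brute-force counting on random vectors", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:80, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    cm <- confusion(s, y)
    TP <- 0; TN <- 0; FP <- 0; FN <- 0
    for (j in seq_len(n)) {
      p <- as.integer(s[j] >= 0.5)
      if (p == 1 && y[j] == 1) TP <- TP + 1
      else if (p == 0 && y[j] == 0) TN <- TN + 1
      else if (p == 1) FP <- FP + 1 else FN <- FN + 1
    }
    expect_equal(cm, list(TP = TP, TN = TN, FP = FP, FN = FN))
    expect_equal(TP + TN + FP + FN, n)
  }
})

test_that("AUC equals the exhaustive pairwise comparison, ties at half", {
  expect_equal(unname(auc_aupr(c(.9, .8, .3, .1), c(1, 1, 0, 0))["AUC"]), 1)
  expect_equal(unname(auc_aupr(c(.9, .8, .3, .1), c(0, 1, 0, 1))["AUC"]),
               0.25)
  expect_equal(unname(auc_aupr(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))["AUC"]),
               0.5)
  expect_error(auc_aupr(c(.1, .2), c(1, 1)), "both classes")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    s <- sample(round(runif(20), 2), n, TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(unname(auc_aupr(s, y)["AUC"]), mean(cmp),
                 tolerance = 1e-12)
  }
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- runif(300); y <- rbinom(300, 1, 0.5)
  ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
  expect_equal(unname(auc_aupr(s, y)["AUC"]), ref, tolerance = 1e-12)
})

test_that("AUPR is the average-precision step area", {
  # hand case: descending scores, labels 1,0,1,0 -> AP = (1 + 2/3) / 2
  expect_equal(unname(auc_aupr(c(.9, .8, .7, .6), c(1, 0, 1, 0))["AUPR"]),
               (1 + 2 / 3) / 2, tolerance = 1e-12)
  # order invariance under permutation
  set.seed(5)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  p <- sample(40)
  expect_equal(auc_aupr(s, y)["AUPR"], auc_aupr(s[p], y[p])["AUPR"])
  # perfect ranking gives AP 1
  expect_equal(unname(auc_aupr(c(.9, .8, .2, .1), c(1, 1, 0, 0))["AUPR"]), 1)
})

test_that("the report has one row per fold plus average and Std", {
  fm <- list(c(ACC = 0.8, AUC = 0.9), c(ACC = 0.9, AUC = 0.8))
  rep <- metric_report(fm)
  expect_equal(rep$fold, c("1", "2", "average", "Std"))
  expect_equal(rep$ACC[3], 0.85)
  expect_equal(rep$ACC[4], sd(c(0.8, 0.9)))
})

test_that("ROC points rise from (0,0) to (1,1)", {
  set.seed(9)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  r <- roc_points(s, y)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})
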