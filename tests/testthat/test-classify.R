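# Downstream classification protocol: feature extraction, SVM-RFE,
# kernel-SVM classification and the Acc/Sen/Spe/AUC metrics.

make_feature_table <- function(X, labels, provenance = "real") {
  colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  structure(list(features = X, labels = labels,
                 provenance = rep(provenance, nrow(X)),
                 sample_ids = sprintf("s%03d", seq_len(nrow(X)))),
            class = "feature_table")
}

test_that("fallback extractor is deterministic with the contracted shape", {
  ph <- generate_phantoms(phantom_config(image_size = 32, n_samples = 3,
                                         seed = 70, group_label = "A"))
  tab <- extract_features(ph)
  expect_identical(dim(tab$features), c(3L, 500L))
  expect_false(any(!is.finite(tab$features)))
  tab2 <- extract_features(ph)
  expect_identical(tab$features, tab2$features)
  expect_error(extract_features(ph, extractor = function(img) numeric(10)),
               "500")
})

test_that("fallback features separate phantom classes of different size", {
  big <- generate_phantoms(phantom_config(image_size = 32, n_samples = 50,
                                          tumor_radius_range = c(8, 12),
                                          seed = 71, group_label = "big"))
  small <- generate_phantoms(phantom_config(image_size = 32, n_samples = 50,
                                            tumor_radius_range = c(3, 5),
                                            seed = 72, group_label = "small"))
  tab <- bind_feature_tables(extract_features(big), extract_features(small))
  tvals <- apply(tab$features, 2, function(col) {
    if (sd(col) == 0) return(0)
    unname(t.test(col[tab$labels == "big"], col[tab$labels == "small"])$statistic)
  })
  best <- which.max(abs(tvals))
  p <- t.test(tab$features[tab$labels == "big", best],
              tab$features[tab$labels == "small", best])$p.value
  expect_lt(p, 0.01)
})

test_that("RFE recovers planted informative features among noise", {
  set.seed(80)
  n <- 100; p <- 500
  y <- rep(c("HGG", "LGG"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:5] <- X[, 1:5] + 1.5 * (y == "HGG")
  tab <- make_feature_table(X, y)
  sel <- rfe_select(tab, n_keep = 30, folds = 5, seed = 7)
  expect_length(sel$selected, 30)
  expect_gte(sum(sprintf("f%03d", 1:5) %in% sel$selected), 4)
  sel2 <- rfe_select(tab, n_keep = 30, folds = 5, seed = 7)
  expect_identical(sel$selected, sel2$selected)
  # boundary: keeping everything is the identity
  all_kept <- rfe_select(tab, n_keep = 500, folds = 5, seed = 7)
  expect_identical(all_kept$selected, colnames(tab$features))
  expect_error(rfe_select(make_feature_table(X[1:6, ], y[c(1:3, 51:53)]),
                          n_keep = 2, folds = 5, seed = 1), "folds")
})

test_that("kernel SVM separates a separable design and is seeded", {
  set.seed(81)
  Xtr <- rbind(matrix(rnorm(100, 3), 20), matrix(rnorm(100, -3), 20))
  Xte <- rbind(matrix(rnorm(50, 3), 10), matrix(rnorm(50, -3), 10))
  ytr <- rep(c("HGG", "LGG"), each = 20)
  yte <- rep(c("HGG", "LGG"), each = 10)
  tr <- make_feature_table(Xtr, ytr)
  te <- make_feature_table(Xte, yte)
  cl <- svm_classify(tr, te, positive = "HGG")
  expect_equal(cl$counts$FP + cl$counts$FN, 0)
  expect_equal(cl$counts$TP, 10)
  cl2 <- svm_classify(tr, te, positive = "HGG")
  expect_identical(cl$predicted, cl2$predicted)
  expect_error(svm_classify(make_feature_table(Xtr, rep("HGG", 40)), te),
               "both classes")
})

test_that("shuffled labels drive AUC to chance level", {
  set.seed(82)
  n <- 200
  X <- matrix(rnorm(n * 20), n, 20)
  y <- sample(rep(c("HGG", "LGG"), each = n / 2))
  tab <- make_feature_table(X, y)
  idx <- sample(n, 120)
  tr <- make_feature_table(X[idx, ], y[idx])
  te <- make_feature_table(X[-idx, ], y[-idx])
  cl <- svm_classify(tr, te, positive = "HGG")
  m <- classification_metrics(cl$counts, cl$scores, cl$labels, "HGG")
  expect_lt(abs(m$auc - 0.5), 0.1)
})

test_that("classification metrics follow their closed forms", {
  m <- classification_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(c(m$acc, m$sen, m$spe), c(1, 1, 1))
  m2 <- classification_metrics(list(TP = 3, FN = 1, TN = 2, FP = 2))
  expect_equal(m2$acc, 0.625)
  expect_equal(m2$sen, 0.75)
  expect_equal(m2$spe, 0.5)
  expect_error(classification_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1)),
               "sensitivity")

  # accuracy is the prevalence-weighted convex combination of Sen and Spe
  set.seed(83)
  for (i in 1:20) {
    cnt <- list(TP = sample(0:9, 1) + 1, FN = sample(0:9, 1),
                TN = sample(0:9, 1) + 1, FP = sample(0:9, 1))
    mm <- classification_metrics(cnt)
    npos <- cnt$TP + cnt$FN; nneg <- cnt$TN + cnt$FP
    expect_equal(mm$acc, (npos * mm$sen + nneg * mm$spe) / (npos + nneg),
                 tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the concordant-pair statistic", {
  set.seed(84)
  for (i in 1:30) {
    n <- 40
    labels <- sample(rep(c("HGG", "LGG"), each = n / 2))
    scores <- rnorm(n) + (labels == "HGG")
    if (i %% 3 == 0) scores <- round(scores, 1)  # force ties
    expect_equal(auc_trapezoid(scores, labels, "HGG"),
                 auc_oracle(scores, labels, "HGG"), tolerance = 1e-9)
  }
})

test_that("augmentation experiment is structured and leakage-proof", {
  set.seed(85)
  n <- 60; p <- 60
  y <- rep(c("HGG", "LGG"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:4] <- X[, 1:4] + 1.5 * (y == "HGG")
  tr <- make_feature_table(X[seq(1, n, 2), ], y[seq(1, n, 2)])
  te <- make_feature_table(X[seq(2, n, 2), ], y[seq(2, n, 2)])
  syn <- make_feature_table(X[seq(1, n, 2), ] + 0.1, y[seq(1, n, 2)],
                            provenance = "synthetic")
  res <- augmentation_experiment(tr, list(cycle = syn), te, n_keep = 10,
                                 folds = 5, seed = 3)
  expect_equal(nrow(res), 2)
  expect_identical(res$arm, c("baseline", "+cycle"))
  expect_equal(res$n_train, c(30, 60))
  base_only <- augmentation_experiment(tr, list(), te, n_keep = 10,
                                       folds = 5, seed = 3)
  expect_equal(base_only[1, -1], res[1, -1])
  expect_error(augmentation_experiment(tr, list(cycle = syn), syn,
                                       n_keep = 10, seed = 3),
               "test set")
})
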