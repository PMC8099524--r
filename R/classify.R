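# Downstream classification protocol: per-image feature extraction,
# SVM-based recursive feature elimination with cross-validation, kernel
# SVM classification, and accuracy / sensitivity / specificity / AUC.
# The feature extractor is pluggable; the shipped extractor is a
# deterministic, non-learned intensity/texture map so the pipeline needs
# no pretrained weights.

#' Deterministic fallback feature extractor
#'
#' Maps an image to a fixed-order numeric vector: a 256-bin grayscale
#' histogram, the 16x16 block-mean downsampled intensities (256 values),
#' distribution moments and quantiles, and gradient-magnitude statistics
#' (542 features in total). Purely a function of the pixel values, so
#' identical images always give identical features.
#'
#' @param image 2D grid in [0,1].
#' @return Named-free numeric vector of length 542.
#' @export
fallback_extractor <- function(image) {
  image <- as.matrix(image)
  h <- histogram_compare(image, image, 256L)$hist_a
  pooled <- as.vector(block_mean(image, 16L))
  q <- quantile(image, probs = seq(0, 1, 0.05), names = FALSE)
  m <- mean(image); s <- sd(as.vector(image))
  mom <- c(m, s,
           if (s > 0) mean(((image - m) / s)^3) else 0,
           if (s > 0) mean(((image - m) / s)^4) else 0)
  gx <- image[-1, , drop = FALSE] - image[-nrow(image), , drop = FALSE]
  gy <- image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  gm <- c(mean(abs(gx)), mean(abs(gy)), max(abs(gx)), max(abs(gy)),
          sd(as.vector(gx)))
  c(h, pooled, q, mom, gm)
}

# average-pool a matrix onto a g x g grid
block_mean <- function(m, g) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- ceiling(seq_len(n1) / n1 * g)
  ci <- ceiling(seq_len(n2) / n2 * g)
  sums <- rowsum(t(rowsum(m, ri)), ci)            # g x g (transposed)
  cnt <- tabulate(ri, g) %o% tabulate(ci, g)
  t(sums) / cnt
}

#' Extract a feature table from paired samples
#'
#' Applies `extractor` to every sample's image and keeps the first
#' `n_features` values of each output, in extractor order.
#'
#' @param samples List of [paired_sample()] objects with group labels.
#' @param extractor Function mapping an image matrix to a numeric vector
#'   of length >= `n_features` (default [fallback_extractor()]).
#' @param n_features Number of leading features to retain (default 500).
#' @param provenance `"real"` or `"synthetic"` tag for every row.
#' @return A `feature_table`: list with `features` (n x n_features
#'   matrix), `labels` (character), `provenance`, `sample_ids`.
#' @export
extract_features <- function(samples, extractor = fallback_extractor,
                             n_features = 500L, provenance = "real") {
  stopifnot(length(samples) >= 1L)
  rows <- lapply(samples, function(s) {
    v <- extractor(s$image)
    if (length(v) < n_features)
      stop(sprintf("extractor produced %d features; %d required",
                   length(v), n_features))
    v[seq_len(n_features)]
  })
  feats <- do.call(rbind, rows)
  if (any(!is.finite(feats))) stop("extractor produced non-finite features")
  colnames(feats) <- sprintf("f%03d", seq_len(n_features))
  structure(list(features = feats,
                 labels = vapply(samples, `[[`, "", "group_label"),
                 provenance = rep(provenance, length(samples)),
                 sample_ids = vapply(samples, `[[`, "", "sample_id")),
            class = "feature_table")
}

#' Bind two feature tables row-wise
#' @param a,b `feature_table` objects with identical columns.
#' @return Combined `feature_table`.
#' @export
bind_feature_tables <- function(a, b) {
  stopifnot(identical(colnames(a$features), colnames(b$features)))
  structure(list(features = rbind(a$features, b$features),
                 labels = c(a$labels, b$labels),
                 provenance = c(a$provenance, b$provenance),
                 sample_ids = c(a$sample_ids, b$sample_ids)),
            class = "feature_table")
}

zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

stratified_folds <- function(labels, folds) {
  f <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Recursive feature elimination with cross-validated SVM ranking
#'
#' SVM-RFE: at each iteration a linear SVM is fitted on the training part
#' of each of `folds` stratified folds, the squared weights are averaged
#' across folds, and the lowest-ranked 10% of the remaining features are
#' dropped (at least one; exact once close to `n_keep`), until `n_keep`
#' features remain. Deterministic under `seed`.
#'
#' @param table A `feature_table` with exactly two classes.
#' @param n_keep Number of features to retain (default 30).
#' @param folds Cross-validation folds (default 5); every class must have
#'   at least `folds` members.
#' @param seed RNG seed for the fold assignment.
#' @return List with `table` (the reduced `feature_table`) and `selected`
#'   (column names kept, in original order).
#' @export
rfe_select <- function(table, n_keep = 30L, folds = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  X <- zscore_cols(table$features)
  y <- factor(table$labels)
  if (nlevels(y) != 2L) stop("rfe_select: need exactly two classes")
  if (min(table(y)) < folds)
    stop("rfe_select: every class needs at least `folds` members")
  if (n_keep >= ncol(X)) {
    return(list(table = table, selected = colnames(table$features)))
  }
  with_seed(seed, {
    fold <- stratified_folds(as.character(y), folds)
    keep <- seq_len(ncol(X))
    while (length(keep) > n_keep) {
      w2 <- numeric(length(keep))
      for (k in seq_len(folds)) {
        tr <- fold != k
        fit <- e1071::svm(X[tr, keep, drop = FALSE], y[tr],
                          kernel = "linear", cost = 1, scale = FALSE)
        w <- crossprod(fit$coefs, fit$SV)    # 1 x p weight vector
        w2 <- w2 + as.numeric(w)^2
      }
      n_drop <- max(1L, floor(0.1 * length(keep)))
      n_drop <- min(n_drop, length(keep) - n_keep)
      keep <- keep[order(w2)][-seq_len(n_drop)]
      keep <- sort(keep)
    }
    sel <- colnames(table$features)[keep]
    red <- table
    red$features <- table$features[, keep, drop = FALSE]
    list(table = red, selected = sel)
  })
}

#' Kernel SVM classification
#'
#' Fits an RBF-kernel SVM (`cost = 1`, bandwidth `1/p`) on the training
#' table and predicts the test table, returning confusion counts and
#' continuous decision scores oriented so larger values favor the
#' positive class.
#'
#' @param train,test `feature_table` objects sharing columns.
#' @param positive Label treated as the positive class (the "HGG"
#'   analogue); default: first level alphabetically.
#' @param kernel,cost Passed to [e1071::svm()].
#' @param seed RNG seed (e1071's fit is deterministic for fixed data; the
#'   seed guards any internal shuffling).
#' @return List with `counts` (TP/TN/FP/FN), `scores`, `predicted`,
#'   `labels`, `positive`.
#' @export
svm_classify <- function(train, test, positive = NULL, kernel = "radial",
                         cost = 1, seed = 1L) {
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (!identical(colnames(train$features), colnames(test$features)))
    stop("train and test tables must share feature columns")
  ytr <- factor(train$labels)
  if (nlevels(ytr) != 2L) stop("training set must contain both classes")
  if (is.null(positive)) positive <- levels(ytr)[1]
  fit <- with_seed(seed,
    e1071::svm(train$features, ytr, kernel = kernel, cost = cost,
               scale = TRUE, decision.values = TRUE))
  pred <- predict(fit, test$features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient scores toward the positive class
  score <- as.numeric(dv[, 1])
  cols <- strsplit(colnames(dv)[1], "/")[[1]]
  if (cols[2] == positive) score <- -score
  yte <- test$labels
  counts <- list(TP = sum(pred == positive & yte == positive),
                 TN = sum(pred != positive & yte != positive),
                 FP = sum(pred == positive & yte != positive),
                 FN = sum(pred != positive & yte == positive))
  list(counts = counts, scores = score, predicted = as.character(pred),
       labels = yte, positive = positive)
}

#' Classification metrics: accuracy, sensitivity, specificity, AUC
#'
#' `Acc = (TP + TN) / (TP + FP + TN + FN)`, `Sen = TP / (TP + FN)`,
#' `Spe = TN / (FP + TN)`; AUC is the trapezoidal area under the ROC
#' curve of the continuous scores (equal to the tie-corrected
#' concordant-pair probability).
#'
#' @param counts List/vector with TP, TN, FP, FN.
#' @param scores Continuous decision scores (larger = more positive).
#' @param labels True labels matching `scores`.
#' @param positive Positive-class label.
#' @return List with `acc`, `sen`, `spe`, `auc`.
#' @export
classification_metrics <- function(counts, scores = NULL, labels = NULL,
                                   positive = NULL) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (tp + tn + fp + fn == 0) stop("empty confusion counts")
  if (tp + fn == 0) stop("sensitivity undefined: no positive samples")
  if (fp + tn == 0) stop("specificity undefined: no negative samples")
  auc <- if (!is.null(scores)) auc_trapezoid(scores, labels, positive)
         else NA_real_
  list(acc = (tp + tn) / (tp + tn + fp + fn),
       sen = tp / (tp + fn),
       spe = tn / (fp + tn),
       auc = auc)
}

#' Trapezoidal ROC area
#'
#' Sweeps the decision threshold across the unique score values and
#' integrates the ROC curve with the trapezoidal rule (ties grouped), so
#' the value equals the Mann-Whitney concordance probability with ties
#' counted half.
#'
#' @param scores Continuous scores, larger favoring `positive`.
#' @param labels True labels.
#' @param positive Positive-class label.
#' @return AUC in [0,1].
#' @export
auc_trapezoid <- function(scores, labels, positive) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("AUC needs both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # group tied scores so ties contribute a diagonal (trapezoid) segment
  grp <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(tapply(p, grp, sum)))
  fp <- c(0, cumsum(tapply(!p, grp, sum)))
  tpr <- tp / sum(pos); fpr <- fp / sum(!pos)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Augmentation-benefit experiment
#'
#' Benchmarks classification with and without synthesized samples added
#' to the training set. For each arm (baseline, plus one per synthetic
#' set) the pipeline is: feature extraction is assumed done (tables in),
#' RFE to `n_keep` features on the arm's training table, RBF-SVM fit,
#' evaluation on the shared test table. Synthetic samples are never
#' allowed in the test set.
#'
#' @param real_train `feature_table` of real training samples.
#' @param synthetic_sets Named list of `feature_table`s of synthesized
#'   samples (provenance must be `"synthetic"`).
#' @param test `feature_table` of real test samples.
#' @param n_keep,folds,seed Passed to [rfe_select()].
#' @param positive Positive-class label.
#' @return `data.frame` with one row per arm: `arm`, `n_train`, `acc`,
#'   `sen`, `spe`, `auc`.
#' @export
augmentation_experiment <- function(real_train, synthetic_sets = list(),
                                    test, n_keep = 30L, folds = 5L,
                                    seed = 1L, positive = NULL) {
  if (any(test$provenance != "real"))
    stop("synthetic samples must never appear in the test set")
  arms <- c(list(baseline = real_train),
            lapply(synthetic_sets, function(sy) {
              if (any(sy$provenance != "synthetic"))
                stop("synthetic_sets must carry provenance 'synthetic'")
              bind_feature_tables(real_train, sy)
            }))
  names(arms)[-1] <- paste0("+", names(synthetic_sets))
  rows <- lapply(names(arms), function(nm) {
    tr <- arms[[nm]]
    sel <- rfe_select(tr, n_keep = n_keep, folds = folds, seed = seed)
    te <- test
    te$features <- test$features[, sel$selected, drop = FALSE]
    cl <- svm_classify(sel$table, te, positive = positive, seed = seed)
    m <- classification_metrics(cl$counts, cl$scores, cl$labels, cl$positive)
    data.frame(arm = nm, n_train = nrow(tr$features), acc = m$acc,
               sen = m$sen, spe = m$spe, auc = m$auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
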