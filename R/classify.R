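# Nearest-shrunken-centroid classification of expression profiles on module
# gene sets, with 10-fold cross-validated shrinkage selection, repeated
# randomized train/test splits and ROC/AUROC evaluation.

#' Train a nearest-shrunken-centroid model
#'
#' Standardized centroid differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s_0))` with
#' `m_k = sqrt(1/n_k - 1/n)` are soft-thresholded by `delta`
#' (`d'_ik = sign(d_ik) max(|d_ik| - delta, 0)`), and the shrunken class
#' centroids are rebuilt as `xbar_i + m_k (s_i + s_0) d'_ik`.  `s_i` is the
#' pooled within-class standard deviation, `s_0` its median (a fudge floor
#' for near-constant genes), and class priors are the class frequencies.
#'
#' @param x genes x samples matrix.
#' @param y two-level class labels (factor or character), one per sample.
#' @param delta nonnegative shrinkage threshold.
#' @return `nsc_model` list: `centroid_overall`, `centroids` (raw),
#'   `shrunken_centroids`, `d`, `d_shrunk`, `s`, `s0`, `m`, `priors`,
#'   `classes`, `delta`, `surviving` (genes with any nonzero shrunken
#'   difference).
#' @export
nsc_train <- function(x, y, delta = 0) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required")
  if (ncol(x) != length(y)) stop("one label per sample required")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  if (delta < 0) stop("delta must be nonnegative")
  classes <- levels(y)
  n <- length(y)
  nk <- table(y)
  xbar <- rowMeans(x)
  cent <- vapply(classes, function(k) rowMeans(x[, y == k, drop = FALSE]),
                 numeric(nrow(x)))
  ss <- rowSums(vapply(classes, function(k) {
    xc <- x[, y == k, drop = FALSE] - cent[, k]
    rowSums(xc^2)
  }, numeric(nrow(x))))
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  m <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(m) <- classes
  d <- sweep(cent - xbar, 1L, s + s0, "/")
  d <- sweep(d, 2L, m, "/")
  d_shr <- sign(d) * pmax(abs(d) - delta, 0)
  cent_shr <- xbar + sweep(sweep(d_shr, 2L, m, "*"), 1L, s + s0, "*")
  model <- list(centroid_overall = xbar, centroids = cent,
                shrunken_centroids = cent_shr, d = d, d_shrunk = d_shr,
                s = s, s0 = s0, m = m,
                priors = as.numeric(nk) / n, classes = classes,
                delta = delta,
                surviving = rownames(x)[rowSums(abs(d_shr)) > 0])
  class(model) <- "nsc_model"
  model
}

#' Predict classes with a nearest-shrunken-centroid model
#'
#' Discriminant score
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s_0)^2 - 2 log pi_k`;
#' the predicted class minimizes it.  The ROC `score` is
#' `delta_(class 1) - delta_(class 2)` (second factor level treated as the
#' positive class: a lower discriminant for it gives a higher score).
#'
#' @param model an `nsc_model`.
#' @param x_new genes x samples matrix over the training genes.
#' @return list: `class` (character), `discriminant` (samples x 2),
#'   `score`.
#' @export
nsc_predict <- function(model, x_new) {
  if (is.null(dim(x_new))) x_new <- matrix(x_new, ncol = 1)
  if (!identical(rownames(x_new), names(model$centroid_overall)))
    stop("x_new genes must match the training genes")
  w <- (model$s + model$s0)^2
  disc <- vapply(seq_along(model$classes), function(k) {
    colSums((x_new - model$shrunken_centroids[, k])^2 / w) -
      2 * log(model$priors[k])
  }, numeric(ncol(x_new)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  colnames(disc) <- model$classes
  rownames(disc) <- colnames(x_new)
  list(class = model$classes[apply(disc, 1L, which.min)],
       discriminant = disc,
       score = disc[, 1L] - disc[, 2L])
}

#' Cross-validated selection of the shrinkage threshold
#'
#' Stratified k-fold cross-validation of the misclassification rate over a
#' grid of shrinkage thresholds; the selected threshold is the *largest*
#' delta achieving the minimum CV error (most parsimonious signature).
#'
#' @param x genes x samples matrix.
#' @param y two-level labels.
#' @param k_folds folds (default 10); every class must have at least
#'   `k_folds` samples so each fold contains both classes.
#' @param delta_grid thresholds to evaluate (default: 30 values from 0 to
#'   the largest unshrunken |d|).
#' @param seed seed for the fold assignment.
#' @return list: `delta` (selected), `cv_error` (named by delta),
#'   `delta_grid`.
#' @export
nsc_cv <- function(x, y, k_folds = 10, delta_grid = NULL, seed = 1) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required")
  loo <- k_folds == length(y)   # leave-one-out: stratification impossible
  if (!loo && any(table(y) < k_folds))
    stop("a class is too small to stratify into ", k_folds, " folds")
  if (is.null(delta_grid)) {
    full <- nsc_train(x, y, delta = 0)
    delta_grid <- seq(0, max(abs(full$d)), length.out = 30)
  }
  set.seed(seed)
  fold <- integer(length(y))
  if (loo) {
    fold <- seq_along(y)
  } else {
    for (k in levels(y)) {
      idx <- sample(which(y == k))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  }
  errs <- matrix(NA_real_, k_folds, length(delta_grid))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    for (j in seq_along(delta_grid)) {
      fit <- nsc_train(x[, tr, drop = FALSE], y[tr], delta_grid[j])
      pred <- nsc_predict(fit, x[, !tr, drop = FALSE])$class
      errs[f, j] <- mean(pred != as.character(y[!tr]))
    }
  }
  cv <- colMeans(errs)
  best <- max(delta_grid[cv == min(cv)])  # parsimony tie-break
  list(delta = best, cv_error = stats::setNames(cv, signif(delta_grid, 4)),
       delta_grid = delta_grid)
}

#' ROC curve and AUROC
#'
#' Threshold sweep over the unique scores (higher score = more confidently
#' positive); tied scores step diagonally.  The AUROC is the trapezoidal
#' area and equals the Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric scores, one per sample.
#' @param labels class labels.
#' @param positive label treated as positive (default: last factor level).
#' @return list: `fpr`, `tpr` (curve points from (0,0) to (1,1)), `auroc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("both classes must be present")
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == positive
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; ps <- pos[ord]
  # group tied scores so they step simultaneously
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(ps); fp <- cumsum(!ps)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auroc = auroc)
}

#' Repeated randomized train/test evaluation of module gene signatures
#'
#' For each of `n_splits` stratified random splits (default 75% train):
#' the shrinkage threshold is selected by [nsc_cv()] on the training set,
#' the model refit at that threshold, the test set scored, and the AUROC
#' computed; genes are ranked by the largest absolute shrunken difference
#' `|d'|`.  Per feature set, the summary reports the gene ranked first most
#' often.
#'
#' @param x genes x samples matrix.
#' @param y two-level labels.
#' @param feature_sets named list of gene-id vectors (e.g. module members).
#' @param n_splits randomized splits (default 10).
#' @param train_frac training fraction per class (default 0.75).
#' @param k_folds CV folds inside each training set (default 10).
#' @param seed seed.
#' @return list per feature set: data.frame `splits` (split, auroc, delta,
#'   n_surviving, top_gene) and `top_gene` (modal first-ranked gene).
#' @export
repeated_split_eval <- function(x, y, feature_sets, n_splits = 10,
                                train_frac = 0.75, k_folds = 10, seed = 1) {
  y <- factor(y)
  set.seed(seed)
  split_seeds <- sample.int(1e6, n_splits)
  lapply(feature_sets, function(genes) {
    genes <- intersect(genes, rownames(x))
    xg <- x[genes, , drop = FALSE]
    rows <- lapply(seq_len(n_splits), function(s) {
      set.seed(split_seeds[s])
      tr_idx <- unlist(lapply(levels(y), function(k) {
        idx <- which(y == k)
        sample(idx, max(2, round(train_frac * length(idx))))
      }))
      tr <- seq_along(y) %in% tr_idx
      sel <- nsc_cv(xg[, tr, drop = FALSE], y[tr], k_folds = k_folds,
                    seed = split_seeds[s])
      fit <- nsc_train(xg[, tr, drop = FALSE], y[tr], sel$delta)
      pred <- nsc_predict(fit, xg[, !tr, drop = FALSE])
      roc <- roc_auc(pred$score, y[!tr])
      rank_stat <- apply(abs(fit$d_shrunk), 1L, max)
      if (all(rank_stat == 0))  # fully shrunken: fall back to unshrunken d
        rank_stat <- apply(abs(fit$d), 1L, max)
      data.frame(split = s, auroc = roc$auroc, delta = sel$delta,
                 n_surviving = length(fit$surviving),
                 top_gene = names(which.max(rank_stat)),
                 stringsAsFactors = FALSE)
    })
    splits <- do.call(rbind, rows)
    tab <- sort(table(splits$top_gene), decreasing = TRUE)
    list(splits = splits, top_gene = names(tab)[1L],
         top_gene_freq = as.integer(tab[1L]))
  })
}
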