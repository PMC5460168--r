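# independent straight-line recomputation of the shrunken-centroid algebra
nsc_oracle <- function(x, y, delta) {
  y <- factor(y); classes <- levels(y)
  n <- length(y); nk <- table(y)
  xbar <- rowMeans(x)
  cent <- sapply(classes, function(k) rowMeans(x[, y == k, drop = FALSE]))
  ss <- 0
  for (k in classes)
    ss <- ss + rowSums((x[, y == k, drop = FALSE] - cent[, k])^2)
  s <- sqrt(ss / (n - 2))
  s0 <- median(s)
  out <- list(s = s, s0 = s0, cent = cent, xbar = xbar)
  out$d <- out$dp <- out$shr <- cent
  for (k in classes) {
    mk <- sqrt(1 / nk[[k]] - 1 / n)
    dk <- (cent[, k] - xbar) / (mk * (s + s0))
    dpk <- sign(dk) * pmax(abs(dk) - delta, 0)
    out$d[, k] <- dk
    out$dp[, k] <- dpk
    out$shr[, k] <- xbar + mk * (s + s0) * dpk
  }
  out$priors <- as.numeric(nk) / n
  out
}

nsc_predict_oracle <- function(or, xnew, classes) {
  apply(xnew, 2, function(v) {
    disc <- vapply(seq_along(classes), function(k)
      sum((v - or$shr[, k])^2 / (or$s + or$s0)^2) - 2 * log(or$priors[k]),
      numeric(1))
    classes[which.min(disc)]
  })
}

toy_cohort <- function(n_per_class = 6, seed = 70) {
  set.seed(seed)
  y <- rep(c("healthy", "disease"), each = n_per_class)
  x <- matrix(rnorm(4 * 2 * n_per_class), 4, 2 * n_per_class,
              dimnames = list(paste0("g", 1:4),
                              paste0("s", 1:(2 * n_per_class))))
  # two informative genes with a 3-sd class shift, two pure noise
  x[1:2, y == "disease"] <- x[1:2, y == "disease"] + 3
  list(x = x, y = factor(y))
}

test_that("zero shrinkage reproduces raw centroids; full shrinkage collapses them", {
  tc <- toy_cohort()
  m0 <- nsc_train(tc$x, tc$y, delta = 0)
  expect_equal(m0$shrunken_centroids, m0$centroids, tolerance = 1e-12)
  expect_setequal(m0$surviving, rownames(tc$x))

  big <- max(abs(m0$d)) + 1
  mfull <- nsc_train(tc$x, tc$y, delta = big)
  expect_equal(unname(mfull$shrunken_centroids[, 1]),
               unname(mfull$centroid_overall), tolerance = 1e-12)
  expect_length(mfull$surviving, 0)
  # with collapsed centroids and unbalanced priors, the majority class wins
  yu <- factor(c(rep("healthy", 4), rep("disease", 8)))
  mu <- nsc_train(tc$x, yu, delta = max(abs(nsc_train(tc$x, yu, 0)$d)) + 1)
  pred <- nsc_predict(mu, tc$x)
  expect_true(all(pred$class == "disease"))
})

test_that("moderate shrinkage keeps exactly the informative genes", {
  tc <- toy_cohort()
  m0 <- nsc_train(tc$x, tc$y, delta = 0)
  d_noise <- max(abs(m0$d[c("g3", "g4"), ]))
  d_info <- min(abs(m0$d[c("g1", "g2"), ]))
  expect_gt(d_info, d_noise)
  m <- nsc_train(tc$x, tc$y, delta = (d_noise + d_info) / 2)
  expect_setequal(m$surviving, c("g1", "g2"))
})

test_that("training matches the independent formula oracle", {
  set.seed(71)
  for (rep in 1:20) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    y <- factor(rep(c("a", "b"), c(n1, n2)))
    x <- matrix(rnorm(6 * (n1 + n2)), 6, n1 + n2,
                dimnames = list(paste0("g", 1:6),
                                paste0("s", 1:(n1 + n2))))
    delta <- runif(1, 0, 2)
    fit <- nsc_train(x, y, delta)
    or <- nsc_oracle(x, y, delta)
    expect_equal(fit$s, or$s, tolerance = 1e-12)
    expect_equal(fit$s0, or$s0, tolerance = 1e-12)
    expect_equal(unname(fit$d), unname(or$d), tolerance = 1e-12)
    expect_equal(unname(fit$shrunken_centroids), unname(or$shr),
                 tolerance = 1e-12)
  }
})

test_that("prediction agrees with the exhaustive per-sample oracle", {
  set.seed(72)
  tc <- toy_cohort(n_per_class = 10, seed = 72)
  fit <- nsc_train(tc$x, tc$y, delta = 0.5)
  or <- nsc_oracle(tc$x, tc$y, 0.5)
  xnew <- matrix(rnorm(4 * 100), 4, 100,
                 dimnames = list(rownames(tc$x), paste0("n", 1:100)))
  pred <- nsc_predict(fit, xnew)
  expect_identical(pred$class,
                   unname(nsc_predict_oracle(or, xnew, fit$classes)))

  # a sample sitting on a shrunken centroid is assigned to that class
  on_cent <- fit$shrunken_centroids[, "healthy", drop = FALSE]
  colnames(on_cent) <- "q"
  yb <- factor(rep(c("healthy", "disease"), each = 10))  # balanced priors
  fitb <- nsc_train(tc$x, yb, delta = 0.5)
  predc <- nsc_predict(fitb, fitb$shrunken_centroids[, "healthy",
                                                     drop = FALSE])
  expect_equal(unname(predc$class), "healthy")
})

test_that("prediction is invariant to per-gene constant shifts", {
  tc <- toy_cohort(n_per_class = 8, seed = 73)
  fit <- nsc_train(tc$x, tc$y, delta = 0.3)
  shift <- c(5, -3, 100, 0.5)
  xs <- tc$x + shift
  fits <- nsc_train(xs, tc$y, delta = 0.3)
  xnew <- matrix(rnorm(4 * 30), 4, 30, dimnames = list(rownames(tc$x),
                                                       paste0("n", 1:30)))
  expect_identical(nsc_predict(fit, xnew)$class,
                   nsc_predict(fits, xnew + shift)$class)
})

test_that("surviving-gene count decreases weakly along the shrinkage grid", {
  tc <- toy_cohort(n_per_class = 10, seed = 74)
  grid <- seq(0, 4, length.out = 25)
  sizes <- vapply(grid, function(dl)
    length(nsc_train(tc$x, tc$y, dl)$surviving), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cross-validation selects a separating threshold and is stratified", {
  set.seed(75)
  n <- 40
  y <- factor(rep(c("healthy", "disease"), each = n / 2))
  x <- matrix(rnorm(10 * n), 10, n,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:n)))
  x[1:3, y == "disease"] <- x[1:3, y == "disease"] + 4
  cv <- nsc_cv(x, y, k_folds = 10, seed = 5)
  expect_equal(min(cv$cv_error), 0)
  expect_gte(cv$delta, 0)
  expect_error(nsc_cv(x[, 15:26], y[15:26], k_folds = 10), "too small")
})

test_that("leave-one-out CV matches an explicit oracle", {
  tc <- toy_cohort(n_per_class = 6, seed = 76)
  grid <- c(0, 0.5, 1)
  cv <- nsc_cv(tc$x, tc$y, k_folds = 12, delta_grid = grid, seed = 1)
  loo <- vapply(grid, function(dl) {
    errs <- vapply(seq_along(tc$y), function(i) {
      fit <- nsc_train(tc$x[, -i, drop = FALSE], tc$y[-i], dl)
      nsc_predict(fit, tc$x[, i, drop = FALSE])$class !=
        as.character(tc$y[i])
    }, logical(1))
    mean(errs)
  }, numeric(1))
  expect_equal(unname(cv$cv_error), loo, tolerance = 1e-12)
})

test_that("permuted labels drive CV error to the majority baseline", {
  errs <- vapply(1:10, function(sd) {
    set.seed(sd)
    n <- 40
    y <- factor(sample(rep(c("healthy", "disease"), each = n / 2)))
    x <- matrix(rnorm(15 * n), 15, n,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:n)))
    cv <- nsc_cv(x, y, k_folds = 5, seed = sd)
    min(cv$cv_error)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.2)
})

test_that("ROC handles separation, ties, and the Mann-Whitney identity", {
  y <- c(rep("neg", 4), rep("pos", 4))
  perfect <- roc_auc(c(1, 2, 3, 4, 5, 6, 7, 8), y, positive = "pos")
  expect_equal(perfect$auroc, 1)
  expect_equal(roc_auc(rep(1, 8), y, positive = "pos")$auroc, 0.5)
  expect_error(roc_auc(1:4, rep("pos", 4)), "both classes")

  # AUROC == Mann-Whitney U / (n1 n0), exactly, including ties
  set.seed(77)
  for (rep in 1:100) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    sc <- sample(1:8, n1 + n0, replace = TRUE)   # heavy ties
    lab <- c(rep("pos", n1), rep("neg", n0))
    r <- roc_auc(sc, lab, positive = "pos")
    ranks <- rank(sc)
    u <- sum(ranks[lab == "pos"]) - n1 * (n1 + 1) / 2
    expect_equal(r$auroc, u / (n1 * n0), tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(78)
  sc <- rnorm(40)
  lab <- sample(c("pos", "neg"), 40, replace = TRUE, prob = c(0.4, 0.6))
  a1 <- roc_auc(sc, lab, positive = "pos")$auroc
  expect_equal(roc_auc(exp(sc), lab, positive = "pos")$auroc, a1)
  expect_equal(roc_auc(sc^3 + 5 * sc, lab, positive = "pos")$auroc, a1)
})

test_that("ROC agrees with the pROC reference implementation", {
  set.seed(79)
  for (rep in 1:20) {
    sc <- rnorm(30)
    lab <- sample(c("a", "b"), 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    mine <- roc_auc(sc, lab, positive = "b")$auroc
    ref <- suppressMessages(pROC::auc(pROC::roc(lab, sc, levels = c("a", "b"),
                                                direction = "<")))
    expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("repeated split evaluation is deterministic and well-formed", {
  set.seed(80)
  n <- 44
  y <- factor(rep(c("healthy", "disease"), each = n / 2))
  x <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:n)))
  x[1:5, y == "disease"] <- x[1:5, y == "disease"] + 2
  fs <- list(info = paste0("g", 1:10))
  r1 <- repeated_split_eval(x, y, fs, n_splits = 4, k_folds = 5, seed = 3)
  r2 <- repeated_split_eval(x, y, fs, n_splits = 4, k_folds = 5, seed = 3)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$info$splits), 4)
  expect_true(all(r1$info$splits$auroc >= 0 & r1$info$splits$auroc <= 1))
  expect_true(r1$info$top_gene %in% paste0("g", 1:10))
})
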