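test_that("macro AUC agrees with brute-force pair counting", {
  # perfectly separated two-class scores
  y <- rep(c("a", "b"), each = 10)
  s <- c(rnorm(10, -5), rnorm(10, 5))
  expect_equal(macro_auc(cbind(a = -s, b = s), y), 1.0)

  # the 4-point fixture: pair counting gives 1.0 with positives at
  # {0.4, 0.8} and 0.75 with positives at {0.35, 0.8}
  s4 <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(macro_auc(cbind(n = -s4, p = s4), c("n", "p", "n", "p")), 1.0)
  expect_equal(macro_auc(cbind(n = -s4, p = s4), c("n", "n", "p", "p")), 0.75)

  # random multiclass scores with ties vs the enumeration oracle
  set.seed(41)
  for (k in 2:3) {
    y <- sample(letters[1:k], 60, replace = TRUE)
    sc <- matrix(sample(seq(0, 1, 0.1), 60 * k, replace = TRUE), ncol = k)
    colnames(sc) <- letters[1:k]
    expect_equal(macro_auc(sc, y), brute_macro_auc(sc, y))
  }

  # chance level for label-independent scores
  set.seed(42)
  y <- sample(c("a", "b"), 4000, replace = TRUE)
  s <- rnorm(4000)
  expect_lt(abs(macro_auc(cbind(a = -s, b = s), y) - 0.5), 0.03)

  expect_error(macro_auc(cbind(a = 1:4, b = 4:1), rep("a", 4)),
               "2 classes")
})

test_that("macro AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  y <- sample(c("neg", "pos"), 80, replace = TRUE)
  s <- rnorm(80) + (y == "pos")
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(macro_auc(cbind(neg = -s, pos = s), y), ref)
})

test_that("expected calibration error follows the binned definition", {
  # all confident and correct
  p <- cbind(a = rep(1, 5), b = rep(0, 5))
  expect_equal(expected_calibration_error(p, rep("a", 5)), 0)

  # one bin, perfectly calibrated: confidence 0.7, 70% correct
  p <- cbind(a = rep(0.7, 10), b = rep(0.3, 10))
  y <- c(rep("a", 7), rep("b", 3))
  expect_equal(expected_calibration_error(p, y), 0)

  # hand-computed 10-row fixture (10 bins): 0.22 exactly
  conf <- c(.55, .65, .65, .75, .75, .75, .85, .85, .95, .95)
  correct <- c(1, 0, 1, 1, 0, 1, 1, 1, 1, 0)
  p <- cbind(A = conf, B = 1 - conf)
  y <- ifelse(correct == 1, "A", "B")
  expect_equal(expected_calibration_error(p, y, 10), 0.22)

  # invariant under class relabelling; bounded in [0, 1]
  p2 <- p[, c(2, 1)]; colnames(p2) <- c("B", "A")
  expect_equal(expected_calibration_error(p2, y, 10), 0.22)
  expect_gte(expected_calibration_error(p, sample(y), 10), 0)
  expect_lte(expected_calibration_error(p, rep("B", 10), 10), 1)

  expect_error(expected_calibration_error(p[0, ], character(0)), "empty")
  expect_error(expected_calibration_error(cbind(a = 0.8, b = 0.5), "a"),
               "sum to 1")
})

test_that("fixed-width interval schemes tile the beat axis", {
  sch <- interval_scheme_fixed(475, 25)
  expect_length(sch, 19)
  expect_equal(sch[[1]], c(0, 25))
  expect_equal(sch[[19]], c(450, 475))
  # remainder dropped
  expect_length(interval_scheme_fixed(500, 30), 16)
  expect_error(interval_scheme_fixed(10, 25))
})

test_that("landmark interval scheme names P, QRS, T, TP in beat coordinates", {
  tpl <- default_template()
  sch <- interval_scheme_landmarks(tpl)
  expect_named(sch, c("P", "QRS", "T", "TP"))
  expect_equal(sch$P[1], 0)
  expect_equal(sch$TP[2], 500)
  # QRS spans 35 + 55 ms around the internal R offset
  expect_equal(sch$QRS, c(95 - 18, 95 + 28))
  # contiguous tiling
  expect_equal(sch$P[2], sch$QRS[1])
  expect_equal(sch$QRS[2], sch$T[1])
  expect_equal(sch$T[2], sch$TP[1])
})

test_that("permutation importance localizes to the informative block", {
  set.seed(17)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 100, sd = 0.1), ncol = 100)
  X[, 26:50] <- X[, 26:50] + ifelse(y == "b", 1, -1)  # block 2 informative
  sch <- interval_scheme_fixed(100, 25)
  pred <- make_interval_mean_predictor(X, y, c(25L, 50L), positive = "b")
  prof <- grouped_permutation_importance(X, y, pred, sch,
                                         n_repeats = 20, seed = 7)
  expect_equal(attr(prof, "baseline"), 1.0)
  expect_equal(attr(prof, "n_repeats"), 20L)
  # permuting the informative block drives the AUC towards chance
  expect_equal(prof$mean_drop[2], 0.5, tolerance = 0.15)
  # blocks the predictor provably ignores drop exactly zero
  expect_identical(prof$mean_drop[c(1, 3, 4)], c(0, 0, 0))
  expect_identical(prof$sd_drop[c(1, 3, 4)], c(0, 0, 0))

  # a predictor ignoring all inputs scores zero drop everywhere
  lazy <- function(newX) cbind(a = rep(0, nrow(newX)), b = rep(1, nrow(newX)))
  prof0 <- grouped_permutation_importance(X, y, lazy, sch,
                                          n_repeats = 3, seed = 1)
  expect_identical(prof0$mean_drop, rep(0, 4))

  # deterministic under a fixed seed
  prof2 <- grouped_permutation_importance(X, y, pred, sch,
                                          n_repeats = 20, seed = 7)
  expect_identical(prof$mean_drop, prof2$mean_drop)
  expect_identical(attr(prof, "drops"), attr(prof2, "drops"))

  expect_error(grouped_permutation_importance(
    X, y, pred, interval_scheme_fixed(200, 25), seed = 1), "exceeds")
})

test_that("permutation importance permutes all leads of an interval jointly", {
  set.seed(23)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X3 <- array(rnorm(n * 50 * 2, sd = 0.1), dim = c(n, 50, 2))
  X3[, 1:25, 1] <- X3[, 1:25, 1] + ifelse(y == "b", 1, -1)
  # predictor reads lead 2 of block 1 minus lead 1 of block 1: a shared
  # row permutation keeps their difference structure intact per row
  sch <- interval_scheme_fixed(50, 25)
  pred <- function(newX) {
    m <- rowMeans(newX[, 1:25, 1])
    cbind(a = -m, b = m)
  }
  prof <- grouped_permutation_importance(X3, y, pred, sch,
                                         n_repeats = 10, seed = 3)
  expect_gt(prof$mean_drop[1], 0.3)
  expect_identical(prof$mean_drop[2], 0)
})

test_that("importance correlation flags zero-variance inputs", {
  v <- c(1, 3, 2, 5, 4)
  m <- importance_correlation(list(v, v, -v))
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], -1)
  expect_equal(diag(m), rep(1, 3))

  w <- c(2, 1, 4, 3, 6)
  direct <- sum((v - mean(v)) * (w - mean(w))) /
    sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  expect_equal(importance_correlation(cbind(v, w))[1, 2], direct)

  expect_warning(m0 <- importance_correlation(list(v, rep(1, 5))),
                 "zero-variance")
  expect_true(is.na(m0[1, 2]))
  expect_error(importance_correlation(list(v)), "at least 2")
})

test_that("map realignment preserves constants and concentrates QRS mass", {
  tpl <- default_template()
  rec <- generate_record(90, seed = 5)
  res <- suppressWarnings(transform(rec, alignment_config(
    tpl, output = "full_signal")))

  cmap <- importance_map(matrix(2.5, n_samples(rec), 1))
  al <- realign_map(cmap, res)
  expect_equal(al$space, "aligned")
  expect_lt(max(abs(al$values - 2.5)), 1e-9)

  # indicator on the source QRS windows ends up in the template QRS interval
  mv <- matrix(0, n_samples(rec), 1)
  for (t in rec$truth_rpeaks) {
    mv[seq(max(1, t - 17), min(n_samples(rec), t + 28)) + 1, ] <- 1
  }
  am <- realign_map(importance_map(mv), res)
  sch <- interval_scheme_landmarks(tpl)
  frac <- sum(am$values[(sch$QRS[1] + 1):sch$QRS[2], ]) / sum(am$values)
  expect_gte(frac, 0.95)

  expect_error(realign_map(importance_map(matrix(1, 10, 1)), res),
               "does not match")
  expect_error(realign_map(al, res), "original")
})

test_that("map aggregation is the pointwise mean", {
  m1 <- importance_map(matrix(1:20, ncol = 2), space = "aligned")
  m2 <- importance_map(matrix(-(1:20), ncol = 2), space = "aligned")
  expect_equal(aggregate_maps(list(m1))$values, m1$values)
  expect_equal(max(abs(aggregate_maps(list(m1, m2))$values)), 0)

  set.seed(19)
  mu <- matrix(rnorm(40), ncol = 2)
  maps <- lapply(1:100, function(i)
    importance_map(mu + matrix(rnorm(40, sd = 0.5), ncol = 2),
                   space = "aligned"))
  agg <- aggregate_maps(maps)
  se <- 0.5 / sqrt(100)
  expect_true(all(abs(agg$values - mu) < 3 * se + 0.05))
  expect_equal(attr(agg, "n_maps"), 100)

  expect_error(aggregate_maps(list()), "empty")
  expect_error(aggregate_maps(list(m1, importance_map(matrix(1, 3, 1),
                                                      space = "aligned"))),
               "shape")
})

test_that("interval PCA isolates single modes of variation", {
  tpl <- default_template()
  sch <- interval_scheme_landmarks(tpl)
  set.seed(29)
  n <- 40
  base <- sin(seq(0, 3 * pi, length.out = 500)) * 0.05
  t_pattern <- numeric(500)
  t_pattern[(sch$T[1] + 1):sch$T[2]] <- dnorm(1:(sch$T[2] - sch$T[1]),
                                              mean = 70, sd = 20)
  scal <- rnorm(n)
  beats <- t(sapply(scal, function(s)
    base + s * t_pattern + rnorm(500, sd = 1e-4)))
  res <- interval_pca(beats, sch)
  expect_equal(colnames(res$scores), c("QRS", "T"))
  # T scores recover the generating scalar up to an affine map
  expect_gt(abs(cor(res$scores[, "T"], scal)), 0.9999)
  expect_lt(sd(res$scores[, "QRS"]), 0.01 * sd(res$scores[, "T"]))
  # sign convention: largest-magnitude loading element positive
  for (l in res$loadings) expect_gt(l[which.max(abs(l))], 0)

  # duplicated beats give duplicated scores
  res2 <- interval_pca(rbind(beats, beats), sch)
  expect_equal(res2$scores[1:n, ], res2$scores[n + 1:n, ],
               tolerance = 1e-9)

  # shift invariance / scale equivariance
  res_shift <- interval_pca(beats + 5, sch)
  expect_equal(res_shift$scores, res$scores, tolerance = 1e-6)
  res_scale <- interval_pca(3 * beats, sch)
  expect_equal(res_scale$scores, 3 * res$scores, tolerance = 1e-6)

  expect_error(interval_pca(matrix(1, 5, 500), sch), "zero variance")
  expect_error(interval_pca(beats[, 1:100], sch), "exceeds")
  expect_error(interval_pca(beats, interval_scheme_fixed(500, 25)),
               "named QRS and T")
})
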