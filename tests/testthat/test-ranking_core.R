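test_that("linear SVM recovers the analytic maximum-margin hyperplane", {
  # symmetric 1D pair: boundary at 0, w > 0
  X1 <- matrix(c(1, -1), nrow = 1,
               dimnames = list("g1", c("s1", "s2")))
  fit1 <- train_linear_svm(X1, c(1, -1), cost = 1e4)
  expect_gt(fit1$weights, 0)
  expect_lt(abs(-fit1$bias / fit1$weights), 1e-6)

  # 2D: 4 points at (+-1, +-0.1), labels by first coordinate; the
  # max-margin separator is x1 = 0 with w = (1, 0)
  X2 <- rbind(g1 = c(1, 1, -1, -1), g2 = c(0.1, -0.1, 0.1, -0.1))
  colnames(X2) <- paste0("s", 1:4)
  fit2 <- train_linear_svm(X2, c(1, 1, -1, -1), cost = 1e4)
  expect_gt(abs(fit2$weights["g1"]), 100 * abs(fit2$weights["g2"]))
  expect_lt(abs(-fit2$bias / fit2$weights["g1"]), 1e-3)
})

test_that("weights are reconstructible from the dual and training is deterministic", {
  ds <- tiny_dataset(seed = 31, d = 10)
  fit <- train_linear_svm(ds$matrix, ds$labels, cost = 10)
  # dual reconstruction: w = sum_k (alpha_k y_k) x_k over support samples
  w_dual <- drop(ds$matrix[, fit$support, drop = FALSE] %*% fit$dual_coef)
  expect_equal(unname(fit$weights), unname(w_dual), tolerance = 1e-6)
  # decision value is w'x + b and separates the training classes
  dec <- predict(fit, ds$matrix)
  expect_true(all(sign(dec) == ds$labels$labels))

  fit2 <- train_linear_svm(ds$matrix, ds$labels, cost = 10)
  expect_identical(fit$weights, fit2$weights)

  expect_error(train_linear_svm(ds$matrix, rep(1, ncol(ds$matrix))),
               "both classes")
})

test_that("dual reconstruction holds on every iteration of a small run", {
  ds <- tiny_dataset(seed = 33, d = 10, n_informative = 3)
  X <- ds$matrix
  s <- seq_len(nrow(X))
  while (length(s) > 1) {
    fit <- train_linear_svm(X[s, , drop = FALSE], ds$labels, cost = 10)
    w_dual <- drop(X[s, fit$support, drop = FALSE] %*% fit$dual_coef)
    expect_equal(unname(fit$weights), unname(w_dual), tolerance = 1e-6)
    s <- s[-order(fit$weights^2)[1]]
  }
})

test_that("welch_t matches hand computation and stats::t.test", {
  # hand-derived: t = (3-2)/sqrt(1/2*2... ) = 1/sqrt(2), Welch dof = 2
  tt <- welch_t(c(2, 4), c(1, 3))
  expect_equal(tt$t_statistic, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(tt$dof, 2, tolerance = 1e-12)
  oracle <- t.test(c(2, 4), c(1, 3))
  expect_equal(tt$p_two_sided, oracle$p.value, tolerance = 1e-12)
  expect_equal(tt$dof, unname(oracle$parameter), tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  tt0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(tt0$t_statistic, 0)
  expect_identical(tt0$p_two_sided, 1)

  # agreement with t.test on random draws, including unequal sizes
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(sample(2:9, 1)); b <- rnorm(sample(2:9, 1), mean = 0.5)
    got <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$dof, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t is invariant to common affine transforms", {
  set.seed(42)
  a <- rnorm(6); b <- rnorm(8, 1)
  base <- welch_t(a, b)
  for (sc in c(0.25, 3, 1000)) {
    shifted <- welch_t(sc * a + 7, sc * b + 7)
    expect_equal(shifted$t_statistic, base$t_statistic, tolerance = 1e-10)
    expect_equal(shifted$dof, base$dof, tolerance = 1e-10)
    expect_equal(shifted$p_two_sided, base$p_two_sided, tolerance = 1e-10)
  }
})

test_that("welch_t singleton fallback and degenerate variances behave as documented", {
  # singleton in the minus group: one-sample t of plus group against the
  # singleton's value
  a <- c(3, 4, 5); b <- 2
  got <- welch_t(a, b)
  ref <- t.test(a, mu = 2)
  expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
  expect_equal(got$dof, 2)
  # singleton in the plus group keeps the sign convention (plus > minus positive)
  got2 <- welch_t(10, c(1, 2, 3))
  expect_gt(got2$t_statistic, 0)

  expect_error(welch_t(1, 2), "n >= 2")
  # constant and equal -> null; constant and different -> maximal significance
  eq <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_identical(eq$p_two_sided, 1)
  ne <- welch_t(c(2, 2, 2), c(5, 5, 5))
  expect_identical(ne$p_two_sided, .Machine$double.eps)
})

test_that("vectorized per-row p-values agree with scalar welch_t", {
  ds <- tiny_dataset(seed = 43, d = 25)
  y <- ds$labels$labels
  p_vec <- sigrfe:::row_welch_p(ds$matrix, ds$labels)
  p_ref <- vapply(seq_len(nrow(ds$matrix)), function(i) {
    welch_t(ds$matrix[i, y == 1], ds$matrix[i, y == -1])$p_two_sided
  }, numeric(1))
  expect_equal(p_vec, p_ref, tolerance = 1e-12)
})

test_that("ranking criteria implement the three documented modes", {
  # rfe: w^2
  sc <- ranking_criteria(c(3, -1, 0.5), mode = "rfe")
  expect_equal(sc$criterion, c(9, 1, 0.25))
  expect_identical(which.min(sc$criterion), 3L)
  # significant: w^2 (1 - p); equal weights, less significant removed first
  sc2 <- ranking_criteria(c(1, 1), c(0.01, 0.9), mode = "significant")
  expect_equal(sc2$criterion, c(0.99, 0.1))
  expect_identical(which.min(sc2$criterion), 2L)
  # literal: w * p, direct substitution
  sc3 <- ranking_criteria(c(0.5, 2), c(0.04, 0.5), mode = "literal")
  expect_equal(sc3$criterion, c(0.02, 1.0))
  expect_identical(which.min(sc3$criterion), 1L)

  expect_error(ranking_criteria(c(1, 2), c(0.5), mode = "significant"),
               "length mismatch")
})

test_that("recursive elimination returns a full permutation and honors E", {
  ds <- tiny_dataset(seed = 51, d = 20, n_informative = 4)
  for (E in c(1, 10, 50, 100)) {
    rl <- recursive_eliminate(ds$matrix, ds$labels, elim_percent = E)
    expect_identical(sort(rl$order), seq_len(20L))
    expect_identical(sum(order(rl$order)), sum(seq_len(20L)))
  }
  # d = 1 degenerate case: one iteration, one feature
  rl1 <- recursive_eliminate(ds$matrix[1, , drop = FALSE], ds$labels)
  expect_identical(rl1$order, 1L)
  expect_identical(nrow(rl1$elimination_trace), 1L)

  expect_error(recursive_eliminate(ds$matrix, ds$labels, elim_percent = 0),
               "elim_percent")
  expect_error(recursive_eliminate(ds$matrix, ds$labels, elim_percent = 101),
               "elim_percent")
})

test_that("E = 100 reduces to a single-pass sort of first-iteration criteria", {
  ds <- tiny_dataset(seed = 52, d = 15, n_informative = 3)
  for (mode in c("significant", "literal", "rfe")) {
    rl <- recursive_eliminate(ds$matrix, ds$labels, mode = mode,
                              elim_percent = 100)
    fit <- train_linear_svm(ds$matrix, ds$labels, cost = 10)
    pv <- if (mode == "rfe") NULL else sigrfe:::row_welch_p(ds$matrix, ds$labels)
    crit <- ranking_criteria(fit$weights, pv, mode = mode)$criterion
    expect_identical(rl$order, order(-crit, -seq_along(crit)))
  }
})

test_that("one-at-a-time elimination matches an independent step-by-step replay", {
  ds <- tiny_dataset(seed = 53, d = 5, n_informative = 2, n_plus = 6,
                     n_minus = 6)
  rl <- svm_rfe(ds$matrix, ds$labels, elim_percent = 1)
  # independent replay: recompute each iteration's w^2 ordering directly
  s <- seq_len(5); expected <- integer(5); pos <- 5L
  while (length(s) > 1) {
    fit <- train_linear_svm(ds$matrix[s, , drop = FALSE], ds$labels, cost = 10)
    drop_i <- order(fit$weights^2, seq_along(s))[1]
    expected[pos] <- s[drop_i]; pos <- pos - 1L
    s <- s[-drop_i]
  }
  expected[1] <- s
  expect_identical(rl$order, expected)
})

test_that("elimination is deterministic and breaks duplicate-feature ties by index", {
  ds <- tiny_dataset(seed = 54, d = 10, n_informative = 2)
  X <- ds$matrix
  X[2, ] <- X[1, ]  # exact duplicate pair
  rownames(X) <- paste0("g", 1:10)
  r1 <- svm_rfe(X, ds$labels)
  r2 <- svm_rfe(X, ds$labels)
  expect_identical(r1$order, r2$order)
  # the duplicate with the smaller index is eliminated first (worse rank)
  expect_gt(which(r1$order == 1L), which(r1$order == 2L))
})

test_that("a strongly shifted planted feature is ranked first almost always", {
  hits <- 0L
  for (seed in 1:25) {
    ds <- simulate_two_class(20, 20, 20, 1, delta = 3, seed = seed)
    rl <- recursive_eliminate(ds$matrix, ds$labels, mode = "significant")
    hits <- hits + (rl$feature_ids[1] == ds$informative_ids)
  }
  expect_gte(hits, 22L)
})
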