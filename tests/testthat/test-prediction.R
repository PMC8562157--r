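test_that("ridge_fit at fixed lambda matches the closed-form oracle", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    m <- sample(2:20, 1)
    X <- matrix(rnorm(n * m), n, m)
    y <- rnorm(n)
    lam <- 10^runif(1, -2, 2)
    fit <- ridge_fit(X, y, lambda = lam)
    expect_equal(unname(fit$effects), oracle_ridge_effects(X, y, lam),
                 tolerance = 1e-8)
    # stored intercept reproduces yhat = ybar + Zc u on the original scale
    expect_equal(ridge_predict(fit, X),
                 mean(y) + drop(sweep(X, 2, colMeans(X)) %*% fit$effects),
                 tolerance = 1e-8)
  }
})

test_that("spectral REML objective equals the determinant-based likelihood", {
  set.seed(202)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    m <- sample(2:25, 1) # both m < n and m >= n paths
    X <- matrix(rnorm(n * m), n, m)
    y <- rnorm(n)
    for (lam in c(0.05, 1, 20)) {
      expect_equal(ridge_reml_loglik(X, y, lam), oracle_reml_loglik(X, y, lam),
                   tolerance = 1e-8)
    }
  }
})

test_that("ridge_fit basic behavior and degenerate inputs", {
  X <- matrix(c(1, -1, 1, -1), ncol = 1)
  y <- c(2, 0, 2, 0)
  # at small lambda the single effect approaches 1, intercept 1
  fit <- ridge_fit(X, y, lambda = 1e-8)
  expect_equal(unname(fit$effects), 1, tolerance = 1e-6)
  expect_equal(ridge_predict(fit, matrix(0, 1, 1)), fit$intercept)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  # shrinkage is monotone in lambda
  expect_lt(abs(ridge_fit(X, y, lambda = 10)$effects), 1)

  # translation invariance
  set.seed(7)
  X2 <- matrix(rnorm(40), 10, 4)
  y2 <- rnorm(10)
  f1 <- ridge_fit(X2, y2)
  f2 <- ridge_fit(X2, y2 + 100)
  expect_equal(f2$effects, f1$effects, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept + 100, tolerance = 1e-4)

  expect_error(ridge_fit(X2, rep(1, 10)), "zero-variance")
  expect_error(ridge_fit(X2[1, , drop = FALSE], 1), "at least 2")
  expect_error(ridge_predict(f1, X2[, c(2, 1, 3, 4)][, , drop = FALSE]), NA)
})

test_that("ridge_predict respects column identity and duplicates", {
  set.seed(31)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("c", 1:5)))
  y <- rnorm(12)
  fit <- ridge_fit(X, y)
  Xbad <- X[, c(2, 1, 3, 4, 5)]
  expect_error(ridge_predict(fit, Xbad), "columns")
  # duplicated row predicts identically
  p <- ridge_predict(fit, X[c(1, 1), , drop = FALSE])
  expect_equal(p[1], p[2])
})

test_that("REML recovers the variance ratio in simulation", {
  set.seed(55)
  ratios <- replicate(30, {
    n <- 120; m <- 30
    X <- matrix(rnorm(n * m), n, m)
    u <- rnorm(m)
    y <- drop(X %*% u) + rnorm(n)
    fit <- ridge_fit(X, y)
    fit$sigma_u2 / fit$sigma_e2
  })
  expect_equal(mean(ratios), 1, tolerance = 0.25)
})

test_that("evaluate_split follows the 80/20, top-q protocol", {
  set.seed(77)
  n <- 120; m <- 60
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  u <- rnorm(m, sd = 0.3)
  g <- drop(X %*% u)
  y <- g + rnorm(n, sd = sd(g)) # h2 = 0.5
  rep1 <- evaluate_split(X, y, seed = 5)
  expect_equal(rep1$n_train, 96L)
  expect_equal(rep1$n_test, 24L)
  expect_true(rep1$accuracy > 0 && rep1$accuracy <= 1)
  expect_true(rep1$heritability >= 0 && rep1$heritability <= 1)
  expect_equal(rep1$selection_differential, rep1$top_q_mean - rep1$test_mean)

  # q = 1 selects everything: differential is exactly zero
  rep_all <- evaluate_split(X, y, q = 1, seed = 5)
  expect_equal(rep_all$top_q_mean, rep_all$test_mean)
  expect_equal(rep_all$selection_differential, 0)

  # seed determinism: identical reports on rerun
  rep2 <- evaluate_split(X, y, seed = 5)
  expect_identical(rep1, rep2)
  # in-sample correlation dominates out-of-sample
  fit <- rep1$model
  ins <- cor(ridge_predict(fit, X[rep1$train, ]), y[rep1$train])
  expect_gte(ins, rep1$accuracy)

  # stratified split keeps the fraction within every stratum
  fam <- rep(1:4, each = 30)
  rep_s <- evaluate_split(X, y, seed = 5, strata = fam)
  expect_equal(as.integer(table(fam[rep_s$train])), rep(24L, 4))
})

test_that("accuracy stays within the theoretical band", {
  # h2 = 0.5 additive trait: accuracy should be positive and below sqrt(h2)
  # plus sampling slack
  set.seed(99)
  n <- 220; m <- 100
  accs <- sapply(1:8, function(s) {
    X <- matrix(rbinom(n * m, 2, 0.5), n, m)
    u <- rnorm(m)
    g <- drop(X %*% u)
    y <- g + rnorm(n, sd = sd(g))
    evaluate_split(X, y, seed = s)$accuracy
  })
  expect_true(all(accs > 0))
  expect_true(all(accs < sqrt(0.5) + 0.15))
})

test_that("cross_validate partitions lines and pools predictions", {
  set.seed(123)
  n <- 60; m <- 30
  X <- matrix(rnorm(n * m), n, m)
  y <- drop(X %*% rnorm(m, sd = 0.5)) + rnorm(n)
  cv <- cross_validate(X, y, k = 5, seed = 2)
  expect_equal(sort(unlist(lapply(cv$reports, `[[`, "test"))), 1:n)
  expect_equal(length(cv$fold), n)
  expect_true(is.finite(cv$pooled_accuracy))
  # determinism
  cv2 <- cross_validate(X, y, k = 5, seed = 2)
  expect_identical(cv$predictions, cv2$predictions)
  # leave-one-out on a 10-line fixture still runs
  loo <- cross_validate(X[1:10, ], y[1:10], k = 10, seed = 1)
  expect_true(is.finite(loo$pooled_accuracy))
  expect_error(cross_validate(X, y, k = 1), "k >= 2")
})

test_that("pooled accuracy tracks mean per-fold accuracy", {
  set.seed(321)
  n <- 300; m <- 80
  X <- matrix(rbinom(n * m, 2, 0.5), n, m)
  g <- drop(X %*% rnorm(m))
  y <- g + rnorm(n, sd = sd(g) * 0.8)
  cv <- cross_validate(X, y, k = 5, seed = 4)
  per_fold <- mean(vapply(cv$reports, `[[`, 0, "accuracy"))
  expect_lt(abs(cv$pooled_accuracy - per_fold), 0.05)
})

test_that("marker_heritability behaves at the signal extremes", {
  set.seed(404)
  n <- 150; m <- 40
  X <- matrix(rbinom(n * m, 2, 0.5), n, m)
  u <- rnorm(m)
  g <- drop(X %*% u)
  # noiseless additive trait
  expect_gt(marker_heritability(X, g), 0.95)
  # pure noise
  h2_null <- sapply(1:15, function(i) marker_heritability(X, rnorm(n)))
  expect_gte(mean(h2_null < 0.15), 0.9)
  # scale invariance
  y <- g + rnorm(n, sd = sd(g))
  expect_equal(marker_heritability(X, y), marker_heritability(X, 5 * y),
               tolerance = 1e-4)
})

test_that("compare_methods shares one split across both arms", {
  sim <- quick_sim(seed = 61, lines_per_family = 20L)
  origins <- trace_generation(sim$genotypes, sim$pedigree, sim$map)
  cmp <- compare_methods(origins, sim$genotypes, sim$phenotypes,
                         "trait1", "env1", seed = 9)
  expect_identical(cmp$raw$train, cmp$aee$train)
  expect_identical(cmp$raw$test, cmp$aee$test)
  expect_equal(cmp$accuracy_ratio, cmp$aee$accuracy / cmp$raw$accuracy)
  expect_equal(cmp$top_q_ratio, cmp$aee$top_q_mean / cmp$raw$top_q_mean)
  # rerun with the same seed reproduces the record exactly
  cmp2 <- compare_methods(origins, sim$genotypes, sim$phenotypes,
                          "trait1", "env1", seed = 9)
  expect_identical(cmp[c("accuracy_ratio", "top_q_ratio", "bottom_q_ratio")],
                   cmp2[c("accuracy_ratio", "top_q_ratio", "bottom_q_ratio")])
})

test_that("compare_methods cv mode pools out-of-fold predictions", {
  sim <- quick_sim(seed = 62, lines_per_family = 20L)
  origins <- trace_generation(sim$genotypes, sim$pedigree, sim$map)
  cmp <- compare_methods(origins, sim$genotypes, sim$phenotypes,
                         "trait1", "env1", seed = 3, mode = "cv", k = 4L)
  expect_equal(cmp$mode, "cv")
  expect_equal(cmp$n_test, nrow(sim$truth$origins)) # every line tested once
  expect_true(is.finite(cmp$accuracy_ratio))
  cmp2 <- compare_methods(origins, sim$genotypes, sim$phenotypes,
                          "trait1", "env1", seed = 3, mode = "cv", k = 4L)
  expect_identical(cmp$accuracy_ratio, cmp2$accuracy_ratio)
})

test_that("raw_marker_matrix codes dosage and imputes column means", {
  calls <- matrix(c("A", "B", "H", NA, "B", "B"), nrow = 2,
                  dimnames = list(c("L1", "L2"), c("m1", "m2", "m3")))
  X <- raw_marker_matrix(calls)
  expect_equal(unname(X[, "m1"]), c(0, 2))
  expect_equal(unname(X[, "m2"]), c(1, 1)) # NA -> column mean of observed (1)
  expect_equal(unname(X[, "m3"]), c(2, 2))
})
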