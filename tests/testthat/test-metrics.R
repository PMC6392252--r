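test_that("fsr and nsr follow the binary-decision definitions", {
  expect_equal(fsr_nsr(3, 0, 0), c(fsr = 0, nsr = 0))
  expect_equal(fsr_nsr(3, 1, 1), c(fsr = 0.25, nsr = 0.25))
  expect_equal(fsr_nsr(0, 2, 0)[["fsr"]], 1)
  # degenerate denominators are flagged, not NaN
  deg <- fsr_nsr(0, 0, 0)
  expect_equal(unname(deg), c(0, 0), ignore_attr = TRUE)
  expect_setequal(attr(deg, "degenerate"), c("fsr", "nsr"))
  expect_true(all(fsr_nsr(2, 5, 9) >= 0 & fsr_nsr(2, 5, 9) <= 1))
})

test_that("estimation error is the Euclidean norm of the difference", {
  expect_equal(estimation_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(estimation_error(c(3, 0), c(0, -4)), 5)
  # metric properties: symmetry and triangle inequality
  set.seed(40)
  a <- rnorm(10); b <- rnorm(10); c <- rnorm(10)
  expect_equal(estimation_error(a, b), estimation_error(b, a))
  expect_lte(estimation_error(a, c),
             estimation_error(a, b) + estimation_error(b, c))
  expect_error(estimation_error(1:3, 1:4))
})

test_that("component matching finds the minimizing permutation", {
  set.seed(41)
  truth <- lapply(1:3, function(k) rnorm(8))
  expect_equal(match_components(truth, truth), 1:3)
  swapped <- truth[c(2, 3, 1)]
  expect_equal(match_components(swapped, truth), c(3L, 1L, 2L))

  # brute-force oracle: enumerate all 6 permutations explicitly
  est <- lapply(1:3, function(k) rnorm(8))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  costs <- vapply(perms, function(pm)
    sum(vapply(1:3, function(k)
      estimation_error(est[[pm[k]]], truth[[k]]), 0)), 0)
  expect_equal(match_components(est, truth),
               as.integer(perms[[which.min(costs)]]))
  expect_error(match_components(est[1:2], truth), "differ")
})

test_that("clustering metrics count per-component assignment decisions", {
  tau <- rep(1:2, each = 5)
  labels <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 1L)
  m <- clustering_metrics(labels, tau)
  expect_equal(m$tp, c(4L, 4L))
  expect_equal(m$fp, c(1L, 1L))
  expect_equal(m$fn, c(1L, 1L))
  expect_equal(m$fsr, c(0.2, 0.2))
  # permutation-aware: swapped labels with the swapping perm are perfect
  m2 <- clustering_metrics(3L - labels, tau, perm = c(2L, 1L))
  expect_equal(m2$tp, c(4L, 4L))
})

test_that("prediction modes agree for K = 1 and handle constants", {
  f <- iccmix:::new_sparse_fit(1.5, 2, 1L, 1L, NA_real_, TRUE, 10L)
  one <- mixreg_model(1, list(f), 1)
  set.seed(42)
  X <- matrix(rnorm(40), 20, 2)
  y <- 1.5 + 2 * X[, 1] + rnorm(20, 0, 0.1)
  p1 <- predict(one, X, y, mode = "posterior")
  p2 <- predict(one, X, mode = "mixture")
  p3 <- predict(one, X, mode = "prior")
  expect_equal(p1$yhat, p2$yhat)
  expect_equal(p1$yhat, p3$yhat)
  expect_equal(p1$yhat, 1.5 + 2 * X[, 1])

  # constant predictor: yhat = c, RMSE = root mean square around c
  fc <- iccmix:::new_sparse_fit(4, numeric(0), integer(0), integer(0),
                                NA_real_, TRUE, 10L)
  const <- mixreg_model(1, list(fc), 1)
  pc <- predict(const, X, y, mode = "mixture")
  expect_equal(pc$yhat, rep(4, 20))
  expect_equal(pc$rmse, sqrt(mean((y - 4)^2)))
  expect_true(is.na(pc$corr))

  expect_error(predict(one, X, mode = "posterior"), "supply y")
})

test_that("posterior-mode prediction assigns well-separated samples correctly", {
  cfg <- small_design()
  d <- simulate_mixreg(cfg, seed = 43)
  sp <- split_train_test(length(d$y), 0.8, scheme = "shuffled", seed = 43)
  fit <- icc_mixreg(d$X[sp$train, ], d$y[sp$train], K = 2, iters = 80,
                    burn_in = 20, seed = 43)
  pr <- predict(fit, d$X[sp$test, ], y = d$y[sp$test], mode = "posterior")
  perm <- match_components(fit$model,
                           lapply(1:2, true_beta, config = d$truth,
                                  p = cfg$p), p = cfg$p)
  acc <- mean(match(pr$cluster, perm) == d$truth$tau[sp$test])
  expect_gt(acc, 0.8)
  expect_gt(pr$corr, 0.8)
})

test_that("Fisher z-transform is exact, odd and increasing", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "strictly")
})

test_that("paired z comparison handles signal and null cases", {
  r <- c(0.8, 0.7, 0.9, 0.85, 0.75)
  # identical lists: zero differences, p = 1 by convention
  expect_equal(paired_z_test(r, r)$p.value, 1)
  # a uniform improvement is significant
  out <- paired_z_test(r, r - 0.3 + c(0.01, -0.01, 0, 0.02, -0.02))
  expect_lt(out$p.value, 0.01)
  expect_gt(out$mean_diff, 0)
  expect_equal(out$n_pairs, 5L)
})
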