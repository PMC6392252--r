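toy_model <- function() {
  f1 <- iccmix:::new_sparse_fit(0.5, 2, 1L, 1L, NA_real_, TRUE, 2L)
  f2 <- iccmix:::new_sparse_fit(-1, c(1, -3), c(1L, 2L), 1:2, NA_real_,
                                TRUE, 2L)
  mixreg_model(c(0.3, 0.7), list(f1, f2), c(1, 2.5))
}

test_that("posterior memberships match direct density arithmetic", {
  # hand toy: n = 2, K = 2, scalar dnorm evaluation of the posterior
  m <- toy_model()
  X <- matrix(c(1, -2, 0.5, 3), 2, 2)
  y <- c(2, -4)
  P <- posterior_membership(m, X, y)
  mu1 <- 0.5 + 2 * X[, 1]
  mu2 <- -1 + X[, 1] - 3 * X[, 2]
  num1 <- 0.3 * dnorm(y, mu1, 1)
  num2 <- 0.7 * dnorm(y, mu2, 2.5)
  expect_equal(P, cbind(num1, num2) / (num1 + num2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
})

test_that("posterior degenerates correctly for symmetric and single models", {
  set.seed(10)
  X <- matrix(rnorm(20), 10)
  y <- rnorm(10)
  f <- iccmix:::new_sparse_fit(1, 2, 1L, 1L, NA_real_, TRUE, 10L)
  twin <- mixreg_model(c(0.5, 0.5), list(f, f), c(1, 1))
  expect_equal(posterior_membership(twin, X, y),
               matrix(0.5, 10, 2), ignore_attr = TRUE)
  one <- mixreg_model(1, list(f), 1)
  expect_equal(posterior_membership(one, X, y), matrix(1, 10, 1),
               ignore_attr = TRUE)
})

test_that("membership imputation is categorical and seed-reproducible", {
  probs <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 3, 2, byrow = TRUE)
  set.seed(11); lab1 <- impute_memberships(probs)
  set.seed(11); lab2 <- impute_memberships(probs)
  expect_identical(lab1, lab2)
  expect_equal(lab1[1], 1L)
  expect_equal(lab1[2], 2L)

  set.seed(12)
  half <- matrix(0.5, 1e5, 2)
  freq <- mean(impute_memberships(half) == 1L)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("component updates follow the count/fit/residual recipe", {
  set.seed(13)
  n <- 200
  X <- matrix(rnorm(n * 50), n)
  y <- 4 * X[, 3] + 1
  # zero residuals: sigma hits the floor rather than collapsing to 0
  up <- update_component(X, y, seq_len(n))
  expect_equal(up$sigma, 1e-4)
  expect_equal(up$pi, 1)

  # single-cluster reduction equals the plain sparse fit
  y2 <- 4 * X[, 3] + rnorm(n)
  up2 <- update_component(X, y2, seq_len(n))
  ref <- sis_mcp(X, y2)
  expect_equal(up2$fit$support, ref$support)
  expect_equal(up2$fit$coef, ref$coef)

  # undersized clusters get intercept-only fits
  up3 <- update_component(X, y2, 1:5)
  expect_length(up3$fit$support, 0L)
  expect_equal(up3$fit$intercept, mean(y2[1:5]))
})

test_that("sigma is recovered at the component scale", {
  cfg <- single_design(n = 200L, p = 2000L)
  d <- simulate_mixreg(cfg, seed = 14)
  up <- update_component(d$X, d$y, seq_len(200), 200)
  expect_equal(up$sigma, 1, tolerance = 0.15)
})

test_that("the ICC chain is reproducible and conserves proportions", {
  d <- simulate_mixreg(small_design(), seed = 15)
  tr1 <- run_icc(d$X, d$y, K = 2, iters = 40, burn_in = 10, seed = 15)
  tr2 <- run_icc(d$X, d$y, K = 2, iters = 40, burn_in = 10, seed = 15)
  expect_identical(tr1$memberships, tr2$memberships)
  expect_equal(tr1$bic, tr2$bic)
  for (m in tr1$models) expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_true(all(tr1$memberships %in% 1:2))
})

test_that("K = 1 short-circuits to a single SIS-MCP fit", {
  d <- simulate_mixreg(single_design(n = 100L, p = 200L), seed = 16)
  tr <- run_icc(d$X, d$y, K = 1, seed = 16)
  expect_equal(tr$iters, 1L)
  # the chain's fits select lambda by the classical BIC
  ref <- sis_mcp(d$X, d$y, ebic_gamma = 0)
  expect_equal(tr$models[[1]]$fits[[1]]$support, ref$support)
  expect_equal(tr$models[[1]]$fits[[1]]$coef, ref$coef)
})

test_that("averaging the relabeled chain recovers the coefficients", {
  cfg <- comparison_design()
  d <- simulate_mixreg(cfg, seed = 17)
  tr <- run_icc(d$X, d$y, K = 3, iters = 150, burn_in = 50, seed = 17)
  avg <- average_model(tr, p = cfg$p)
  truth <- lapply(1:3, function(k) true_beta(cfg, k))
  perm <- match_components(lapply(1:3, function(k) avg$beta[, k]), truth)
  errs <- vapply(1:3, function(k)
    estimation_error(avg$beta[, perm[k]], truth[[k]]), 0)
  expect_true(all(errs < 1.0))
})
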