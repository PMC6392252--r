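test_that("screening ranks by absolute marginal correlation", {
  set.seed(1)
  X <- matrix(rnorm(50 * 10), 50)
  y <- X[, 7]
  expect_equal(sure_independence_screen(X, y, d = 1), 7L)

  # exact positive and negative correlation outrank noise; ties by index
  X2 <- cbind(y, -y, matrix(rnorm(50 * 5), 50))
  expect_equal(sure_independence_screen(X2, y, d = 2), c(1L, 2L))

  # budget beyond dimension returns all features, ranked
  all_idx <- sure_independence_screen(X, y, d = 100)
  expect_length(all_idx, 10L)
  expect_equal(all_idx[1], 7L)
})

test_that("screening is invariant to affine rescaling of columns", {
  set.seed(2)
  X <- matrix(rnorm(40 * 8), 40)
  y <- rnorm(40)
  Xr <- sweep(X, 2, c(2, -5, 0.1, 1, 100, -0.3, 7, 1), "*")
  Xr <- sweep(Xr, 2, rnorm(8), "+")
  expect_equal(sure_independence_screen(X, y, d = 8),
               sure_independence_screen(Xr, y, d = 8))
})

test_that("constant columns and constant responses are handled", {
  set.seed(3)
  X <- cbind(rep(1, 30), matrix(rnorm(30 * 3), 30))
  y <- X[, 2]
  idx <- sure_independence_screen(X, y, d = 4)
  expect_equal(idx[1], 2L)
  expect_equal(idx[4], 1L)  # zero-correlation constant column ranks last
  expect_error(sure_independence_screen(X, rep(2, 30)), "constant")
})

test_that("univariate MCP rule matches grid-search minimization", {
  # oracle: dense grid search over the penalized univariate objective
  mcp_pen <- function(b, lam, gamma)
    ifelse(abs(b) <= gamma * lam, lam * abs(b) - b^2 / (2 * gamma),
           gamma * lam^2 / 2)
  grid_argmin <- function(z, lam, gamma) {
    obj <- function(b) (z - b)^2 / 2 + mcp_pen(b, lam, gamma)
    b <- seq(-1.5 * max(abs(z), 1), 1.5 * max(abs(z), 1), length.out = 1e5)
    b0 <- b[which.min(obj(b))]
    h <- diff(b[1:2])
    fine <- seq(b0 - 2 * h, b0 + 2 * h, length.out = 1e5)
    fine[which.min(obj(fine))]
  }
  cases <- expand.grid(z = c(-4, -1.2, -0.4, 0, 0.7, 2.5, 6),
                       lam = c(0.3, 1), gamma = c(2.5, 3))
  cases <- cases[seq_len(20), ]
  for (i in seq_len(nrow(cases))) {
    expect_equal(mcp_threshold(cases$z[i], cases$lam[i], cases$gamma[i]),
                 grid_argmin(cases$z[i], cases$lam[i], cases$gamma[i]),
                 tolerance = 1e-6)
  }
  # threshold and unbiasedness regions
  expect_equal(mcp_threshold(0, 2), 0)
  expect_equal(mcp_threshold(10, 1, 3), 10)
  expect_error(mcp_threshold(1, 1, gamma = 1), "gamma")
  expect_error(mcp_threshold(1, -1), "lambda")
})

test_that("path endpoints and orthonormal designs match closed forms", {
  set.seed(4)
  n <- 60; d <- 6
  Q <- qr.Q(qr(scale(matrix(rnorm(n * d), n), scale = FALSE)))
  y <- rnorm(n, 2)
  yc <- y - mean(y)
  z <- as.vector(crossprod(Q, yc))
  lam_max <- max(abs(z))

  path <- fit_mcp_path(Q, y, lambda = c(lam_max, lam_max / 2, lam_max / 10))
  # null-model endpoint: empty support, intercept = mean(y)
  expect_equal(path$df[1], 0L)
  expect_equal(path$intercept[1], mean(y))
  # orthonormal columns: path solution is the coordinatewise MCP rule
  for (l in 2:3)
    expect_equal(path$beta[, l], mcp_threshold(z, path$lambda[l]),
                 tolerance = 1e-8)
  # support size non-increasing in lambda on an orthogonal design
  expect_true(all(diff(path$df) >= 0))
})

test_that("the path recovers a strong single signal", {
  set.seed(1)
  X <- matrix(rnorm(50 * 3), 50)
  y <- 3 * X[, 1] + rnorm(50, 0, 0.1)
  path <- fit_mcp_path(X, y)
  j <- which.min(path$bic)
  expect_equal(which(path$beta[, j] != 0), 1L)
  expect_equal(path$beta[1, j], 3, tolerance = 0.2)
  expect_error(fit_mcp_path(X, y, lambda = c(1, 2)), "descending")
})

test_that("sis_mcp reduces to the full path when screening is a no-op", {
  set.seed(6)
  X <- matrix(rnorm(80 * 5), 80)
  y <- 2 * X[, 2] - X[, 4] + rnorm(80, 0, 0.3)
  fit <- sis_mcp(X, y, d = 10)
  path <- fit_mcp_path(X, y)
  j <- which.min(path$bic)
  expect_equal(fit$support, which(path$beta[, j] != 0))
  expect_equal(fit$coef, unname(path$beta[path$beta[, j] != 0, j]),
               tolerance = 1e-10)
  expect_equal(fit$intercept, path$intercept[j], tolerance = 1e-10)
})

test_that("sis_mcp recovers sparse truth at the component scale", {
  cfg <- single_design(n = 200L, p = 2000L)
  hits <- vapply(1:50, function(r) {
    d <- simulate_mixreg(cfg, seed = 7000 + r)
    fit <- sis_mcp(d$X, d$y)
    setequal(fit$support, cfg$beta_specs[[1]]$index)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("pure-noise fits stay (near-)empty", {
  near_empty <- vapply(1:30, function(r) {
    set.seed(8000 + r)
    X <- matrix(rnorm(100 * 300), 100)
    y <- rnorm(100)
    length(sis_mcp(X, y)$support) <= 2
  }, TRUE)
  expect_gte(mean(near_empty), 0.9)
})

test_that("model-free rank screening finds monotone signals", {
  set.seed(9)
  X <- matrix(rnorm(100 * 40), 100)
  y <- exp(X[, 5]) + rnorm(100, 0, 0.2)   # monotone, nonlinear signal
  expect_equal(model_free_screen(X, y, d = 1), 5L)
  expect_length(model_free_screen(X, y, d = 10), 10L)
})
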