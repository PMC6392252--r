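#' Simulation design for mixture-regression data
#'
#' Describes a finite mixture of sparse Gaussian linear regressions from which
#' [simulate_mixreg()] draws datasets. The default design has three components
#' of 200 samples each (n = 600), p = 2000 Gaussian predictors, residual
#' standard deviation 1 in every component, and three nonzero slope
#' coefficients per component all equal to 3, with exactly one nonzero feature
#' shared by all components and the remaining nonzero features mutually
#' exclusive.
#'
#' Predictor vectors are drawn i.i.d. from N(mu * 1_p, I_p), where the common
#' mean mu is drawn once per dataset from uniform(0, 1) (`mu_per = "dataset"`,
#' the default) or independently per feature column (`mu_per = "column"`).
#' Component memberships are assigned deterministically in blocks of
#' `n_per_component` samples, so the empirical mixing proportions equal
#' `n_per_component / sum(n_per_component)` exactly.
#'
#' @param n_per_component integer vector, samples per component. Its length
#'   sets the number of components K.
#' @param p number of predictor features.
#' @param sigma residual standard deviation per component (recycled to K).
#' @param coef_value value of every nonzero slope coefficient.
#' @param n_coef number of nonzero slopes per component.
#' @param shared if `TRUE` (default) the first support feature is common to
#'   all components and the remaining `n_coef - 1` per component are mutually
#'   exclusive; if `FALSE` all supports are mutually exclusive.
#' @param intercept true intercept per component (recycled).
#' @param beta_specs optional explicit supports: a list of K lists, each with
#'   elements `index` (integer feature indices) and `value` (numeric, same
#'   length). Overrides `coef_value`, `n_coef`, `shared`.
#' @param mu_per `"dataset"` or `"column"`: whether the predictor mean mu is
#'   drawn once per dataset or once per feature column.
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_mixreg()]
#' @export
sim_config <- function(n_per_component = c(200L, 200L, 200L), p = 2000L,
                       sigma = 1, coef_value = 3, n_coef = 3L, shared = TRUE,
                       intercept = 0, beta_specs = NULL,
                       mu_per = c("dataset", "column")) {
  mu_per <- match.arg(mu_per)
  K <- length(n_per_component)
  stopifnot(K >= 1L, all(n_per_component >= 1L), p >= 1L)
  sigma <- rep_len(sigma, K)
  intercept <- rep_len(intercept, K)
  if (any(sigma < 0)) stop("sigma must be nonnegative")

  if (is.null(beta_specs)) {
    stopifnot(n_coef >= 1L)
    if (shared && K > 1L) {
      need <- 1L + K * (n_coef - 1L)
      if (need > p) stop("p too small for the requested supports")
      beta_specs <- lapply(seq_len(K), function(k) {
        excl <- if (n_coef > 1L)
          1L + (k - 1L) * (n_coef - 1L) + seq_len(n_coef - 1L) else integer(0)
        list(index = c(1L, excl), value = rep(coef_value, n_coef))
      })
    } else {
      if (K * n_coef > p) stop("p too small for the requested supports")
      beta_specs <- lapply(seq_len(K), function(k) {
        list(index = (k - 1L) * n_coef + seq_len(n_coef),
             value = rep(coef_value, n_coef))
      })
    }
  } else {
    if (length(beta_specs) != K) stop("beta_specs must have one entry per component")
    for (k in seq_len(K)) {
      bs <- beta_specs[[k]]
      if (length(bs$index) != length(bs$value))
        stop("beta_specs index/value length mismatch in component ", k)
      if (anyDuplicated(bs$index) || any(bs$index < 1L) || any(bs$index > p))
        stop("beta_specs indices must be distinct values in 1..p")
    }
  }

  structure(list(n_per_component = as.integer(n_per_component), p = as.integer(p),
                 K = K, sigma = sigma, intercept = intercept,
                 beta_specs = beta_specs, mu_per = mu_per),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Mixture-regression simulation design\n")
  cat(sprintf("  K = %d components, n = %d samples (%s), p = %d features\n",
              x$K, sum(x$n_per_component),
              paste(x$n_per_component, collapse = "+"), x$p))
  cat(sprintf("  sigma = %s; supports: %s\n",
              paste(format(x$sigma), collapse = ", "),
              paste(vapply(x$beta_specs, function(b)
                paste0("{", paste(b$index, collapse = ","), "}"), ""),
                collapse = " ")))
  invisible(x)
}

#' Generate a synthetic mixture-regression dataset
#'
#' Draws one dataset from the design described by a [sim_config()]: predictor
#' rows are i.i.d. N(mu * 1_p, I_p) with mu ~ uniform(0, 1), memberships are
#' assigned in deterministic blocks, and responses follow the component-wise
#' linear model y_i = b_k0 + x_i' b_k + e_i with e_i ~ N(0, sigma_k^2).
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return A list of class `"mixreg_data"` with elements `X` (n x p matrix),
#'   `y` (length-n response) and `truth` (list: `tau` memberships, `beta`
#'   the support specs, `intercept`, `sigma`, `pi`, `mu`).
#' @examples
#' d <- simulate_mixreg(sim_config(c(20, 20), p = 50), seed = 1)
#' dim(d$X); table(d$truth$tau)
#' @export
simulate_mixreg <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(config$n_per_component)
  p <- config$p
  K <- config$K

  mu <- if (config$mu_per == "dataset") rep(runif(1L), p) else runif(p)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2L, mu, "+")

  tau <- rep.int(seq_len(K), config$n_per_component)
  y <- numeric(n)
  for (k in seq_len(K)) {
    idx <- which(tau == k)
    bs <- config$beta_specs[[k]]
    lin <- config$intercept[k] +
      as.vector(X[idx, bs$index, drop = FALSE] %*% bs$value)
    y[idx] <- lin + rnorm(length(idx), 0, config$sigma[k])
  }

  structure(list(X = X, y = y,
                 truth = list(tau = tau, beta = config$beta_specs,
                              intercept = config$intercept,
                              sigma = config$sigma,
                              pi = config$n_per_component / n, mu = mu)),
            class = "mixreg_data")
}

#' Dense true coefficient vector of one component
#'
#' @param config a [sim_config()] or the `truth` element of a
#'   [simulate_mixreg()] dataset.
#' @param k component index.
#' @param p feature dimension (required when `config` is a truth list).
#' @return Numeric vector of length p + 1: intercept followed by the p slopes.
#' @export
true_beta <- function(config, k, p = NULL) {
  if (inherits(config, "sim_config")) {
    p <- config$p
    bs <- config$beta_specs[[k]]
    ic <- config$intercept[k]
  } else {
    stopifnot(!is.null(p))
    bs <- config$beta[[k]]
    ic <- config$intercept[k]
  }
  beta <- numeric(p + 1L)
  beta[1L] <- ic
  beta[bs$index + 1L] <- bs$value
  beta
}
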