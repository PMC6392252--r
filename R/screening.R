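#' Sure independence screening
#'
#' Ranks features by absolute marginal Pearson correlation with the response
#' and keeps the top `d`. Constant feature columns get correlation 0 (never
#' `NA`); ties are broken by ascending feature index, so the result is
#' deterministic. Because correlation is scale- and location-free, screening
#' is invariant to affine rescaling of individual columns.
#'
#' @param X n x p numeric matrix.
#' @param y length-n numeric response; must not be constant.
#' @param d screening budget (number of features kept); defaults to
#'   `floor(n / log(n))`, the usual sample-size-driven budget.
#' @return Integer vector of `min(d, p)` feature indices, ranked by
#'   decreasing |correlation|.
#' @export
sure_independence_screen <- function(X, y, d = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(n >= 2L, length(y) == n)
  if (sd(y) == 0) stop("response is constant; screening is undefined")
  d <- d %||% max(1L, floor(n / log(n)))
  if (d < 1L) stop("screening budget d must be >= 1")
  # marginal Pearson correlations via cross-products (single BLAS pass)
  xm <- colMeans(X)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- as.vector(crossprod(X, y)) - n * xm * mean(y)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(pmax(sxx, 0) * syy)
  r[!is.finite(r)] <- 0
  ord <- order(-abs(r), seq_len(p))
  ord[seq_len(min(d, p))]
}

#' Model-free marginal screening by rank correlation
#'
#' A generic marginal utility screener based on absolute Spearman rank
#' correlation with the response, for reducing very large feature sets (for
#' example expression matrices) to a workable dimension before mixture
#' fitting. It is a simple rank-based utility, robust to monotone marginal
#' transformations, not a reimplementation of any particular published
#' screening statistic.
#'
#' @inheritParams sure_independence_screen
#' @param d number of features to keep.
#' @return Integer vector of kept feature indices, ranked.
#' @export
model_free_screen <- function(X, y, d = 500L) {
  n <- nrow(X)
  stopifnot(n >= 2L, length(y) == n)
  r <- suppressWarnings(as.vector(cor(X, y, method = "spearman")))
  r[!is.finite(r)] <- 0
  ord <- order(-abs(r), seq_len(ncol(X)))
  ord[seq_len(min(d, ncol(X)))]
}

#' Univariate MCP thresholding operator
#'
#' Solution of the one-dimensional MCP-penalized least-squares problem
#' `argmin_b (z - b)^2 / 2 + P(|b|; lambda, gamma)`, where P is the minimax
#' concave penalty. Equals the soft-threshold of `z` rescaled by
#' `1 / (1 - 1/gamma)` when `|z| <= gamma * lambda`, and `z` itself beyond
#' that (the unbiasedness region).
#'
#' @param z numeric (vectorized) ordinary-least-squares-scale coordinate.
#' @param lambda penalty level, `>= 0`.
#' @param gamma concavity parameter, `> 1`; default 3.
#' @return Numeric vector like `z`.
#' @export
mcp_threshold <- function(z, lambda, gamma = 3) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (gamma <= 1) stop("gamma must be > 1")
  soft <- sign(z) * pmax(abs(z) - lambda, 0)
  ifelse(abs(z) <= gamma * lambda, soft / (1 - 1 / gamma), z)
}

#' MCP coordinate-descent solution path
#'
#' Fits MCP-penalized least squares along a descending penalty grid by cyclic
#' coordinate descent with warm starts. Columns are centered and scaled to
#' unit L2 norm internally; the intercept is unpenalized and everything is
#' reported on the original scale. Each path point records the residual sum
#' of squares, the support size and a BIC value
#' `n * log(RSS / n) + df * log(n)` used for penalty selection.
#'
#' @param X n x d numeric matrix (the screened design).
#' @param y length-n response.
#' @param gamma MCP concavity, `> 1`.
#' @param lambda optional descending penalty grid; by default `nlambda`
#'   log-spaced values from `lambda_max` (the smallest penalty zeroing every
#'   coordinate) down to `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio grid size and lower endpoint ratio.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep.
#' @param max_sweeps maximum coordinate-descent sweeps per path point;
#'   non-converged points are flagged in `converged`, not hidden.
#' @param ebic_gamma extended-BIC weight: the per-coefficient penalty is
#'   `log(n) + 2 * ebic_gamma * log(p_total)`. The default 0 gives the
#'   classical BIC.
#' @param p_total dimension over which model search effectively ranged
#'   (relevant when `X` holds the survivors of screening a much larger
#'   feature set); defaults to `ncol(X)`.
#' @return Object of class `"mcp_path"`: list with `lambda`, `beta`
#'   (d x nlambda, original scale), `intercept`, `rss`, `df`, `bic`,
#'   `converged`, `n`.
#' @export
fit_mcp_path <- function(X, y, gamma = 3, lambda = NULL, nlambda = 100L,
                         lambda_min_ratio = 0.001, tol = 1e-7,
                         max_sweeps = 1000L, ebic_gamma = 0, p_total = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 2L)
  if (gamma <= 1) stop("gamma must be > 1")
  if (is.null(lambda)) {
    xm <- colMeans(X)
    Xc <- sweep(X, 2L, xm)
    nrm <- sqrt(colSums(Xc^2))
    nrm[nrm < 1e-12] <- Inf
    lam_max <- max(abs(as.vector(crossprod(Xc, y - mean(y)))) / nrm)
    if (lam_max <= 0) lam_max <- 1e-8
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    if (is.unsorted(rev(lambda), strictly = TRUE))
      stop("lambda grid must be strictly descending")
  }
  fit <- cpp_mcp_path(X, y, gamma, lambda, tol, max_sweeps)
  rss <- pmax(fit$rss, 1e-12)
  p_total <- p_total %||% ncol(X)
  bic <- n * log(rss / n) +
    fit$df * (log(n) + 2 * ebic_gamma * log(p_total))
  if (any(fit$converged == 0L))
    warning("MCP coordinate descent did not converge at ",
            sum(fit$converged == 0L), " path point(s)")
  structure(list(lambda = lambda, beta = fit$beta,
                 intercept = as.vector(fit$intercept),
                 rss = as.vector(fit$rss), df = as.vector(fit$df),
                 bic = as.vector(bic),
                 converged = as.logical(fit$converged), n = n),
            class = "mcp_path")
}

#' @export
print.mcp_path <- function(x, ...) {
  cat(sprintf("MCP path: %d penalty values, n = %d, d = %d\n",
              length(x$lambda), x$n, nrow(x$beta)))
  cat(sprintf("  support sizes %d..%d; BIC-selected lambda = %.4g (df = %d)\n",
              min(x$df), max(x$df), x$lambda[which.min(x$bic)],
              x$df[which.min(x$bic)]))
  invisible(x)
}

# Assemble a sparse_fit record from one path point, mapping the screened
# column positions back to original feature indices.
new_sparse_fit <- function(intercept, coef, support, screened, lambda,
                           converged, n) {
  structure(list(intercept = intercept, coef = coef, support = support,
                 screened = screened, lambda = lambda, converged = converged,
                 n = n),
            class = "sparse_fit")
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("Sparse fit: intercept %.4g, %d nonzero slope(s) (n = %d)\n",
              x$intercept, length(x$support), x$n))
  if (length(x$support))
    cat("  features:", paste0(x$support, " (", format(x$coef, digits = 3), ")",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Sparse regression by screening plus MCP (SIS-MCP)
#'
#' The per-component workhorse: screen to the top `d` features by marginal
#' correlation, fit the MCP path on the survivors, and keep the path point
#' minimizing BIC. All bookkeeping (screened set, selected support on the
#' original feature indexing, penalty level) is retained.
#'
#' Because screening searched the full feature set, the penalty level is
#' chosen by the extended BIC with the *original* dimension p in its
#' complexity term (`ebic_gamma = 1` by default); the classical BIC, blind
#' to the screening step, systematically admits spurious survivors of the
#' marginal-correlation ranking.
#'
#' @inheritParams fit_mcp_path
#' @param d screening budget; defaults to `floor(n / log(n))`.
#' @param ebic_gamma extended-BIC weight for penalty selection; 0 recovers
#'   the classical BIC.
#' @return Object of class `"sparse_fit"`: `intercept`, `coef` (numeric,
#'   aligned with `support`), `support` (original feature indices),
#'   `screened`, `lambda`, `converged`, `n`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100 * 50), 100)
#' y <- 3 * X[, 7] + rnorm(100, 0, 0.5)
#' sis_mcp(X, y)$support
#' @export
sis_mcp <- function(X, y, d = NULL, gamma = 3, nlambda = 100L,
                    lambda_min_ratio = 0.001, tol = 1e-7, max_sweeps = 1000L,
                    ebic_gamma = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("too few samples for a sparse fit (n = ", n, ")")
  keep <- sure_independence_screen(X, y, d = d)
  path <- fit_mcp_path(X[, keep, drop = FALSE], y, gamma = gamma,
                       nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio, tol = tol,
                       max_sweeps = max_sweeps, ebic_gamma = ebic_gamma,
                       p_total = ncol(X))
  j <- which.min(path$bic)
  b <- path$beta[, j]
  nz <- which(b != 0)
  ord <- order(keep[nz])
  new_sparse_fit(intercept = path$intercept[j], coef = b[nz][ord],
                 support = keep[nz][ord], screened = keep,
                 lambda = path$lambda[j], converged = path$converged[j], n = n)
}

# Component mean vector for a sparse fit evaluated on rows of X.
fitted_mean <- function(fit, X) {
  mu <- rep(fit$intercept, nrow(X))
  if (length(fit$support))
    mu <- mu + as.vector(X[, fit$support, drop = FALSE] %*% fit$coef)
  mu
}

#' Dense coefficient vector of a sparse fit
#'
#' @param fit a `"sparse_fit"`.
#' @param p original feature dimension.
#' @return Numeric vector of length p + 1 (intercept first).
#' @export
dense_beta <- function(fit, p) {
  beta <- numeric(p + 1L)
  beta[1L] <- fit$intercept
  if (length(fit$support)) beta[fit$support + 1L] <- fit$coef
  beta
}
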