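#' Construct a mixture regression model object
#'
#' @param pi mixing proportions (length K, nonnegative, summing to 1).
#' @param fits list of K [sis_mcp()] `"sparse_fit"` records.
#' @param sigma residual standard deviations (length K, positive).
#' @return Object of class `"mixreg_model"`.
#' @export
mixreg_model <- function(pi, fits, sigma) {
  K <- length(pi)
  stopifnot(length(fits) == K, length(sigma) == K, all(sigma > 0),
            all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  structure(list(K = K, pi = pi, fits = fits, sigma = sigma),
            class = "mixreg_model")
}

#' @export
print.mixreg_model <- function(x, ...) {
  cat(sprintf("Mixture regression model with K = %d components\n", x$K))
  for (k in seq_len(x$K))
    cat(sprintf("  [%d] pi = %.3f, sigma = %.3f, support = {%s}\n", k,
                x$pi[k], x$sigma[k],
                paste(x$fits[[k]]$support, collapse = ", ")))
  invisible(x)
}

#' Posterior membership probabilities
#'
#' Posterior probability that each sample belongs to each mixture component,
#' proportional to `pi_k * dnorm(y_i, x_i' beta_k, sigma_k)`. Computed in
#' log space; rows sum to 1. If every component underflows for a sample the
#' row falls back to uniform with a warning.
#'
#' @param model a `"mixreg_model"`.
#' @param X n x p predictor matrix.
#' @param y length-n response.
#' @return n x K matrix of probabilities.
#' @export
posterior_membership <- function(model, X, y) {
  stopifnot(inherits(model, "mixreg_model"))
  n <- nrow(X)
  K <- model$K
  logd <- matrix(0, n, K)
  for (k in seq_len(K)) {
    mu <- fitted_mean(model$fits[[k]], X)
    logd[, k] <- log(model$pi[k]) + dnorm(y, mu, model$sigma[k], log = TRUE)
  }
  bad <- !is.finite(apply(logd, 1L, max))
  if (any(bad)) {
    warning(sum(bad), " sample(s) underflowed in every component; ",
            "using uniform membership")
    logd[bad, ] <- 0
  }
  P <- exp(logd - logsumexp_rows(logd))
  P / rowSums(P)
}

#' Stochastically impute memberships
#'
#' One categorical draw per sample from its row of membership probabilities
#' (the I-step). Uses the current RNG state, so results are reproducible
#' under `set.seed()`.
#'
#' @param probs n x K matrix with probability rows.
#' @return Integer label vector in 1..K.
#' @export
impute_memberships <- function(probs) {
  n <- nrow(probs)
  cp <- probs %*% upper.tri(diag(ncol(probs)), diag = TRUE)
  u <- runif(n)
  lab <- rowSums(u > cp) + 1L
  as.integer(pmin(lab, ncol(probs)))
}

#' Re-estimate one mixture component from its imputed members
#'
#' The CC-step for one component: the mixing proportion is the member count
#' over n, the coefficients come from [sis_mcp()] on the member rows, and the
#' residual standard deviation is `sqrt(RSS / (m - s - 1))` with `m` members
#' and `s` selected slopes. When the denominator is nonpositive it is
#' replaced by 1, and sigma is floored at `sigma_floor` so a perfectly
#' fitting component cannot become an absorbing state. Components smaller
#' than `min_size` get an intercept-only fit (no variables selected).
#'
#' @param X,y full data.
#' @param members integer row indices belonging to this component.
#' @param n_total total sample size n (denominator of the proportion).
#' @param min_size minimum member count for a full SIS-MCP fit.
#' @param sigma_floor lower bound on sigma.
#' @param ... passed to [sis_mcp()].
#' @return List with `pi`, `fit` (a `"sparse_fit"`), `sigma`.
#' @export
update_component <- function(X, y, members, n_total = nrow(X),
                             min_size = 10L, sigma_floor = 1e-4, ...) {
  m <- length(members)
  if (m == 0L) stop("cannot update a component with no members")
  ym <- y[members]
  Xm <- X[members, , drop = FALSE]
  if (m >= min_size) {
    fit <- sis_mcp(Xm, ym, ...)
  } else {
    fit <- new_sparse_fit(intercept = mean(ym), coef = numeric(0),
                          support = integer(0), screened = integer(0),
                          lambda = NA_real_, converged = TRUE, n = m)
  }
  rss <- sum((ym - fitted_mean(fit, Xm))^2)
  denom <- m - length(fit$support) - 1L
  if (denom <= 0L) denom <- 1L
  sigma <- max(sqrt(rss / denom), sigma_floor)
  list(pi = m / n_total, fit = fit, sigma = sigma)
}

model_df <- function(model) {
  # slopes + intercept + sigma per component, plus free mixing proportions
  sum(vapply(model$fits, function(f) length(f$support), 0)) +
    2 * model$K + (model$K - 1)
}

# Complete-data BIC given a partition and the component models:
# -2 * sum_k sum_{i in comp k} log phi(y_i | mu_ik, sigma_k^2) + df * log(n).
complete_data_bic <- function(model, X, y, tau) {
  n <- length(y)
  ll <- 0
  for (k in seq_len(model$K)) {
    idx <- which(tau == k)
    if (!length(idx)) next
    mu <- fitted_mean(model$fits[[k]], X[idx, , drop = FALSE])
    ll <- ll + sum(dnorm(y[idx], mu, model$sigma[k], log = TRUE))
  }
  -2 * ll + model_df(model) * log(n)
}

# Observed-data BIC: -2 * mixture log-likelihood + df * log(n).
mixture_bic <- function(model, X, y) {
  n <- length(y)
  logd <- matrix(0, n, model$K)
  for (k in seq_len(model$K)) {
    mu <- fitted_mean(model$fits[[k]], X)
    logd[, k] <- log(model$pi[k]) + dnorm(y, mu, model$sigma[k], log = TRUE)
  }
  -2 * sum(logsumexp_rows(logd)) + model_df(model) * log(n)
}

#' Run the imputation-conditional consistency chain
#'
#' Alternates stochastic imputation of cluster memberships from their
#' posterior (I-step) with component-wise re-estimation of the mixing
#' proportions, SIS-MCP coefficients and residual standard deviations
#' (CC-step), starting from a uniformly random partition. Each iteration
#' records the imputed labels, the fitted model and the complete-data BIC.
#' `K = 1` short-circuits to a single SIS-MCP fit (one iteration).
#'
#' During burn-in, a component whose imputed membership falls below
#' `restart_size` (default `max(min_size, ceiling(n / (4K)))`) is re-seeded
#' by a split move: it receives a random half of the largest cluster's
#' members. Without this, a gradually shrinking component either
#' degenerates into a near-zero-variance "spike" or silently dies, wedging
#' the chain in a local mode where two true components stay merged; the
#' split re-seed puts the dying component on equal prior footing with the
#' dominant (typically merged) cluster and confines the competition to that
#' pool, while the burn-in iterations it perturbs are discarded anyway.
#' After burn-in no re-seeding happens, so genuinely small stable clusters
#' can persist into the inference window. The number of re-seeds is
#' recorded as `restarts` on the trace.
#'
#' If a component receives no members at a post-burn-in iteration it keeps
#' its previous parameters and its mixing proportion is floored at `1/n` for
#' the next I-step; a component empty for more than `max_empty` consecutive
#' iterations aborts the run with a suggestion to reduce K.
#'
#' @param X n x p predictor matrix.
#' @param y length-n response.
#' All within-chain component fits select their penalty level by the
#' classical BIC (`chain_ebic_gamma = 0`): the chain's fits are an
#' imputation engine, and a mildly liberal selection there helps the
#' components differentiate early on; the conservative extended-BIC
#' correction belongs to the final clusterwise selection
#' ([clusterwise_select()]), not to the chain.
#'
#' @param K number of components.
#' @param iters total iterations T.
#' @param burn_in burn-in iterations t0 (`0 <= burn_in < iters`); stored on
#'   the trace and used by downstream summaries.
#' @param seed optional integer seed; equal seeds give identical traces.
#' @param min_size,sigma_floor see [update_component()].
#' @param max_empty abort threshold for consecutive empty iterations.
#' @param restart_size burn-in re-seeding trigger; see Details.
#' @param chain_ebic_gamma extended-BIC weight for the within-chain fits.
#' @param bic_type per-iteration BIC flavor recorded on the trace (and thus
#'   driving [average_bic()] and [select_K()]): `"mixture"` (default) uses
#'   the observed-data mixture log-likelihood, `"complete"` conditions on
#'   the imputed partition. See [select_K()] for why the mixture form is
#'   the default.
#' @param ... passed to [sis_mcp()].
#' @return Object of class `"icc_trace"`: `memberships` (iters x n integer
#'   matrix), `models` (list of `"mixreg_model"`), `bic` (numeric vector),
#'   `K`, `iters`, `burn_in`, `n`, `seed`.
#' @export
run_icc <- function(X, y, K, iters = 500L, burn_in = 100L, seed = NULL,
                    min_size = 10L, sigma_floor = 1e-4, max_empty = 20L,
                    restart_size = NULL, chain_ebic_gamma = 0,
                    bic_type = c("mixture", "complete"), ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  bic_type <- match.arg(bic_type)
  bic_fun <- function(model, tau)
    if (bic_type == "mixture") mixture_bic(model, X, y)
    else complete_data_bic(model, X, y, tau)
  stopifnot(K >= 1L, length(y) == n)
  if (!is.null(seed)) set.seed(seed)

  if (K == 1L) {
    comp <- update_component(X, y, seq_len(n), n, min_size = min_size,
                             sigma_floor = sigma_floor,
                             ebic_gamma = chain_ebic_gamma, ...)
    model <- mixreg_model(1, list(comp$fit), comp$sigma)
    tau <- rep(1L, n)
    return(structure(list(memberships = matrix(tau, 1L, n),
                          models = list(model),
                          bic = bic_fun(model, tau),
                          K = 1L, iters = 1L, burn_in = 0L, n = n,
                          seed = seed, restarts = 0L),
                     class = "icc_trace"))
  }
  stopifnot(iters > burn_in, burn_in >= 0L)
  restart_size <- restart_size %||% max(min_size, ceiling(n / (4 * K)))

  memberships <- matrix(0L, iters, n)
  models <- vector("list", iters)
  bics <- numeric(iters)
  empty_run <- integer(K)
  model <- NULL
  restarts <- 0L

  for (t in seq_len(iters)) {
    tau <- if (t == 1L) sample.int(K, n, replace = TRUE)
           else impute_memberships(posterior_membership(model, X, y))

    if (t <= burn_in) {
      counts <- tabulate(tau, K)
      for (k in which(counts < restart_size)) {
        # split move: hand the dying component a random half of the largest
        # cluster, so the two compete on equal prior footing
        big <- which(tau == which.max(tabulate(tau, K)))
        tau[sample(big, length(big) %/% 2L)] <- k
        restarts <- restarts + 1L
      }
    }

    pi <- numeric(K)
    fits <- vector("list", K)
    sigma <- numeric(K)
    for (k in seq_len(K)) {
      members <- which(tau == k)
      if (!length(members)) {
        empty_run[k] <- empty_run[k] + 1L
        if (empty_run[k] > max_empty)
          stop("component ", k, " stayed empty for more than ", max_empty,
               " consecutive iterations; consider a smaller K")
        if (is.null(model))
          stop("empty component at initialization; n too small for K = ", K)
        pi[k] <- 0
        fits[[k]] <- model$fits[[k]]
        sigma[k] <- model$sigma[k]
      } else {
        empty_run[k] <- 0L
        comp <- update_component(X, y, members, n, min_size = min_size,
                                 sigma_floor = sigma_floor,
                                 ebic_gamma = chain_ebic_gamma, ...)
        pi[k] <- comp$pi
        fits[[k]] <- comp$fit
        sigma[k] <- comp$sigma
      }
    }
    # floor empty components' proportions for the next I-step only
    pi_use <- pmax(pi, ifelse(pi == 0, 1 / n, 0))
    model <- mixreg_model(pi_use / sum(pi_use), fits, sigma)
    memberships[t, ] <- tau
    models[[t]] <- mixreg_model(pi / sum(pi), fits, sigma)
    bics[t] <- bic_fun(models[[t]], tau)
  }

  structure(list(memberships = memberships, models = models, bic = bics,
                 K = K, iters = iters, burn_in = burn_in, n = n, seed = seed,
                 restarts = restarts),
            class = "icc_trace")
}

#' @export
print.icc_trace <- function(x, ...) {
  cat(sprintf("ICC trace: K = %d, %d iterations (burn-in %d), n = %d\n",
              x$K, x$iters, x$burn_in, x$n))
  if (x$iters > x$burn_in)
    cat(sprintf("  average BIC over post-burn-in window: %.2f\n",
                mean(x$bic[(x$burn_in + 1):x$iters])))
  invisible(x)
}

#' Post-burn-in average of the chain's parameter estimates
#'
#' Relabels every post-burn-in model to the final iteration's component order
#' (the permutation minimizing summed L2 distance between coefficient
#' vectors) and averages the dense coefficient vectors, sigmas and mixing
#' proportions across iterations.
#'
#' @param trace an `"icc_trace"`.
#' @param p original feature dimension.
#' @return List with `beta` (a (p+1) x K matrix of averaged coefficients,
#'   intercept first), `sigma`, `pi`.
#' @export
average_model <- function(trace, p) {
  stopifnot(inherits(trace, "icc_trace"))
  win <- (trace$burn_in + 1):trace$iters
  ref <- lapply(trace$models[[trace$iters]]$fits, dense_beta, p = p)
  K <- trace$K
  beta_sum <- matrix(0, p + 1L, K)
  sigma_sum <- numeric(K)
  pi_sum <- numeric(K)
  for (t in win) {
    m <- trace$models[[t]]
    bt <- lapply(m$fits, dense_beta, p = p)
    perm <- match_components(bt, ref)
    for (k in seq_len(K)) {
      beta_sum[, k] <- beta_sum[, k] + bt[[perm[k]]]
      sigma_sum[k] <- sigma_sum[k] + m$sigma[perm[k]]
      pi_sum[k] <- pi_sum[k] + m$pi[perm[k]]
    }
  }
  w <- length(win)
  list(beta = beta_sum / w, sigma = sigma_sum / w, pi = pi_sum / w)
}
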