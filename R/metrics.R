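#' False and negative selection rates
#'
#' `fsr = FP / (TP + FP)` and `nsr = FN / (TP + FN)` from binary decision
#' counts. Degenerate denominators yield 0 with a `"degenerate"` attribute
#' flag rather than `NaN`.
#'
#' @param tp,fp,fn nonnegative true-positive, false-positive and
#'   false-negative counts.
#' @return Named numeric vector `c(fsr, nsr)`.
#' @export
fsr_nsr <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  deg <- c(fsr = tp + fp == 0, nsr = tp + fn == 0)
  out <- c(fsr = if (deg[["fsr"]]) 0 else fp / (tp + fp),
           nsr = if (deg[["nsr"]]) 0 else fn / (tp + fn))
  if (any(deg)) attr(out, "degenerate") <- names(deg)[deg]
  out
}

#' L2 estimation error between coefficient vectors
#'
#' @param beta_hat,beta_true numeric vectors of equal length (dense,
#'   intercept included).
#' @return Euclidean norm of the difference.
#' @export
estimation_error <- function(beta_hat, beta_true) {
  stopifnot(length(beta_hat) == length(beta_true))
  sqrt(sum((beta_hat - beta_true)^2))
}

#' Match estimated components to true components
#'
#' Exhaustive search over all K! permutations for the assignment of
#' estimated components to true components minimizing the summed L2 distance
#' between coefficient vectors — the relabeling step needed before any
#' per-component comparison (mixture labels are exchangeable).
#'
#' @param estimated,truth lists of K dense coefficient vectors (equal
#'   lengths), or two `"mixreg_model"`s plus `p`.
#' @param p feature dimension, required when models are passed.
#' @return Integer permutation `perm` with `perm[k]` the estimated component
#'   matched to true component `k`.
#' @export
match_components <- function(estimated, truth, p = NULL) {
  if (inherits(estimated, "mixreg_model"))
    estimated <- lapply(estimated$fits, dense_beta, p = p)
  if (inherits(truth, "mixreg_model"))
    truth <- lapply(truth$fits, dense_beta, p = p)
  K <- length(truth)
  if (length(estimated) != K)
    stop("component counts differ (", length(estimated), " vs ", K, ")")
  if (K > 6L) stop("exhaustive matching supported for K <= 6")
  cost <- outer(seq_len(K), seq_len(K),
                Vectorize(function(k, j) estimation_error(estimated[[j]],
                                                          truth[[k]])))
  best <- NULL
  best_cost <- Inf
  for (perm in all_permutations(K)) {
    cc <- sum(cost[cbind(seq_len(K), perm)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- perm
    }
  }
  as.integer(best)
}

#' Per-component variable-selection metrics against a known truth
#'
#' After matching estimated components to the true ones by coefficient
#' distance, compares each selected support with the true support and
#' reports TP/FP/FN counts, fsr/nsr and the L2 coefficient estimation error.
#'
#' @param model fitted `"mixreg_model"`.
#' @param truth `truth` element of a [simulate_mixreg()] dataset (or a
#'   `sim_config`).
#' @param p feature dimension.
#' @return data.frame with one row per true component.
#' @export
selection_metrics <- function(model, truth, p) {
  true_betas <- lapply(seq_along(truth$beta), function(k)
    true_beta(truth, k, p = p))
  perm <- match_components(lapply(model$fits, dense_beta, p = p), true_betas)
  K <- length(true_betas)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- model$fits[[perm[k]]]
    ts <- truth$beta[[k]]$index
    tp <- length(intersect(fit$support, ts))
    fp <- length(setdiff(fit$support, ts))
    fn <- length(setdiff(ts, fit$support))
    rates <- fsr_nsr(tp, fp, fn)
    out[[k]] <- data.frame(component = k, matched = perm[k], tp = tp,
                           fp = fp, fn = fn, fsr = rates[["fsr"]],
                           nsr = rates[["nsr"]],
                           l2_error = estimation_error(
                             dense_beta(fit, p), true_betas[[k]]))
  }
  do.call(rbind, out)
}

#' Per-component clustering metrics against true memberships
#'
#' Treats each sample's assignment as a binary decision per true component
#' k: with estimated clusters aligned to true components by `perm`,
#' `TP = |est_k intersect true_k|`, `FP = |est_k \ true_k|`,
#' `FN = |true_k \ est_k|`, and fsr/nsr follow.
#'
#' @param labels estimated cluster labels.
#' @param tau true memberships.
#' @param perm permutation aligning clusters to true components, typically
#'   from [match_components()]; identity by default.
#' @return data.frame with one row per true component.
#' @export
clustering_metrics <- function(labels, tau, perm = seq_len(max(tau))) {
  K <- max(tau)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    est_k <- which(labels == perm[k])
    true_k <- which(tau == k)
    tp <- length(intersect(est_k, true_k))
    fp <- length(setdiff(est_k, true_k))
    fn <- length(setdiff(true_k, est_k))
    rates <- fsr_nsr(tp, fp, fn)
    out[[k]] <- data.frame(component = k, tp = tp, fp = fp, fn = fn,
                           fsr = rates[["fsr"]], nsr = rates[["nsr"]])
  }
  do.call(rbind, out)
}

#' Predict responses for new samples from a mixture regression model
#'
#' Three prediction modes are exposed and the report names the one used:
#' \describe{
#'   \item{`"posterior"`}{assign each new sample to the component maximizing
#'     its membership posterior evaluated *with the observed test response*,
#'     then predict from that component's regression. This is the rule used
#'     by the drug-sensitivity application; note it reads the test response
#'     during cluster assignment, so it measures conditional fit rather than
#'     pure out-of-sample prediction. Requires `y`.}
#'   \item{`"mixture"`}{the posterior-free mixture mean
#'     `sum_k pi_k (b_k0 + x' b_k)`.}
#'   \item{`"prior"`}{predict from the single component with the largest
#'     mixing proportion.}
#' }
#'
#' @param object a `"mixreg_model"`.
#' @param X matrix of new samples.
#' @param y optional observed responses (required for `mode = "posterior"`;
#'   used for the accuracy summaries otherwise).
#' @param mode prediction mode, see Details.
#' @param ... ignored.
#' @return Object of class `"prediction_report"`: `yhat`, `cluster` (NA for
#'   `"mixture"`), `corr`, `rmse` (NA without `y`), `mode`.
#' @export
predict.mixreg_model <- function(object, X, y = NULL,
                                 mode = c("posterior", "mixture", "prior"),
                                 ...) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- vapply(object$fits, function(f) fitted_mean(f, X), numeric(n))
  mu <- matrix(mu, n, object$K)
  cluster <- rep(NA_integer_, n)
  if (mode == "posterior") {
    if (is.null(y))
      stop("mode = \"posterior\" assigns clusters with the observed ",
           "response; supply y or use \"mixture\"/\"prior\"")
    P <- posterior_membership(object, X, y)
    cluster <- max.col(P, ties.method = "first")
    yhat <- mu[cbind(seq_len(n), cluster)]
  } else if (mode == "mixture") {
    yhat <- as.vector(mu %*% object$pi)
  } else {
    cluster <- rep(which.max(object$pi), n)
    yhat <- mu[, cluster[1L]]
  }
  corr <- rmse <- NA_real_
  if (!is.null(y)) {
    corr <- if (sd(yhat) > 0 && sd(y) > 0) cor(y, yhat) else NA_real_
    rmse <- sqrt(mean((y - yhat)^2))
  }
  structure(list(yhat = yhat, cluster = cluster, corr = corr, rmse = rmse,
                 mode = mode),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Prediction report (mode = %s, n = %d)\n", x$mode,
              length(x$yhat)))
  if (!is.na(x$corr))
    cat(sprintf("  corr(Y, Yhat) = %.3f, RMSE = %.3f\n", x$corr, x$rmse))
  invisible(x)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, odd and strictly increasing on
#' (-1, 1); approximately normal with standard deviation `1/sqrt(N - 3)` for
#' a correlation computed from N samples.
#'
#' @param r correlation value(s) with `|r| < 1`.
#' @return z-score(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be strictly less than 1")
  0.5 * log((1 + r) / (1 - r))
}

#' Paired comparison of two methods' prediction correlations
#'
#' Transforms both correlation lists to Fisher z-scores and runs a two-sided
#' paired t-test on the per-item differences. When all differences are
#' (numerically) zero the p-value is 1 by convention.
#'
#' @param r_a,r_b aligned correlation vectors for the two methods.
#' @param n optional aligned sample sizes (kept for reporting; the paired
#'   t-test itself uses only the z differences).
#' @return List with `p.value`, `statistic`, `mean_diff` (mean z
#'   difference), `n_pairs`.
#' @export
paired_z_test <- function(r_a, r_b, n = NULL) {
  stopifnot(length(r_a) == length(r_b))
  dz <- fisher_z(r_a) - fisher_z(r_b)
  if (all(abs(dz - mean(dz)) < 1e-12)) {
    p <- if (abs(mean(dz)) < 1e-12) 1 else 0
    return(list(p.value = p, statistic = NA_real_, mean_diff = mean(dz),
                n_pairs = length(dz)))
  }
  tt <- t.test(dz)
  list(p.value = tt$p.value, statistic = unname(tt$statistic),
       mean_diff = mean(dz), n_pairs = length(dz))
}
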