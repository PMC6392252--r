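#' Co-clustering dissimilarity matrix
#'
#' For every sample pair (i, j), the number of post-burn-in iterations at
#' which the chain assigned them to different clusters:
#' `d_ij = (T - t0) - #{t > t0 : tau_i^(t) = tau_j^(t)}`. The matrix is
#' symmetric with zero diagonal and entries in `[0, T - t0]`, and depends
#' only on co-assignment, so it is invariant to relabeling components within
#' iterations.
#'
#' @param trace an `"icc_trace"`.
#' @param burn_in burn-in override; defaults to the trace's own.
#' @return n x n numeric matrix with attribute `window = c(t0, T)`.
#' @export
dissimilarity_matrix <- function(trace, burn_in = trace$burn_in) {
  stopifnot(inherits(trace, "icc_trace"))
  W <- trace$iters - burn_in
  if (W < 1L) stop("empty post-burn-in window")
  M <- trace$memberships[(burn_in + 1):trace$iters, , drop = FALSE]
  n <- ncol(M)
  K <- max(trace$K, max(M))
  # co-assignment counts via an n x (W*K) stacked indicator matrix
  A <- matrix(0, n, W * K)
  for (t in seq_len(W))
    A[cbind(seq_len(n), (t - 1L) * K + M[t, ])] <- 1
  D <- W - tcrossprod(A)
  diag(D) <- 0
  attr(D, "window") <- c(burn_in, trace$iters)
  D
}

#' Consensus clustering of the dissimilarity matrix
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' co-clustering dissimilarity, cut at K clusters. Deterministic given D.
#'
#' @param D n x n dissimilarity matrix from [dissimilarity_matrix()].
#' @param K number of clusters (`1 <= K <= n`).
#' @return Integer label vector (1..K) with the `"hclust"` tree attached as
#'   attribute `"tree"`.
#' @export
consensus_cluster <- function(D, K) {
  n <- nrow(D)
  if (K > n) stop("K cannot exceed the number of samples")
  if (K == 1L) {
    lab <- rep(1L, n)
  } else {
    tree <- hclust(as.dist(D), method = "average")
    lab <- cutree(tree, k = K)
    attr(lab, "tree") <- tree
  }
  lab
}

#' Clusterwise variable selection on a fixed partition
#'
#' Fits SIS-MCP independently within each cluster of the final consensus
#' partition and assembles the resulting mixture model: mixing proportions
#' from cluster sizes, coefficients from the per-cluster sparse fits, and
#' residual standard deviations from the within-cluster residuals. Clusters
#' below `min_size` get intercept-only fits (no variables selected).
#'
#' @param X,y data.
#' @param labels integer cluster labels (1..K).
#' @param min_size,sigma_floor see [update_component()].
#' @param ... passed to [sis_mcp()].
#' @return A `"mixreg_model"` with attributes `labels` and `sizes`.
#' @export
clusterwise_select <- function(X, y, labels, min_size = 10L,
                               sigma_floor = 1e-4, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  K <- max(labels)
  pi <- numeric(K)
  fits <- vector("list", K)
  sigma <- numeric(K)
  for (k in seq_len(K)) {
    members <- which(labels == k)
    if (!length(members)) stop("cluster ", k, " is empty")
    comp <- update_component(X, y, members, n, min_size = min_size,
                             sigma_floor = sigma_floor, ...)
    pi[k] <- comp$pi
    fits[[k]] <- comp$fit
    sigma[k] <- comp$sigma
  }
  model <- mixreg_model(pi, fits, sigma)
  attr(model, "labels") <- as.integer(labels)
  attr(model, "sizes") <- tabulate(labels, K)
  model
}
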