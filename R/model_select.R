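#' Average BIC of an ICC chain
#'
#' Arithmetic mean of the per-iteration complete-data BIC values over the
#' post-burn-in window `burn_in + 1 .. iters` (divided by the number of
#' summed terms).
#'
#' @param trace an `"icc_trace"`.
#' @param burn_in burn-in override; defaults to the trace's own.
#' @return Scalar average BIC.
#' @export
average_bic <- function(trace, burn_in = trace$burn_in) {
  stopifnot(inherits(trace, "icc_trace"))
  if (burn_in >= trace$iters) stop("empty post-burn-in window")
  mean(trace$bic[(burn_in + 1):trace$iters])
}

#' Select the number of mixture components by average BIC
#'
#' Runs an independent ICC chain for every candidate K (with deterministic
#' sub-seeds derived from `seed`, so the whole selection is reproducible from
#' one seed and invariant to the order of candidates) and picks the K with
#' the smallest average BIC. `K = 1` entries use the BIC of the single
#' SIS-MCP fit. Ties prefer the smallest K (parsimony). A failure for one
#' candidate is recorded in the report, not fatal, unless every candidate
#' fails.
#'
#' @param X,y data.
#' @param K_grid integer vector of candidate component counts.
#' @param iters,burn_in chain length and burn-in per candidate.
#' @param seed master seed.
#' @param ... passed to [run_icc()].
#' @return Object of class `"k_selection"`: `table` (data.frame with K,
#'   average BIC and its Monte-Carlo standard error), `selected`, `traces`.
#' @export
select_K <- function(X, y, K_grid, iters = 500L, burn_in = 100L,
                     seed = NULL, ...) {
  stopifnot(length(K_grid) >= 1L)
  traces <- lapply(seq_along(K_grid), function(i) {
    s <- if (is.null(seed)) NULL else sub_seed(seed, K_grid[i])
    tryCatch(run_icc(X, y, K_grid[i], iters = iters, burn_in = burn_in,
                     seed = s, ...),
             error = function(e) e)
  })
  ok <- vapply(traces, inherits, TRUE, what = "icc_trace")
  if (!any(ok)) stop("every candidate K failed: ",
                     conditionMessage(traces[[1L]]))
  avg <- se <- rep(NA_real_, length(K_grid))
  for (i in which(ok)) {
    tr <- traces[[i]]
    w <- tr$bic[(tr$burn_in + 1):tr$iters]
    avg[i] <- mean(w)
    se[i] <- if (length(w) > 1L) sd(w) / sqrt(length(w)) else 0
  }
  minimizers <- K_grid[which(avg == min(avg, na.rm = TRUE))]
  structure(list(table = data.frame(K = K_grid, avg_bic = avg, se = se,
                                    ok = ok),
                 selected = min(minimizers), traces = traces),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Average-BIC selection of the number of components\n")
  print(x$table, row.names = FALSE)
  cat("selected K =", x$selected, "\n")
  invisible(x)
}

#' Plot BIC paths of the candidate chains
#'
#' One panel per candidate K showing the per-iteration BIC along the chain,
#' the standard convergence diagnostic for the ICC run.
#'
#' @param x a `"k_selection"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.k_selection <- function(x, ...) {
  ok <- which(x$table$ok)
  oldpar <- graphics::par(mfrow = c(1, length(ok)))
  on.exit(graphics::par(oldpar))
  for (i in ok) {
    tr <- x$traces[[i]]
    graphics::plot(tr$bic, type = "l", xlab = "iteration", ylab = "BIC",
                   main = paste0("K = ", x$table$K[i]), ...)
    if (tr$burn_in > 0) graphics::abline(v = tr$burn_in, lty = 2)
  }
  invisible(x)
}
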