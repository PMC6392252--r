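# Small simulation designs reused across tests.

# two well-separated components, modest dimension: fast end-to-end runs
small_design <- function() sim_config(c(60L, 60L), p = 100L)

# the reduced-dimension three-component design used for model selection
comparison_design <- function() sim_config(p = 200L)

# single-component sparse regression design
single_design <- function(n = 200L, p = 500L)
  sim_config(n_per_component = n, p = p)

# hand-built trace object for consensus/selection unit tests
fake_trace <- function(memberships, burn_in = 0L, bic = NULL, K = NULL) {
  memberships <- as.matrix(memberships)
  structure(list(memberships = memberships, models = NULL,
                 bic = bic %||% numeric(nrow(memberships)),
                 K = K %||% max(memberships), iters = nrow(memberships),
                 burn_in = burn_in, n = ncol(memberships), seed = NULL),
            class = "icc_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
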