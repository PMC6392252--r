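# Internal helpers shared across modules.

# Row-wise log-sum-exp, guarding against -Inf rows.
logsumexp_rows <- function(M) {
  m <- apply(M, 1L, max)
  bad <- !is.finite(m)
  if (any(bad)) m[bad] <- 0
  m + log(rowSums(exp(M - m)))
}

# Deterministic sub-seed derivation so independent stages draw from
# independent streams reproducible from one master seed. Kept below 2^31.
sub_seed <- function(seed, index) {
  ((as.numeric(seed) %% 104729) * 15485863 + index * 7919) %% 2147483629
}

# All permutations of 1..k as a list of integer vectors (k <= 6 in practice).
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
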