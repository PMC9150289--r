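# internal helpers shared across modules

# Deterministic substream seed derived from a global seed and an operation id.
# Kept below 2^31 - 1 so set.seed() always accepts it.
sub_seed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + id * 16807) %% 2147483629)
}

# permutation p with add-one correction: p = (1 + #null >= obs) / (1 + n_perm)
perm_pvalue <- function(n_ge, n_perm) {
  (1 + n_ge) / (1 + n_perm)
}

# count, for each element of obs, how many values in null are >= it
count_ge <- function(obs, null_sorted) {
  length(null_sorted) - findInterval(obs, null_sorted, left.open = TRUE)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
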