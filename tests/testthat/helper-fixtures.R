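# Shared fixtures built in code at test time.

one_chr_map <- function(m, spacing = 10L) {
  data.frame(marker_id = paste0("m", seq_len(m)), chromosome = "chr1",
             position = seq_len(m) * spacing, stringsAsFactors = FALSE)
}

# tiny cohort with a planted survival signature: `frac_sig` of the genes
# load on a latent factor that also drives the hazard
planted_survival_cohort <- function(n = 60, n_genes = 100, n_sig = 10,
                                    effect = 1, cens = 0.3, seed = 1) {
  set.seed(seed)
  factor_score <- rnorm(n)
  expr <- matrix(rnorm(n_genes * n, 0, 1), n_genes, n,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 paste0("S", seq_len(n))))
  sig <- seq_len(n_sig)
  expr[sig, ] <- expr[sig, ] + rep(factor_score, each = n_sig)
  rate <- 0.05 * exp(effect * factor_score)
  t_event <- rexp(n, rate)
  if (cens > 0) {
    cc <- uniroot(function(c) mean(pmin(t_event, c) / c) - cens,
                  c(1e-6, max(t_event) * 5), extendInt = "downX")$root
    cv <- runif(n, 0, cc)
    outcome <- data.frame(sample_id = colnames(expr),
                          time = pmin(t_event, cv),
                          event = as.integer(t_event <= cv))
  } else {
    outcome <- data.frame(sample_id = colnames(expr), time = t_event,
                          event = 1L)
  }
  list(expr = expr, outcome = outcome, signature = rownames(expr)[sig],
       score = factor_score)
}

# two-class expression with a planted mean shift on the first n_de genes
planted_binary_dataset <- function(n_per = 20, n_genes = 60, n_de = 10,
                                   effect = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  labels <- rep(c(0L, 1L), each = n_per)
  expr <- matrix(rnorm(n_genes * n), n_genes, n,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 paste0("S", seq_len(n))))
  expr[seq_len(n_de), labels == 1L] <-
    expr[seq_len(n_de), labels == 1L] + effect
  list(expr = expr, labels = labels)
}
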