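#' Reduce a probe-level expression matrix to gene level by IQR
#'
#' For each gene symbol, the probe with the largest interquartile range
#' across samples is kept (ties broken by the lexicographically smallest
#' probe id). Probes with no mapping are dropped; their count is recorded in
#' the `n_unmapped` attribute.
#'
#' @param expr probes x samples numeric matrix with probe ids as rownames.
#' @param probe_to_gene named character vector mapping probe id -> gene
#'   symbol.
#' @return gene-level matrix (gene symbols as rownames) with attributes
#'   `n_unmapped` and `probe_used` (named by gene).
#' @export
reduce_probes <- function(expr, probe_to_gene) {
  if (length(probe_to_gene) == 0L)
    stop("empty probe-to-gene map", call. = FALSE)
  probes <- rownames(expr)
  gene <- unname(probe_to_gene[probes])
  unmapped <- is.na(gene)
  n_unmapped <- sum(unmapped)
  keep <- which(!unmapped)
  iqr <- apply(expr[keep, , drop = FALSE], 1, stats::IQR)
  ord <- keep[order(gene[keep], -iqr, probes[keep])]
  first <- ord[!duplicated(gene[ord])]
  out <- expr[first, , drop = FALSE]
  rownames(out) <- gene[first]
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "probe_used") <- stats::setNames(probes[first], gene[first])
  out
}

#' Median-center an expression matrix gene-wise
#'
#' Subtracts each gene's median across samples, guarding against bias from
#' extreme intensities when datasets are later combined. Idempotent.
#'
#' @param expr gene-level matrix (genes x samples).
#' @return centered matrix with attribute `centered = TRUE`.
#' @export
median_center <- function(expr) {
  med <- apply(expr, 1, stats::median)
  out <- expr - med
  attr(out, "centered") <- TRUE
  out
}

#' Per-gene Spearman concurrency between copy number and expression
#'
#' For every gene present in both matrices, the midrank-tie Spearman
#' correlation between its gene-centric copy-number values and its
#' expression over shared samples, with a two-sided p from the t
#' approximation on n - 2 degrees of freedom. Genes with fewer than
#' `min_n` complete pairs or constant input are flagged undefined.
#'
#' @param gene_cnv genes x samples matrix of gene-centric copy number.
#' @param gene_expr genes x samples expression matrix (gene-level).
#' @param min_n minimum complete pairs (default 4).
#' @return data.frame: gene, r, n, p, defined (logical).
#' @export
spearman_per_gene <- function(gene_cnv, gene_expr, min_n = 4L) {
  genes <- intersect(rownames(gene_cnv), rownames(gene_expr))
  samples <- intersect(colnames(gene_cnv), colnames(gene_expr))
  out <- data.frame(gene = genes, r = NA_real_, n = NA_integer_,
                    p = NA_real_, defined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    x <- gene_cnv[genes[i], samples]
    y <- gene_expr[genes[i], samples]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    out$n[i] <- n
    if (n < min_n) next
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y, method = "spearman")
    out$r[i] <- r
    if (abs(r) >= 1) {
      out$p[i] <- 0
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      out$p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    out$defined[i] <- TRUE
  }
  out
}

#' Fisher's z transformation of a correlation
#'
#' `z = arctanh(r) = 0.5 * log((1 + r) / (1 - r))`, approximately normal
#' with variance `1/(n - 3)`.
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) >= 1))
    stop("|r| must be < 1 for Fisher's z", call. = FALSE)
  atanh(r)
}

#' Combine two cohorts' correlations via weighted Fisher's z
#'
#' `Zbar = ((n1-3) z1 + (n2-3) z2) / (n1 + n2 - 6)`, `rbar = tanh(Zbar)`,
#' `V(Zbar) = 1/(n1 + n2 - 6)`; the two-sided combined p refers
#' `Zbar / sqrt(V(Zbar))` to the standard normal. Vectorized over genes.
#'
#' @param r1,n1 correlation and sample size of cohort 1 (n1 >= 4).
#' @param r2,n2 correlation and sample size of cohort 2 (n2 >= 4).
#' @return data.frame: z1, z2, z_bar, r_bar, var_z_bar, p_combined.
#' @export
combine_cohorts <- function(r1, n1, r2, n2) {
  if (any(n1 < 4) || any(n2 < 4))
    stop("both cohorts need n >= 4 (positive weight and variance)",
         call. = FALSE)
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  w <- n1 + n2 - 6
  z_bar <- ((n1 - 3) * z1 + (n2 - 3) * z2) / w
  var_z_bar <- 1 / w
  p <- 2 * stats::pnorm(-abs(z_bar / sqrt(var_z_bar)))
  data.frame(z1 = z1, z2 = z2, z_bar = z_bar, r_bar = tanh(z_bar),
             var_z_bar = var_z_bar, p_combined = p)
}

#' Filter genes by concurrency p-value
#'
#' Returns genes with `p < alpha`, preserving input order. Undefined
#' (NA) p-values never pass.
#'
#' @param stats_df data.frame with columns `gene` and a p-value column.
#' @param alpha significance level (conventional choices 0.05, 0.01,
#'   0.001).
#' @param p_col name of the p-value column.
#' @return character vector of passing genes.
#' @export
filter_concurrent <- function(stats_df, alpha, p_col = "p") {
  p <- stats_df[[p_col]]
  stats_df$gene[!is.na(p) & p < alpha]
}

#' Two-cohort concurrency table
#'
#' Runs [spearman_per_gene()] on each cohort, combines the per-gene
#' correlations with [combine_cohorts()], and flags the universal
#' concurrent set at `alpha`.
#'
#' @param cnv1,expr1 cohort 1 gene-centric CNV and expression matrices.
#' @param cnv2,expr2 cohort 2 matrices.
#' @param alpha combined-p threshold (default 0.001, the universal-set
#'   level).
#' @return data.frame: gene, r1, n1, p1, r2, n2, p2, z1, z2, z_bar, r_bar,
#'   var_z_bar, p_combined, pass.
#' @export
concurrency_table <- function(cnv1, expr1, cnv2, expr2, alpha = 0.001) {
  s1 <- spearman_per_gene(cnv1, expr1)
  s2 <- spearman_per_gene(cnv2, expr2)
  genes <- intersect(s1$gene[s1$defined], s2$gene[s2$defined])
  a <- s1[match(genes, s1$gene), ]
  b <- s2[match(genes, s2$gene), ]
  # a perfect rank correlation (possible at small n) sits on the boundary of
  # the z transform; nudge it to the largest representable correlation
  clamp <- function(r) pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  cmb <- combine_cohorts(clamp(a$r), a$n, clamp(b$r), b$n)
  out <- data.frame(gene = genes,
                    r1 = a$r, n1 = a$n, p1 = a$p,
                    r2 = b$r, n2 = b$n, p2 = b$p,
                    cmb,
                    stringsAsFactors = FALSE)
  out$pass <- out$p_combined < alpha
  rownames(out) <- NULL
  out
}
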