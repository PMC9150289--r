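#' Univariate Cox screening of genes against survival
#'
#' Proportional-hazards score test of each gene as a single continuous
#' covariate, vectorized over genes: at beta = 0 the score is
#' `U = sum over events of (x_i - mean of x over the risk set)` with
#' information `V` the summed risk-set variances; `chi2 = U^2 / V` on 1 df.
#' Tied event times share their risk set (Breslow handling; with continuous
#' times this coincides with Efron). A Wald test via [survival::coxph()]
#' (Efron ties) is available with `method = "wald"`.
#'
#' @param gene_values numeric vector (one gene) or genes x samples matrix.
#' @param outcome data.frame with `time` and `event` columns, samples in
#'   the same order as the columns of `gene_values`.
#' @param method `"score"` (default, vectorized) or `"wald"` (coxph).
#' @return data.frame: gene, statistic (chi-square 1 df), p, sign (sign of
#'   the estimated association), defined.
#' @export
cox_univariate <- function(gene_values, outcome, method = c("score", "wald")) {
  method <- match.arg(method)
  if (is.null(dim(gene_values)))
    gene_values <- matrix(gene_values, nrow = 1L,
                          dimnames = list("g1", NULL))
  if (sum(outcome$event) < 2L)
    stop("need at least 2 events", call. = FALSE)
  if (any(!is.finite(gene_values)))
    stop("gene values must be finite", call. = FALSE)
  G <- nrow(gene_values)
  genes <- rownames(gene_values)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  if (method == "wald") {
    stat <- p <- sgn <- rep(NA_real_, G)
    def <- rep(FALSE, G)
    for (g in seq_len(G)) {
      x <- gene_values[g, ]
      if (stats::sd(x) == 0) next
      f <- survival::coxph(survival::Surv(outcome$time, outcome$event) ~ x)
      s <- summary(f)
      stat[g] <- s$waldtest["test"]; p[g] <- s$waldtest["pvalue"]
      sgn[g] <- sign(stats::coef(f)); def[g] <- TRUE
    }
    return(data.frame(gene = genes, statistic = stat, p = p, sign = sgn,
                      defined = def, stringsAsFactors = FALSE))
  }
  n <- length(outcome$time)
  ord <- order(outcome$time)
  tm <- outcome$time[ord]; ev <- outcome$event[ord]
  X <- t(gene_values[, ord, drop = FALSE])        # n x G, time-ordered
  rc1 <- apply(X[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  rc2 <- apply(X[n:1, , drop = FALSE]^2, 2, cumsum)[n:1, , drop = FALSE]
  first <- match(tm, tm)                          # first index of tie group
  nr <- n - first + 1
  ei <- which(ev == 1)
  fi <- first[ei]
  mu <- rc1[fi, , drop = FALSE] / nr[ei]
  U <- colSums(X[ei, , drop = FALSE] - mu)
  V <- colSums(rc2[fi, , drop = FALSE] / nr[ei] - mu^2)
  stat <- U^2 / V
  def <- is.finite(stat) & V > 0
  stat[!def] <- NA_real_
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(gene = genes, statistic = stat, p = p,
             sign = ifelse(def, sign(U), NA_real_), defined = def,
             stringsAsFactors = FALSE)
}

#' Fit the supervised principal-component risk model
#'
#' Genes are screened by the univariate Cox score test at `alpha`; the
#' selected genes are standardized (mean 0, SD 1 over training samples) and
#' their first principal component — the "supergene" — gives the loading
#' vector (unit Euclidean norm). Each sample's prognostic index is the
#' loading-weighted sum of its standardized values; the loadings are
#' oriented so a larger index means larger estimated hazard. The high/low
#' risk threshold is the stated percentile of the training indices.
#'
#' @param expr genes x samples expression matrix (gene-level; median-center
#'   first when combining datasets).
#' @param outcome data.frame with `time`, `event` (and optionally
#'   `sample_id`) aligned to the columns of `expr`.
#' @param alpha Cox screening level (default 0.001).
#' @param percentile risk threshold percentile of training indices (50 or
#'   75 in common use).
#' @return an object of class `concur_risk_model` with components `genes`,
#'   `cox` (screening table for selected genes), `center`, `scale`,
#'   `loadings`, `orientation_sign`, `train_index` (named), `percentile`,
#'   `threshold`.
#' @export
fit_risk_model <- function(expr, outcome, alpha = 0.001, percentile = 50) {
  scr <- cox_univariate(expr, outcome)
  sel <- scr$defined & !is.na(scr$p) & scr$p < alpha
  if (!any(sel))
    stop("no gene passes the Cox filter at alpha = ", alpha, call. = FALSE)
  genes <- scr$gene[sel]
  Xs <- t(expr[genes, , drop = FALSE])            # samples x genes
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xs, 2, ctr), 2, scl, "/")
  sv <- svd(Xs, nu = 0, nv = 1)
  loadings <- sv$v[, 1]
  index <- drop(Xs %*% loadings)
  # orient so larger index => larger hazard (PC sign is arbitrary)
  u <- cox_univariate(matrix(index, 1, dimnames = list("pc1", NULL)), outcome)
  sgn <- if (!is.na(u$sign) && u$sign < 0) -1 else 1
  loadings <- sgn * loadings
  index <- sgn * index
  names(index) <- colnames(expr)
  thr <- stats::quantile(index, percentile / 100, names = FALSE)
  structure(list(
    genes = genes,
    cox = scr[sel, , drop = FALSE],
    center = ctr, scale = scl,
    loadings = stats::setNames(loadings, genes),
    orientation_sign = sgn,
    train_index = index,
    percentile = percentile,
    threshold = thr,
    alpha = alpha,
    n_train = ncol(expr)
  ), class = "concur_risk_model")
}

#' @export
print.concur_risk_model <- function(x, ...) {
  cat("Supervised principal-component risk model\n")
  cat(sprintf("  genes selected (Cox p < %g): %d\n", x$alpha,
              length(x$genes)))
  cat(sprintf("  training samples: %d\n", x$n_train))
  cat(sprintf("  risk threshold: %gth percentile of prognostic index (%.4f)\n",
              x$percentile, x$threshold))
  invisible(x)
}

#' @export
summary.concur_risk_model <- function(object, ...) {
  cat("Supervised principal-component risk model\n\n")
  print(object)
  cat("\nTop loadings (|loading|):\n")
  top <- utils::head(order(-abs(object$loadings)), 10L)
  print(round(object$loadings[top], 4))
  n_high <- sum(object$train_index > object$threshold)
  cat(sprintf("\nTraining risk groups: %d high / %d low\n",
              n_high, object$n_train - n_high))
  invisible(object)
}

#' @export
coef.concur_risk_model <- function(object, ...) object$loadings

#' Predict prognostic indices and risk groups for new samples
#'
#' Applies the training standardization and loadings to new expression.
#' Model genes absent from the new matrix are imputed at the training mean
#' (contributing zero after standardization); more than half missing is
#' refused. A sample is "high" risk iff its index strictly exceeds the
#' model threshold (ties go to "low").
#'
#' @param object a fitted `concur_risk_model`.
#' @param newdata genes x samples expression matrix.
#' @param ... unused.
#' @return data.frame: sample_id, prognostic_index, risk_label.
#' @export
predict.concur_risk_model <- function(object, newdata, ...) {
  genes <- object$genes
  have <- genes %in% rownames(newdata)
  if (mean(have) < 0.5)
    stop(sprintf("%d of %d model genes missing from new data",
                 sum(!have), length(genes)), call. = FALSE)
  ns <- ncol(newdata)
  Xs <- matrix(0, ns, length(genes))              # imputed rows stay 0
  Xs[, have] <- t(sweep(sweep(newdata[genes[have], , drop = FALSE], 1,
                              object$center[have]), 1,
                        object$scale[have], "/"))
  index <- drop(Xs %*% object$loadings)
  data.frame(sample_id = colnames(newdata),
             prognostic_index = index,
             risk_label = ifelse(index > object$threshold, "high", "low"),
             n_missing_genes = sum(!have),
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated risk grouping
#'
#' For each sample the entire pipeline — Cox filter, PC1 loadings,
#' orientation, percentile threshold — is refit on the remaining n - 1
#' samples; the held-out sample is then scored and labelled with that
#' fold's model. Folds in which no gene survives the filter fall back to
#' the per-sample mean expression as the index, thresholded at the fold's
#' own percentile (their count is reported in the `n_fallback` attribute).
#'
#' @param expr genes x samples expression matrix.
#' @param outcome aligned survival table (`time`, `event`).
#' @param alpha Cox screening level.
#' @param percentile risk threshold percentile.
#' @return data.frame: sample_id, prognostic_index, risk_label, fold_id;
#'   attribute `n_fallback`.
#' @export
loocv_risk_groups <- function(expr, outcome, alpha = 0.001, percentile = 50) {
  n <- ncol(expr)
  if (n < 10L) stop("need n >= 10 for LOOCV", call. = FALSE)
  idx <- numeric(n); lab <- character(n)
  n_fallback <- 0L
  for (i in seq_len(n)) {
    tr_expr <- expr[, -i, drop = FALSE]
    tr_out <- outcome[-i, , drop = FALSE]
    fit <- tryCatch(
      fit_risk_model(tr_expr, tr_out, alpha = alpha, percentile = percentile),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_fallback <- n_fallback + 1L
      tr_idx <- colMeans(tr_expr)
      thr <- stats::quantile(tr_idx, percentile / 100, names = FALSE)
      idx[i] <- mean(expr[, i])
      lab[i] <- if (idx[i] > thr) "high" else "low"
    } else {
      pr <- predict(fit, expr[, i, drop = FALSE])
      idx[i] <- pr$prognostic_index
      lab[i] <- pr$risk_label
    }
  }
  out <- data.frame(sample_id = colnames(expr), prognostic_index = idx,
                    risk_label = lab, fold_id = seq_len(n),
                    stringsAsFactors = FALSE)
  attr(out, "n_fallback") <- n_fallback
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of survival between two label groups;
#' p-value from the chi-square distribution on 1 df.
#'
#' @param outcome data.frame with `time`, `event`.
#' @param labels two-level grouping aligned to `outcome` rows.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(outcome, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("need exactly two non-empty groups", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(outcome$time, outcome$event) ~ labels)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Time-dependent AUC at a landmark with censoring weights
#'
#' Cumulative-case / dynamic-control discrimination of a continuous index
#' at time t: cases experienced their event by t, controls are still
#' event-free beyond t. Pairs are weighted by inverse probabilities of
#' censoring from the Kaplan-Meier estimate of the censoring distribution
#' (left limit at the case's event time; value at t for controls); tied
#' indices count one half.
#'
#' @param indices numeric prognostic indices.
#' @param outcome aligned survival table (`time`, `event`).
#' @param landmark_time evaluation time, within the observed range.
#' @return AUC in `[0, 1]`, or NA when no comparable case-control pair
#'   exists.
#' @export
time_dependent_auc <- function(indices, outcome, landmark_time) {
  tm <- outcome$time; ev <- outcome$event
  case <- which(tm <= landmark_time & ev == 1)
  ctrl <- which(tm > landmark_time)
  if (length(case) == 0L || length(ctrl) == 0L) return(NA_real_)
  cfit <- survival::survfit(survival::Surv(tm, 1 - ev) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  Gminus <- function(t) {             # left limit G(t-)
    k <- cfit$time < t
    if (!any(k)) 1 else c(1, cfit$surv)[max(which(k)) + 1L]
  }
  w_case <- vapply(tm[case], function(t) 1 / max(Gminus(t), 1e-12), 0)
  w_ctrl <- rep(1 / max(G(landmark_time), 1e-12), length(ctrl))
  mi <- indices[case]; mj <- indices[ctrl]
  num <- 0
  for (a in seq_along(case)) {
    conc <- sum(w_ctrl * ((mi[a] > mj) + 0.5 * (mi[a] == mj)))
    num <- num + w_case[a] * conc
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Consensus counting of per-dataset prognostic flags
#'
#' Given a genes x datasets logical flag matrix (gene prognostic in that
#' dataset), returns for every agreement level k the genes flagged in at
#' least k datasets. Counts are non-increasing in k.
#'
#' @param flags logical matrix, rownames = genes, one column per dataset.
#' @return list with `counts` (named integer vector, level "1".."K") and
#'   `genes` (list of character vectors per level).
#' @export
consensus_filter <- function(flags) {
  flags[is.na(flags)] <- FALSE
  K <- ncol(flags)
  n_flag <- rowSums(flags)
  genes <- lapply(seq_len(K), function(k) rownames(flags)[n_flag >= k])
  counts <- vapply(genes, length, 0L)
  names(counts) <- names(genes) <- as.character(seq_len(K))
  list(counts = counts, genes = genes)
}
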