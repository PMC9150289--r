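#' Univariate two-sample t filter for dichotomous outcomes
#'
#' Pooled-variance two-sample t per gene (vectorized); genes with two-sided
#' `p < alpha` pass. Genes with zero pooled variance are flagged undefined
#' and excluded.
#'
#' @param expr genes x samples matrix.
#' @param labels per-sample class in `{0, 1}`, aligned to columns.
#' @param alpha significance level (default 0.001).
#' @return data.frame: gene, t, p, pass, defined.
#' @export
t_test_filter <- function(expr, labels, alpha = 0.001) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  x1 <- expr[, labels == 1L, drop = FALSE]
  x0 <- expr[, labels == 0L, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2); v0 <- rowSums((x0 - m0)^2)
  sp2 <- (v1 + v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tt <- (m1 - m0) / se
  def <- is.finite(tt)
  p <- 2 * stats::pt(-abs(tt), df = n1 + n0 - 2)
  genes <- rownames(expr)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(expr)))
  data.frame(gene = genes, t = ifelse(def, tt, NA_real_),
             p = ifelse(def, p, NA_real_),
             pass = def & !is.na(p) & p < alpha,
             defined = def, stringsAsFactors = FALSE)
}

#' Global multivariate permutation test
#'
#' Observed statistic: the number of genes passing the t filter at
#' `gene_alpha`. The null redraws class labels `n_perm` times and refilters;
#' `p = (1 + #null >= observed) / (1 + n_perm)`.
#'
#' @param expr genes x samples matrix.
#' @param labels class labels in `{0, 1}`.
#' @param gene_alpha per-gene filter level (default 0.001).
#' @param n_perm label permutations (>= 1000 recommended).
#' @param seed integer seed.
#' @return list with `observed` (gene count) and `p`.
#' @export
global_multivariate_permutation_test <- function(expr, labels,
                                                 gene_alpha = 0.001,
                                                 n_perm = 1000, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2L || n0 < 2L) stop("each class needs >= 2 samples", call. = FALSE)
  if (choose(n0 + n1, n1) < 20)
    stop("fewer than 20 distinct label permutations", call. = FALSE)
  set.seed(sub_seed(seed, 37L))
  obs <- sum(t_test_filter(expr, labels, gene_alpha)$pass)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    lp <- sample(labels)
    if (sum(t_test_filter(expr, lp, gene_alpha)$pass) >= obs)
      n_ge <- n_ge + 1L
  }
  list(observed = obs, p = perm_pvalue(n_ge, n_perm))
}

#' Train a binary classifier on a filtered gene subset
#'
#' Methods follow the classical microarray class-prediction toolkit:
#' \describe{
#'   \item{cc}{compound covariate: score = sum of t_g * x_g over filter
#'     genes, decision at the midpoint of the class mean scores.}
#'   \item{bcc}{Bayesian compound covariate: Gaussian class-conditional
#'     densities of the compound score with pooled variance and equal
#'     priors (configurable); reports the posterior for class 1, label by
#'     posterior > 0.5.}
#'   \item{dlda}{diagonal linear discriminant analysis: class-conditional
#'     Gaussians with shared per-gene variances.}
#'   \item{knn1, knn3}{k-nearest neighbours (k = 1, 3), Euclidean distance
#'     on genes standardized by the training fold.}
#'   \item{centroid}{nearest class centroid in the same standardized
#'     space.}
#'   \item{svm}{linear soft-margin support vector machine, cost 1.}
#' }
#'
#' @param expr genes x samples training matrix (already filtered).
#' @param labels training class labels in `{0, 1}`.
#' @param method one of `"cc"`, `"bcc"`, `"dlda"`, `"knn1"`, `"knn3"`,
#'   `"centroid"`, `"svm"`.
#' @param priors for `bcc`: `"equal"` (default) or `"empirical"`.
#' @return classifier state of class `concur_classifier`.
#' @export
train_classifier <- function(expr, labels,
                             method = c("cc", "bcc", "dlda", "knn1", "knn3",
                                        "centroid", "svm"),
                             priors = c("equal", "empirical")) {
  method <- match.arg(method)
  priors <- match.arg(priors)
  labels <- as.integer(labels)
  if (nrow(expr) == 0L) stop("empty gene set", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("need both classes", call. = FALSE)
  k <- switch(method, knn1 = 1L, knn3 = 3L, NA_integer_)
  if (!is.na(k) && k > ncol(expr)) stop("k exceeds training size", call. = FALSE)
  st <- list(method = method, genes = rownames(expr), labels = labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (method %in% c("cc", "bcc")) {
    # t-statistic weights; a zero pooled variance (perfect separator) gets
    # a floored standard error so its weight stays finite and dominant
    x1 <- expr[, labels == 1L, drop = FALSE]
    x0 <- expr[, labels == 0L, drop = FALSE]
    m1 <- rowMeans(x1); m0 <- rowMeans(x0)
    sp2 <- (rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    floor_se <- if (any(se > 0)) min(se[se > 0]) * 1e-3 else
      1e-3 * max(abs(m1 - m0), 1e-8)
    se[se == 0] <- floor_se
    w <- (m1 - m0) / se
    st$weights <- w
    score <- drop(crossprod(expr, w))
    s1 <- score[labels == 1L]; s0 <- score[labels == 0L]
    st$mid <- (mean(s1) + mean(s0)) / 2
    st$mu1 <- mean(s1); st$mu0 <- mean(s0)
    st$pooled_var <- (sum((s1 - st$mu1)^2) + sum((s0 - st$mu0)^2)) /
      (n1 + n0 - 2)
    st$prior1 <- if (priors == "equal") 0.5 else n1 / (n1 + n0)
  } else if (method == "dlda") {
    x1 <- expr[, labels == 1L, drop = FALSE]
    x0 <- expr[, labels == 0L, drop = FALSE]
    st$m1 <- rowMeans(x1); st$m0 <- rowMeans(x0)
    v <- (rowSums((x1 - st$m1)^2) + rowSums((x0 - st$m0)^2)) / (n1 + n0 - 2)
    v[v == 0] <- min(v[v > 0], 1e-8)
    st$v <- v
  } else if (method %in% c("knn1", "knn3", "centroid")) {
    ctr <- rowMeans(expr)
    scl <- apply(expr, 1, stats::sd); scl[scl == 0] <- 1
    st$center <- ctr; st$scale <- scl
    Z <- (expr - ctr) / scl
    st$train <- Z
    st$k <- k
    if (method == "centroid") {
      st$c1 <- rowMeans(Z[, labels == 1L, drop = FALSE])
      st$c0 <- rowMeans(Z[, labels == 0L, drop = FALSE])
    }
  } else if (method == "svm") {
    st$fit <- e1071::svm(x = t(expr), y = factor(labels, levels = c(0, 1)),
                         kernel = "linear", cost = 1, scale = FALSE)
  }
  structure(st, class = "concur_classifier")
}

#' Predict class labels (and posteriors) for new samples
#'
#' @param object a `concur_classifier` from [train_classifier()].
#' @param newdata genes x samples matrix containing the classifier's genes.
#' @param ... unused.
#' @return data.frame: sample_id, label (0/1); a `posterior` column (class
#'   1 probability) for the Bayesian compound covariate.
#' @export
predict.concur_classifier <- function(object, newdata, ...) {
  X <- newdata[object$genes, , drop = FALSE]
  ids <- colnames(newdata)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(newdata)))
  method <- object$method
  if (method == "cc") {
    score <- drop(crossprod(X, object$weights))
    up <- object$mu1 > object$mu0
    lab <- as.integer(if (up) score > object$mid else score < object$mid)
    return(data.frame(sample_id = ids, label = lab, stringsAsFactors = FALSE))
  }
  if (method == "bcc") {
    score <- drop(crossprod(X, object$weights))
    sd <- sqrt(max(object$pooled_var, 1e-12))
    d1 <- stats::dnorm(score, object$mu1, sd) * object$prior1
    d0 <- stats::dnorm(score, object$mu0, sd) * (1 - object$prior1)
    post <- d1 / (d1 + d0)
    post[!is.finite(post)] <- 0.5
    return(data.frame(sample_id = ids, label = as.integer(post > 0.5),
                      posterior = post, stringsAsFactors = FALSE))
  }
  if (method == "dlda") {
    # discriminant: sum_g [ (x - m)^2 / v ] smaller wins
    d1 <- colSums((X - object$m1)^2 / object$v)
    d0 <- colSums((X - object$m0)^2 / object$v)
    return(data.frame(sample_id = ids, label = as.integer(d1 < d0),
                      stringsAsFactors = FALSE))
  }
  Z <- (X - object$center) / object$scale
  if (method %in% c("knn1", "knn3")) {
    lab <- as.integer(as.character(class::knn(
      train = t(object$train), test = t(Z),
      cl = factor(object$labels, levels = c(0, 1)), k = object$k)))
    return(data.frame(sample_id = ids, label = lab, stringsAsFactors = FALSE))
  }
  if (method == "centroid") {
    d1 <- colSums((Z - object$c1)^2)
    d0 <- colSums((Z - object$c0)^2)
    return(data.frame(sample_id = ids, label = as.integer(d1 < d0),
                      stringsAsFactors = FALSE))
  }
  # svm
  lab <- as.integer(as.character(stats::predict(object$fit, t(X))))
  data.frame(sample_id = ids, label = lab, stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated classification
#'
#' Per fold, the t filter AND the classifier are refit on the n - 1
#' training samples (no leakage); the held-out sample is predicted with
#' that fold's model. Folds whose filter selects no gene fall back to the
#' single smallest-p gene.
#'
#' @param expr genes x samples matrix.
#' @param labels class labels in `{0, 1}`.
#' @param method classifier method (see [train_classifier()]).
#' @param alpha per-gene filter level (default 0.001).
#' @return list of class `concur_cv_result`: method, predictions
#'   (data.frame sample_id, true, predicted, posterior where available),
#'   misclassification rate, n.
#' @export
loocv_classify <- function(expr, labels, method = "cc", alpha = 0.001) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 6L) stop("need n >= 6 for LOOCV", call. = FALSE)
  pred <- integer(n); post <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) < 2L)
      stop("a fold has an empty class", call. = FALSE)
    ft <- t_test_filter(expr[, -i, drop = FALSE], tr_lab, alpha)
    sel <- ft$gene[ft$pass]
    if (length(sel) == 0L)
      sel <- ft$gene[which.min(ft$p)]
    cl <- train_classifier(expr[sel, -i, drop = FALSE], tr_lab, method)
    pr <- predict(cl, expr[sel, i, drop = FALSE])
    pred[i] <- pr$label
    if (!is.null(pr$posterior)) post[i] <- pr$posterior
  }
  structure(list(
    method = method,
    predictions = data.frame(sample_id = colnames(expr) %||%
                               paste0("S", seq_len(n)),
                             true = labels, predicted = pred,
                             posterior = post, stringsAsFactors = FALSE),
    misclassification = mean(pred != labels),
    n = n), class = "concur_cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.concur_cv_result <- function(x, ...) {
  cat(sprintf("LOOCV %s: misclassification %.3f (n = %d)\n",
              x$method, x$misclassification, x$n))
  invisible(x)
}

#' Permutation p-value of a cross-validated misclassification rate
#'
#' For each label permutation the entire LOOCV (filter and classifier
#' refit per fold) is repeated; the p-value is the add-one-corrected
#' fraction of permutations achieving a misclassification rate at most the
#' observed one.
#'
#' @param expr genes x samples matrix.
#' @param labels class labels.
#' @param method classifier method.
#' @param alpha filter level.
#' @param n_perm label permutations; below 1000 (the conventional minimum)
#'   a warning is issued but the test still runs.
#' @param seed integer seed.
#' @return list with `observed` (misclassification rate) and `p`.
#' @export
permutation_pvalue <- function(expr, labels, method = "cc", alpha = 0.001,
                               n_perm = 1000, seed = 1L) {
  if (n_perm < 1000)
    warning("n_perm below the conventional minimum of 1000")
  set.seed(sub_seed(seed, 43L))
  obs <- loocv_classify(expr, labels, method, alpha)$misclassification
  n_le <- 0L
  for (b in seq_len(n_perm)) {
    lp <- sample(as.integer(labels))
    rate <- loocv_classify(expr, lp, method, alpha)$misclassification
    if (rate <= obs) n_le <- n_le + 1L
  }
  list(observed = obs, p = perm_pvalue(n_le, n_perm))
}

#' Cross-validated AUC from Bayesian compound covariate posteriors
#'
#' Mann-Whitney form of the ROC area: the fraction of (class 1, class 0)
#' pairs in which the class-1 posterior is larger, ties counting one half.
#'
#' @param posteriors cross-validated class-1 posterior probabilities.
#' @param labels true class labels in `{0, 1}`.
#' @return AUC in `[0, 1]`; NA when a class is absent.
#' @export
cv_auc_bccp <- function(posteriors, labels) {
  labels <- as.integer(labels)
  p1 <- posteriors[labels == 1L]
  p0 <- posteriors[labels == 0L]
  if (length(p1) == 0L || length(p0) == 0L) return(NA_real_)
  tot <- 0
  for (a in p1) tot <- tot + sum(a > p0) + 0.5 * sum(a == p0)
  tot / (length(p1) * length(p0))
}
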