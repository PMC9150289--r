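test_that("vectorized Cox score test agrees with coxph", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  tm <- rexp(n, exp(0.7 * x))
  ev <- rbinom(n, 1, 0.8)
  out <- data.frame(time = tm, event = ev)
  mine <- cox_univariate(matrix(x, 1, dimnames = list("g", NULL)), out)
  ref <- summary(survival::coxph(survival::Surv(tm, ev) ~ x))$sctest
  expect_equal(mine$statistic, unname(ref["test"]), tolerance = 1e-8)
  expect_equal(mine$p, unname(ref["pvalue"]), tolerance = 1e-8)
  # matrix input, many genes at once, matches gene-by-gene coxph
  X <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("g", 1:5), NULL))
  mm <- cox_univariate(X, out)
  for (g in 1:5) {
    rg <- summary(survival::coxph(survival::Surv(tm, ev) ~ X[g, ]))$sctest
    expect_equal(mm$statistic[g], unname(rg["test"]), tolerance = 1e-8)
  }
  # constant covariate undefined; too few events rejected
  cst <- cox_univariate(matrix(1, 1, n), out)
  expect_false(cst$defined)
  expect_error(cox_univariate(X, data.frame(time = tm, event = rep(0, n))),
               "events")
})

test_that("null Cox screening p-values are approximately uniform", {
  set.seed(6)
  n <- 80
  tm <- rexp(n, 0.05); ev <- rbinom(n, 1, 0.7)
  X <- matrix(rnorm(1000 * n), 1000, n)
  res <- cox_univariate(X, data.frame(time = tm, event = ev))
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  # power: the true log-hazard score is detected
  sc <- planted_survival_cohort(n = 200, effect = 1, seed = 8)
  pw <- cox_univariate(matrix(sc$score, 1), sc$outcome)
  expect_lt(pw$p, 1e-4)
})

test_that("supervised PC model recovers a planted factor and thresholds", {
  sc <- planted_survival_cohort(n = 200, n_genes = 100, n_sig = 15,
                                effect = 1.2, seed = 12)
  fit <- fit_risk_model(sc$expr, sc$outcome, alpha = 0.001, percentile = 50)
  # most selected genes are true signature genes
  expect_gte(mean(fit$genes %in% sc$signature), 0.8)
  # loadings unit norm; training index correlates with the latent factor
  expect_equal(sum(fit$loadings^2), 1)
  expect_gt(abs(cor(fit$train_index, sc$score)), 0.8)
  # orientation: larger index = larger hazard
  u <- cox_univariate(matrix(fit$train_index, 1), sc$outcome)
  expect_gt(u$sign, 0)
  # percentile 50 splits evenly for distinct indices
  n_high <- sum(fit$train_index > fit$threshold)
  expect_true(n_high %in% c(100L, 99L))
  # rank-1 input: PC1 recovers the factor direction
  lat <- rnorm(50)
  X1 <- outer(rnorm(20, 1, 0.2), lat)
  rownames(X1) <- paste0("g", 1:20); colnames(X1) <- paste0("S", 1:50)
  o1 <- data.frame(time = rexp(50, exp(lat)), event = 1L)
  f1 <- fit_risk_model(X1, o1, alpha = 0.05)
  expect_gt(abs(cor(f1$train_index, lat)), 0.999)
  # empty model is an explicit error
  set.seed(31)
  Xn <- matrix(rnorm(10 * 50), 10, 50,
               dimnames = list(paste0("g", 1:10), paste0("S", 1:50)))
  on <- data.frame(time = rexp(50, 0.1), event = rbinom(50, 1, 0.8))
  expect_error(fit_risk_model(Xn, on, alpha = 1e-12), "no gene passes")
})

test_that("prediction is consistent, linear in input, and guards missingness", {
  sc <- planted_survival_cohort(n = 80, seed = 13)
  fit <- fit_risk_model(sc$expr, sc$outcome, alpha = 0.01)
  pr <- predict(fit, sc$expr)
  expect_equal(pr$prognostic_index, unname(fit$train_index))
  expect_equal(pr$risk_label,
               ifelse(fit$train_index > fit$threshold, "high", "low"),
               ignore_attr = TRUE)
  # adding a constant to one sample shifts its index by the loading sum
  new <- sc$expr
  new[, 1] <- new[, 1] + 2
  pr2 <- predict(fit, new)
  shift <- sum(fit$loadings / fit$scale) * 2
  expect_equal(pr2$prognostic_index[1] - pr$prognostic_index[1], shift)
  # missing genes: imputed under 50%, refused above
  drop_few <- sc$expr[setdiff(rownames(sc$expr), fit$genes[1]), ]
  if (length(fit$genes) > 1) {
    pr3 <- predict(fit, drop_few)
    expect_equal(unique(pr3$n_missing_genes), 1L)
  }
  none <- sc$expr[setdiff(rownames(sc$expr), fit$genes), , drop = FALSE]
  expect_error(predict(fit, none), "missing")
  # affine gene-wise rescaling leaves the index invariant
  resc <- sc$expr * 3 + 5
  fit_r <- fit_risk_model(resc, sc$outcome, alpha = 0.01)
  expect_equal(abs(cor(fit_r$train_index, fit$train_index)), 1,
               tolerance = 1e-8)
})

test_that("nested LOOCV risk grouping finds planted signal without leakage", {
  sc <- planted_survival_cohort(n = 100, n_genes = 60, n_sig = 12,
                                effect = 1.5, seed = 14)
  cv <- loocv_risk_groups(sc$expr, sc$outcome, alpha = 0.001)
  expect_equal(nrow(cv), 100L)
  lr <- logrank_test(sc$outcome, cv$risk_label)
  expect_lt(lr$p, 0.01)
  # deterministic
  cv2 <- loocv_risk_groups(sc$expr, sc$outcome, alpha = 0.001)
  expect_identical(cv, cv2)
  # leakage: changing the held-out outcome never changes its label
  out_perm <- sc$outcome
  out_perm$time[7] <- out_perm$time[7] * 10
  out_perm$event[7] <- 1 - out_perm$event[7]
  cv3 <- loocv_risk_groups(sc$expr, out_perm, alpha = 0.001)
  expect_identical(cv3$risk_label[7], cv$risk_label[7])
  expect_error(loocv_risk_groups(sc$expr[, 1:5], sc$outcome[1:5, ]), "n >= 10")
})

test_that("log-rank test matches an exhaustive risk-set tabulation", {
  out <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1L)
  labels <- rep(c("a", "b"), each = 3)
  # hand tabulation: at each event time O - E for group a with risk sets
  # t=1: O=1 E=3/6; t=2: O=1 E=2/5; t=3: O=1 E=1/4; t=4,5,6: O=0 E=0
  oe <- (1 - 3 / 6) + (1 - 2 / 5) + (1 - 1 / 4) + (0) + (0) + (0)
  vr <- sum(c(3 * 3 * 1 * 5 / (36 * 5), 2 * 3 * 1 * 4 / (25 * 4),
              1 * 3 * 1 * 3 / (16 * 3), 0, 0, 0))
  lr <- logrank_test(out, labels)
  expect_equal(lr$chi2, oe^2 / vr, tolerance = 1e-8)
  # identical groups: chi2 0, p 1
  out2 <- data.frame(time = rep(c(1, 2, 3), 2), event = 1L)
  lr2 <- logrank_test(out2, rep(c("a", "b"), 3))
  expect_equal(lr2$chi2, 0, tolerance = 1e-10)
  expect_equal(lr2$p, 1, tolerance = 1e-6)
  # label swap leaves chi2 unchanged
  lr3 <- logrank_test(out, rev(labels))
  expect_equal(lr3$chi2, lr$chi2)
  expect_error(logrank_test(out, rep("a", 6)), "two")
})

test_that("time-dependent AUC matches Mann-Whitney without censoring", {
  # perfect separation at the landmark
  out <- data.frame(time = c(1, 2, 8, 9, 10), event = 1L)
  idx <- c(5, 4, 1, 2, 3)
  expect_equal(time_dependent_auc(idx, out, 5), 1)
  # oracle equivalence: no censoring -> Mann-Whitney of index vs status
  set.seed(15)
  n <- 60
  out2 <- data.frame(time = rexp(n, 0.1), event = 1L)
  idx2 <- rnorm(n) + 0.5 * (out2$time < 7)
  status <- out2$time <= 7
  mw <- mean(outer(idx2[status], idx2[!status], ">") +
               0.5 * outer(idx2[status], idx2[!status], "=="))
  expect_equal(time_dependent_auc(idx2, out2, 7), mw)
  # random indices at large n: near 0.5
  set.seed(16)
  n <- 500
  out3 <- data.frame(time = rexp(n, 0.1),
                     event = rbinom(n, 1, 0.8))
  auc3 <- time_dependent_auc(rnorm(n), out3, median(out3$time))
  expect_lt(abs(auc3 - 0.5), 0.05)
  # undefined when no case
  out4 <- data.frame(time = c(10, 11, 12), event = c(1L, 1L, 1L))
  expect_true(is.na(time_dependent_auc(1:3, out4, 5)))
})

test_that("consensus counting is monotone and exact", {
  flags <- matrix(FALSE, 4, 5,
                  dimnames = list(c("g1", "g2", "g3", "g4"), NULL))
  flags["g1", 1:3] <- TRUE          # flagged in 3 of 5
  flags["g2", 4] <- TRUE
  flags["g3", 5] <- TRUE
  cf <- consensus_filter(flags)
  expect_equal(unname(cf$counts), c(3L, 1L, 1L, 0L, 0L))
  expect_true(all(diff(cf$counts) <= 0))
  expect_equal(cf$genes[["3"]], "g1")
  expect_equal(cf$genes[["4"]], character())
  # disjoint flags -> level 2 empty
  dis <- diag(TRUE, 3); rownames(dis) <- paste0("g", 1:3)
  expect_equal(unname(consensus_filter(dis)$counts[2]), 0L)
})
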