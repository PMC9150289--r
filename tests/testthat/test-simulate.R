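test_that("genome layout places disjoint marker-covering genes deterministically", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 100,
                    n_genes = 10, n_samples = 5, seed = 11)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$marker_map), 100L)
  expect_true(all(diff(g$marker_map$position) > 0))
  expect_equal(nrow(g$genes), 10L)
  expect_true(all(g$genes$n_markers >= 1L))
  # disjoint intervals
  o <- order(g$genes$start)
  expect_true(all(g$genes$start[o][-1] > g$genes$end[o][-10]))
  # determinism
  expect_identical(g, simulate_genome(cfg))
  # degenerate: no genes
  g0 <- simulate_genome(sim_config(n_genes = 0, seed = 11))
  expect_equal(nrow(g0$genes), 0L)
  expect_gt(nrow(g0$marker_map), 0L)
  # sizing error
  expect_error(simulate_genome(sim_config(n_chromosomes = 1,
                                          markers_per_chromosome = 5,
                                          n_genes = 6)),
               "overlap")
})

test_that("CNV profiles are true means plus calibrated noise", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 200,
                    n_genes = 20, n_samples = 50, marker_noise_sd = 0,
                    seg_event_rate = 0.5, seed = 5)
  g <- simulate_genome(cfg)
  cnv <- simulate_cnv_profiles(g$marker_map, cfg)
  expect_identical(cnv$log_ratios, cnv$true_means)  # noiseless
  # zero event rate -> all-zero truth
  cfg0 <- sim_config(seg_event_rate = 0, seed = 5)
  g0 <- simulate_genome(cfg0)
  cnv0 <- simulate_cnv_profiles(g0$marker_map, cfg0)
  expect_true(all(cnv0$true_means == 0))
  # Monte-Carlo: neutral-marker SD within 10% of marker_noise_sd
  cfgn <- sim_config(n_chromosomes = 2, markers_per_chromosome = 200,
                     n_genes = 20, n_samples = 50, marker_noise_sd = 0.2,
                     seg_event_rate = 0.3, seed = 7)
  gn <- simulate_genome(cfgn)
  cn <- simulate_cnv_profiles(gn$marker_map, cfgn)
  resid <- (cn$log_ratios - cn$true_means)[cn$true_means == 0]
  expect_lt(abs(sd(resid) - 0.2) / 0.2, 0.1)
  # determinism
  expect_identical(cn, simulate_cnv_profiles(gn$marker_map, cfgn))
})

test_that("expression carries the planted dosage effect", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 200,
                    n_genes = 60, n_samples = 100, seg_event_rate = 2,
                    seg_mean_length = 60, marker_noise_sd = 0.1,
                    concurrent_fraction = 0.5, dosage_beta = 2,
                    expr_noise_sd = 0, seed = 21)
  co <- concur:::simulate_cohort(cfg)
  # noiseless: expression is exactly affine in true gene copy number
  for (g in head(co$concurrent_genes, 5)) {
    fit <- lm(co$expression[g, ] ~ co$gene_cn_true[g, ])
    expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-8)
    expect_equal(unname(coef(fit)[1]), cfg$expr_baseline, tolerance = 1e-8)
  }
  # with noise: mean Spearman r over concurrent genes clearly positive
  cfg2 <- sim_config(n_chromosomes = 2, markers_per_chromosome = 200,
                     n_genes = 60, n_samples = 100, seg_event_rate = 3,
                     seg_mean_length = 70, marker_noise_sd = 0.05,
                     amp_magnitude = 1.5, del_magnitude = -1.5,
                     gain_magnitude = 0.6, loss_magnitude = -0.6,
                     concurrent_fraction = 0.5, dosage_beta = 1,
                     expr_noise_sd = 1, seed = 22)
  co2 <- concur:::simulate_cohort(cfg2)
  rs <- vapply(co2$concurrent_genes, function(g)
    cor(co2$gene_cn_true[g, ], co2$expression[g, ], method = "spearman"), 0)
  expect_gt(mean(rs), 0.4)
  # null: dosage_beta = 0 leaves no association
  cfg3 <- sim_config(n_chromosomes = 2, markers_per_chromosome = 200,
                     n_genes = 60, n_samples = 100, seg_event_rate = 2,
                     concurrent_fraction = 0.5, dosage_beta = 0,
                     expr_noise_sd = 1, seed = 23)
  co3 <- concur:::simulate_cohort(cfg3)
  rs3 <- vapply(co3$concurrent_genes, function(g)
    cor(co3$gene_cn_true[g, ], co3$expression[g, ], method = "spearman"), 0)
  expect_lt(abs(mean(rs3)), 0.1)
})

test_that("outcomes follow the signature score and censoring target", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 150,
                    n_genes = 50, n_samples = 200, seg_event_rate = 2,
                    concurrent_fraction = 0.4, signature_size = 10,
                    log_hazard_coef = 1, censoring_rate = 0.3, seed = 31)
  co <- concur:::simulate_cohort(cfg)
  # Cox on the true score recovers a positive association
  f <- survival::coxph(survival::Surv(co$survival$time, co$survival$event) ~
                         co$score)
  expect_gt(coef(f), 0)
  expect_lt(summary(f)$sctest["pvalue"], 0.001)
  # censoring near target
  expect_lt(abs(mean(1 - co$survival$event) - 0.3), 0.12)
  expect_true(all(co$survival$time > 0))
  # censoring_rate = 0 -> all events
  cfg0 <- sim_config(censoring_rate = 0, n_samples = 40, seed = 32)
  co0 <- concur:::simulate_cohort(cfg0)
  expect_true(all(co0$survival$event == 1L))
  # empty signature with nonzero coefficient is a configuration error
  expect_error(simulate_outcomes(co$expression, character(), cfg),
               "signature")
})

test_that("multi-cohort generation shares truth and supports probes", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 150,
                    n_genes = 40, seg_event_rate = 2,
                    concurrent_fraction = 0.3, seed = 41)
  cs <- simulate_multi_cohort(cfg, c(31, 60), probes_per_gene = 3)
  expect_length(cs, 2L)
  expect_equal(ncol(cs[[1]]$expression), 31L)
  expect_equal(ncol(cs[[2]]$expression), 60L)
  expect_identical(rownames(cs[[1]]$expression), rownames(cs[[2]]$expression))
  expect_identical(cs[[1]]$concurrent_genes, cs[[2]]$concurrent_genes)
  expect_identical(cs[[1]]$signature_genes, cs[[2]]$signature_genes)
  expect_equal(nrow(cs[[1]]$probe_expression), 3L * 40L)
  # independent noise
  expect_false(identical(cs[[1]]$log_ratios[, 1], cs[[2]]$log_ratios[, 1]))
  # determinism of the whole list
  expect_identical(cs, simulate_multi_cohort(cfg, c(31, 60),
                                             probes_per_gene = 3))
})
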