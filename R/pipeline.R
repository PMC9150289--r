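#' Pipeline configuration
#'
#' Collects all stage parameters with their conventional defaults: CBS
#' accept level 0.01 with 1000 permutations, MAD multipliers 1.0 (high
#' level) and 0.5 (low level), GISTIC thresholds +/-0.1 with q < 0.25 and
#' 10,000 resamplings, per-cohort concurrency level 0.01, universal
#' combined level 0.001, Cox/t filter 0.001, risk percentile 50, and a
#' single global seed from which every stage derives its substream.
#'
#' @param sim a [sim_config()] for the synthetic cohorts.
#' @param cohort_sizes discovery cohort sizes (small, large).
#' @param cbs_alpha,cbs_n_perm CBS accept level and permutations.
#' @param smooth smooth outliers before segmentation.
#' @param high_mult,low_mult MAD multipliers for CNV calls.
#' @param gistic_n_perm,gistic_q GISTIC resamplings and region q cutoff.
#' @param cohort_alpha per-cohort concurrency level.
#' @param combined_alpha universal (combined) concurrency level.
#' @param filter_alpha Cox / t-test screening level.
#' @param percentile risk-group percentile (50 or 75).
#' @param class_method classifier for the dichotomous stage.
#' @param class_n_perm permutations for the classification p-value.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @param seed global integer seed.
#' @return a list of class `concur_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cohort_sizes = c(31L, 345L),
                            cbs_alpha = 0.01, cbs_n_perm = 1000,
                            smooth = TRUE,
                            high_mult = 1, low_mult = 0.5,
                            gistic_n_perm = 10000, gistic_q = 0.25,
                            cohort_alpha = 0.01,
                            combined_alpha = 0.001,
                            filter_alpha = 0.001,
                            percentile = 50,
                            class_method = "bcc",
                            class_n_perm = 1000,
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(inherits(sim, "concur_sim_config"))
  if (!percentile %in% c(50, 75) && (percentile <= 0 || percentile >= 100))
    stop("percentile must be in (0, 100)", call. = FALSE)
  structure(as.list(environment()), class = "concur_pipeline_config")
}

#' Run the full pipeline on synthetic cohorts
#'
#' Stage order: simulate paired cohorts, smooth + segment the small
#' cohort's profiles, call five-state CNV against per-array MAD, score
#' recurrent regions, build gene-centric CNV per cohort, score per-gene
#' concurrency in each cohort and combine by Fisher's z, fit and
#' cross-validate the supervised-PC risk model on the large cohort, and
#' run the dichotomous classifier. A gene-count funnel (genes in/out at
#' each filter) is logged in the report.
#'
#' @param config a [pipeline_config()].
#' @return list of class `concur_report`: `funnel` (named counts),
#'   `concurrency` (table), `risk` (model, cv labels, log-rank, AUC),
#'   `classification`, `frequency` (per-marker gain/loss), `paths` (files
#'   written, when `out_dir` set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "concur_pipeline_config"))
  sim <- config$sim
  sim$seed <- config$seed
  cohorts <- simulate_multi_cohort(sim, config$cohort_sizes)
  small <- cohorts[[1L]]; large <- cohorts[[2L]]
  funnel <- c(genes_simulated = nrow(small$genes))

  # --- segmentation + calling on the small (SNP-array) cohort
  n_small <- ncol(small$log_ratios)
  seg_list <- vector("list", n_small)
  call_list <- vector("list", n_small)
  seg_values <- small$log_ratios * 0
  for (s in seq_len(n_small)) {
    prof <- small$log_ratios[, s]
    if (config$smooth) prof <- smooth_outliers(prof, small$marker_map)
    seg <- cbs_segment(prof, small$marker_map, alpha = config$cbs_alpha,
                       n_perm = config$cbs_n_perm,
                       seed = sub_seed(config$seed, s),
                       sample_id = colnames(small$log_ratios)[s])
    seg <- merge_levels(seg, prof, small$marker_map)
    noise <- compute_mad(prof, colnames(small$log_ratios)[s])
    call_list[[s]] <- call_cnv(seg, noise, config$high_mult, config$low_mult)
    seg_list[[s]] <- seg
    for (r in seq_len(nrow(seg))) {
      sel <- small$marker_map$chromosome == seg$chromosome[r] &
        small$marker_map$position >= seg$start_pos[r] &
        small$marker_map$position <= seg$end_pos[r]
      seg_values[sel, s] <- seg$seg_mean[r]
    }
  }
  calls <- do.call(rbind, call_list)
  freq <- frequency_profile(calls, small$marker_map)

  # --- recurrent CNV
  gistic <- gistic_null(seg_values, small$marker_map,
                        n_perm = config$gistic_n_perm,
                        seed = sub_seed(config$seed, 997L),
                        q_cut = config$gistic_q)

  # --- concurrency: per-cohort Spearman + Fisher-z combination
  cnv_small <- gene_centric_table(small$log_ratios, small$marker_map,
                                  small$genes)
  cnv_large <- gene_centric_table(large$log_ratios, large$marker_map,
                                  large$genes)
  expr_small <- median_center(small$expression)
  expr_large <- median_center(large$expression)
  conc <- concurrency_table(cnv_small, expr_small, cnv_large, expr_large,
                            alpha = config$combined_alpha)
  funnel["genes_tested"] <- nrow(conc)
  funnel["concurrent_cohort1"] <-
    length(filter_concurrent(conc, config$cohort_alpha, "p1"))
  funnel["concurrent_cohort2"] <-
    length(filter_concurrent(conc, config$cohort_alpha, "p2"))
  universal <- conc$gene[conc$pass]
  funnel["universal_concurrent"] <- length(universal)

  # --- survival risk model on the large cohort, restricted to the
  #     universal concurrent set
  risk <- NULL
  if (length(universal) >= 1L) {
    expr_u <- expr_large[universal, , drop = FALSE]
    model <- tryCatch(
      fit_risk_model(expr_u, large$survival, alpha = config$filter_alpha,
                     percentile = config$percentile),
      error = function(e) NULL)
    cv <- loocv_risk_groups(expr_u, large$survival,
                            alpha = config$filter_alpha,
                            percentile = config$percentile)
    lr <- if (length(unique(cv$risk_label)) == 2L)
      logrank_test(large$survival, cv$risk_label)
    else list(chi2 = NA_real_, p = NA_real_)
    landmark <- stats::median(large$survival$time[large$survival$event == 0])
    if (!is.finite(landmark)) landmark <- stats::median(large$survival$time)
    auc <- time_dependent_auc(cv$prognostic_index, large$survival, landmark)
    funnel["cox_selected"] <- if (is.null(model)) 0L else length(model$genes)
    risk <- list(model = model, cv = cv, logrank = lr, landmark = landmark,
                 auc = auc)
  }

  # --- dichotomous classification on the large cohort
  classification <- NULL
  if (length(universal) >= 1L &&
      length(unique(large$binary$label)) == 2L &&
      min(table(large$binary$label)) >= 3L) {
    expr_u <- expr_large[universal, , drop = FALSE]
    cvres <- loocv_classify(expr_u, large$binary$label,
                            method = config$class_method,
                            alpha = config$filter_alpha)
    auc_b <- if (config$class_method == "bcc")
      cv_auc_bccp(cvres$predictions$posterior, cvres$predictions$true)
    else NA_real_
    classification <- list(cv = cvres, cv_auc = auc_b)
  }

  report <- structure(list(
    funnel = funnel, concurrency = conc, risk = risk,
    classification = classification, frequency = freq,
    gistic = gistic, calls = calls, config = config), class = "concur_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    paths <- c(
      write_seg(calls, p("cnv_calls.seg")),
      write_bed_genes(small$genes, p("genes.bed")),
      write_outcomes(large$survival, p("survival.tsv")),
      {
        utils::write.table(conc, p("concurrency.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        p("concurrency.tsv")
      },
      {
        utils::write.table(freq, p("marker_frequency.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        p("marker_frequency.tsv")
      },
      {
        writeLines(paste(names(funnel), funnel, sep = "\t"), p("funnel.tsv"))
        p("funnel.tsv")
      })
    report$paths <- paths
  }
  report
}

#' @export
print.concur_report <- function(x, ...) {
  cat("Concurrent-gene pipeline report\n")
  cat("  gene funnel:\n")
  for (nm in names(x$funnel))
    cat(sprintf("    %-22s %d\n", nm, x$funnel[[nm]]))
  if (!is.null(x$risk)) {
    cat(sprintf("  CV log-rank: chi2 = %.3f, p = %.4g\n",
                x$risk$logrank$chi2, x$risk$logrank$p))
    cat(sprintf("  landmark AUC (t = %.1f): %.3f\n",
                x$risk$landmark, x$risk$auc))
  }
  if (!is.null(x$classification)) {
    cat(sprintf("  LOOCV %s misclassification: %.3f\n",
                x$classification$cv$method,
                x$classification$cv$misclassification))
    if (is.finite(x$classification$cv_auc))
      cat(sprintf("  CV-AUC: %.3f\n", x$classification$cv_auc))
  }
  invisible(x)
}
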