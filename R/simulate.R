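#' Simulation configuration for paired CNV/expression cohorts
#'
#' Builds and validates the parameter set driving the synthetic-data
#' generator. The generator emulates the paired design of a copy-number /
#' gene-expression integration study: segmental copy-number events with
#' per-array noise, a subset of genes whose transcription tracks DNA dosage
#' linearly (the "concurrent" genes), survival times whose hazard depends on
#' a signature supergene, and dichotomous outcomes through a logistic link.
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome evenly spaced markers placed on each
#'   chromosome.
#' @param n_genes number of non-overlapping genes to place across the genome.
#' @param n_samples cohort size.
#' @param seg_event_rate expected CNV events per sample per chromosome
#'   (Poisson mean).
#' @param seg_mean_length mean segment length of an event, in markers
#'   (geometric draw).
#' @param amp_magnitude,del_magnitude log-ratio shift of high-level events
#'   (amplification / homozygous deletion).
#' @param gain_magnitude,loss_magnitude log-ratio shift of low-level events.
#' @param marker_noise_sd per-marker Gaussian noise SD on the log-ratio scale.
#' @param concurrent_fraction fraction of genes given a dosage effect on
#'   expression.
#' @param dosage_beta expression units per copy-number log-ratio unit for
#'   concurrent genes. Ignored when `target_rho` is set.
#' @param target_rho optional target dosage-expression correlation; when
#'   non-`NULL`, `dosage_beta` is sized per gene from its realized
#'   copy-number SD so the generating correlation is approximately
#'   `target_rho` for every concurrent gene.
#' @param expr_noise_sd per-gene expression noise SD.
#' @param expr_baseline baseline expression intensity.
#' @param signature_size number of genes driving outcome.
#' @param log_hazard_coef log-hazard units per SD of the signature score.
#' @param baseline_hazard exponential baseline event rate (per month).
#' @param censoring_rate target fraction of censored samples.
#' @param logistic_intercept,logistic_slope parameters of the logistic link
#'   generating dichotomous adverse-event labels from the signature score.
#' @param marker_spacing base pairs between adjacent markers.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return a validated list of class `concur_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4L,
                       markers_per_chromosome = 250L,
                       n_genes = 100L,
                       n_samples = 50L,
                       seg_event_rate = 1,
                       seg_mean_length = 40,
                       amp_magnitude = 1.2,
                       del_magnitude = -1.2,
                       gain_magnitude = 0.35,
                       loss_magnitude = -0.35,
                       marker_noise_sd = 0.15,
                       concurrent_fraction = 0.2,
                       dosage_beta = 2,
                       target_rho = NULL,
                       expr_noise_sd = 0.5,
                       expr_baseline = 7,
                       signature_size = 10L,
                       log_hazard_coef = 1,
                       baseline_hazard = 0.02,
                       censoring_rate = 0.3,
                       logistic_intercept = 0,
                       logistic_slope = 1,
                       marker_spacing = 10000L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    n_genes = as.integer(n_genes),
    n_samples = as.integer(n_samples),
    seg_event_rate = seg_event_rate,
    seg_mean_length = seg_mean_length,
    amp_magnitude = amp_magnitude,
    del_magnitude = del_magnitude,
    gain_magnitude = gain_magnitude,
    loss_magnitude = loss_magnitude,
    marker_noise_sd = marker_noise_sd,
    concurrent_fraction = concurrent_fraction,
    dosage_beta = dosage_beta,
    target_rho = target_rho,
    expr_noise_sd = expr_noise_sd,
    expr_baseline = expr_baseline,
    signature_size = as.integer(signature_size),
    log_hazard_coef = log_hazard_coef,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    logistic_intercept = logistic_intercept,
    logistic_slope = logistic_slope,
    marker_spacing = as.integer(marker_spacing),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_chromosomes < 1L || markers_per_chromosome < 1L || n_samples < 1L)
      stop("counts must be >= 1", call. = FALSE)
    if (n_genes < 0L) stop("n_genes must be >= 0", call. = FALSE)
    if (seg_event_rate < 0) stop("seg_event_rate must be >= 0", call. = FALSE)
    if (concurrent_fraction < 0 || concurrent_fraction > 1)
      stop("concurrent_fraction must be in [0, 1]", call. = FALSE)
    if (censoring_rate < 0 || censoring_rate >= 1)
      stop("censoring_rate must be in [0, 1)", call. = FALSE)
    if (gain_magnitude >= amp_magnitude)
      stop("gain_magnitude must be < amp_magnitude", call. = FALSE)
    if (abs(loss_magnitude) >= abs(del_magnitude))
      stop("|loss_magnitude| must be < |del_magnitude|", call. = FALSE)
    if (marker_noise_sd < 0 || expr_noise_sd < 0)
      stop("noise SDs must be >= 0", call. = FALSE)
  })
  structure(cfg, class = "concur_sim_config")
}

#' Simulate the genome layout: marker map and gene models
#'
#' Markers are evenly spaced and strictly increasing within each chromosome.
#' Genes are non-overlapping intervals, each covering at least one marker;
#' they are placed by partitioning each chromosome's markers into equal
#' blocks and letting the gene span the central portion of its block.
#'
#' @param config a [sim_config()] object.
#' @return list with `marker_map` (data.frame: marker_id, chromosome,
#'   position) and `genes` (data.frame: gene, chromosome, start, end,
#'   n_markers).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "concur_sim_config"))
  n_chr <- config$n_chromosomes
  m_per <- config$markers_per_chromosome
  sp <- config$marker_spacing
  chrom <- rep(paste0("chr", seq_len(n_chr)), each = m_per)
  pos <- rep.int(seq_len(m_per), n_chr) * sp
  marker_map <- data.frame(
    marker_id = paste0("m", seq_len(n_chr * m_per)),
    chromosome = chrom,
    position = as.integer(pos),
    stringsAsFactors = FALSE
  )
  ng <- config$n_genes
  if (ng > n_chr * m_per)
    stop("n_genes exceeds the number of markers; genes cannot be placed without overlap",
         call. = FALSE)
  if (ng == 0L) {
    genes <- data.frame(gene = character(), chromosome = character(),
                        start = integer(), end = integer(),
                        n_markers = integer(), stringsAsFactors = FALSE)
    return(list(marker_map = marker_map, genes = genes))
  }
  # spread genes across chromosomes proportionally to marker counts
  per_chr <- diff(round(seq(0, ng, length.out = n_chr + 1)))
  # guarantee no chromosome is asked for more genes than it has markers
  over <- per_chr > m_per
  if (any(over)) {
    excess <- sum(per_chr[over] - m_per)
    per_chr[over] <- m_per
    room <- which(per_chr < m_per)
    for (i in room) {
      add <- min(excess, m_per - per_chr[i]); per_chr[i] <- per_chr[i] + add
      excess <- excess - add
      if (excess == 0) break
    }
  }
  rows <- vector("list", n_chr)
  gid <- 0L
  for (c in seq_len(n_chr)) {
    g <- per_chr[c]
    if (g == 0L) next
    bounds <- round(seq(0, m_per, length.out = g + 1))
    st_m <- integer(g); en_m <- integer(g)
    for (k in seq_len(g)) {
      lo <- bounds[k] + 1L; hi <- bounds[k + 1]
      w <- hi - lo + 1L
      # central ~60% of the block, at least one marker, gap to the neighbour
      pad <- floor(w * 0.2)
      st_m[k] <- lo + pad
      en_m[k] <- max(st_m[k], hi - pad)
    }
    rows[[c]] <- data.frame(
      gene = paste0("g", gid + seq_len(g)),
      chromosome = paste0("chr", c),
      start = as.integer(st_m * sp),
      end = as.integer(en_m * sp),
      n_markers = en_m - st_m + 1L,
      stringsAsFactors = FALSE
    )
    gid <- gid + g
  }
  genes <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(genes) <- NULL
  list(marker_map = marker_map, genes = genes)
}

#' Simulate marker-level copy-number profiles
#'
#' Each sample's profile is a piecewise-constant vector of true segment
#' means (0 for neutral) plus independent Gaussian marker noise. Events are
#' drawn per chromosome with Poisson counts, geometric lengths (mean
#' `seg_mean_length` markers) and uniformly placed starts; overlapping draws
#' are resolved later-event-wins. Event states are equiprobable among gain,
#' loss, amplification and homozygous deletion.
#'
#' @param marker_map marker map from [simulate_genome()].
#' @param config a [sim_config()] object.
#' @param seed_offset integer distinguishing substreams (e.g. per cohort).
#' @return list with `log_ratios` (markers x samples matrix, dimnames set),
#'   `true_means` (same shape, noiseless), and `true_segments` (data.frame:
#'   sample_id, chromosome, start_marker, end_marker, state, magnitude).
#' @export
simulate_cnv_profiles <- function(marker_map, config, seed_offset = 0L) {
  stopifnot(inherits(config, "concur_sim_config"))
  set.seed(sub_seed(config$seed, 101L + seed_offset))
  n_mark <- nrow(marker_map)
  n_samp <- config$n_samples
  chrs <- unique(marker_map$chromosome)
  idx_by_chr <- lapply(chrs, function(ch) which(marker_map$chromosome == ch))
  names(idx_by_chr) <- chrs
  states <- c("AMP", "GAIN", "LOSS", "HOMDEL")
  mags <- c(AMP = config$amp_magnitude, GAIN = config$gain_magnitude,
            LOSS = config$loss_magnitude, HOMDEL = config$del_magnitude)
  # high-level events are rarer than low-level ones, as on real arrays
  state_prob <- c(AMP = 0.1, GAIN = 0.4, LOSS = 0.4, HOMDEL = 0.1)

  true_means <- matrix(0, n_mark, n_samp)
  seg_rows <- list()
  k <- 0L
  for (s in seq_len(n_samp)) {
    for (ch in chrs) {
      idx <- idx_by_chr[[ch]]
      m <- length(idx)
      n_ev <- stats::rpois(1L, config$seg_event_rate)
      if (n_ev == 0L) next
      for (e in seq_len(n_ev)) {
        len <- min(m, 1L + stats::rgeom(1L, 1 / config$seg_mean_length))
        start <- sample.int(m - len + 1L, 1L)
        st <- sample(states, 1L, prob = state_prob)
        span <- idx[start:(start + len - 1L)]
        true_means[span, s] <- mags[[st]]   # later event wins
        k <- k + 1L
        seg_rows[[k]] <- data.frame(
          sample_id = paste0("S", s), chromosome = ch,
          start_marker = start, end_marker = start + len - 1L,
          state = st, magnitude = mags[[st]], stringsAsFactors = FALSE)
      }
    }
  }
  noise <- matrix(stats::rnorm(n_mark * n_samp, 0, config$marker_noise_sd),
                  n_mark, n_samp)
  lr <- true_means + noise
  dimnames(lr) <- list(marker_map$marker_id, paste0("S", seq_len(n_samp)))
  dimnames(true_means) <- dimnames(lr)
  true_segments <- if (k > 0L) do.call(rbind, seg_rows) else
    data.frame(sample_id = character(), chromosome = character(),
               start_marker = integer(), end_marker = integer(),
               state = character(), magnitude = double(),
               stringsAsFactors = FALSE)
  list(log_ratios = lr, true_means = true_means, true_segments = true_segments)
}

#' Simulate gene expression with planted dosage effects
#'
#' A chosen fraction of genes is "concurrent": their expression is
#' `baseline + beta * true_copy_number + noise`. All other genes are
#' independent of copy number. When `config$target_rho` is set, beta is
#' sized per gene from the realized SD of its true copy-number values so
#' the generating (Pearson) dosage-expression correlation is approximately
#' `target_rho`; genes whose copy number never varies cannot be concurrent
#' and are excluded from selection.
#'
#' @param gene_cn genes x samples matrix of TRUE gene-level copy-number
#'   values (e.g. the per-gene mean of `true_means` markers).
#' @param genes gene table from [simulate_genome()].
#' @param config a [sim_config()] object.
#' @param seed_offset substream offset.
#' @return list with `expression` (genes x samples), `concurrent_genes`
#'   (character), and `beta` (named per-gene dosage slopes, 0 for
#'   non-concurrent genes).
#' @export
simulate_expression <- function(gene_cn, genes, config, seed_offset = 0L) {
  stopifnot(inherits(config, "concur_sim_config"))
  set.seed(sub_seed(config$seed, 211L + seed_offset))
  ng <- nrow(gene_cn); ns <- ncol(gene_cn)
  gene_ids <- rownames(gene_cn)
  cn_sd <- apply(gene_cn, 1, stats::sd)
  n_conc <- floor(config$concurrent_fraction * ng)
  eligible <- which(cn_sd > 0)
  if (n_conc > length(eligible)) n_conc <- length(eligible)
  conc_idx <- if (n_conc > 0L) sort(sample(eligible, n_conc)) else integer()
  beta <- rep(0, ng); names(beta) <- gene_ids
  if (n_conc > 0L) {
    if (!is.null(config$target_rho)) {
      rho <- config$target_rho
      beta[conc_idx] <- rho / sqrt(1 - rho^2) *
        config$expr_noise_sd / cn_sd[conc_idx]
    } else {
      beta[conc_idx] <- config$dosage_beta
    }
  }
  noise <- matrix(stats::rnorm(ng * ns, 0, config$expr_noise_sd), ng, ns)
  expression <- config$expr_baseline + beta * gene_cn + noise
  dimnames(expression) <- dimnames(gene_cn)
  list(expression = expression,
       concurrent_genes = gene_ids[conc_idx],
       beta = beta)
}

#' Simulate survival and dichotomous outcomes from a signature score
#'
#' The per-sample score is the standardized mean expression of the
#' signature genes. Event times are exponential with
#' `log hazard = log(baseline_hazard) + log_hazard_coef * score`; censoring
#' is independent Uniform(0, c) with c solved numerically so the expected
#' censoring fraction matches `censoring_rate`. Binary adverse-event labels
#' are Bernoulli with a logistic link on the same score.
#'
#' @param expr genes x samples expression matrix.
#' @param signature_genes character vector, subset of `rownames(expr)`.
#' @param config a [sim_config()] object.
#' @param seed_offset substream offset.
#' @return list with `survival` (data.frame: sample_id, time, event),
#'   `binary` (data.frame: sample_id, label), and `score` (the true linear
#'   predictor, named).
#' @export
simulate_outcomes <- function(expr, signature_genes, config, seed_offset = 0L) {
  stopifnot(inherits(config, "concur_sim_config"))
  if (length(signature_genes) == 0L && config$log_hazard_coef != 0)
    stop("empty signature with nonzero log_hazard_coef", call. = FALSE)
  if (!all(signature_genes %in% rownames(expr)))
    stop("signature_genes must all be rows of expr", call. = FALSE)
  set.seed(sub_seed(config$seed, 307L + seed_offset))
  ns <- ncol(expr)
  score <- if (length(signature_genes) > 0L) {
    raw <- colMeans(expr[signature_genes, , drop = FALSE])
    as.numeric(scale(raw))
  } else rep(0, ns)
  names(score) <- colnames(expr)
  rate <- config$baseline_hazard * exp(config$log_hazard_coef * score)
  t_event <- stats::rexp(ns, rate)
  if (config$censoring_rate <= 0) {
    time <- t_event; event <- rep(1L, ns)
  } else {
    target <- config$censoring_rate
    # E[fraction censored | event times] = mean(P(C < T_i)) = mean(pmin(T,c)/c)
    f <- function(cc) mean(pmin(t_event, cc) / cc) - target
    hi <- max(t_event) * 2
    cc <- if (f(hi) > 0) hi else stats::uniroot(f, c(1e-8, hi))$root
    cens <- stats::runif(ns, 0, cc)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  }
  time <- pmax(time, .Machine$double.eps)
  p1 <- stats::plogis(config$logistic_intercept + config$logistic_slope * score)
  label <- stats::rbinom(ns, 1L, p1)
  list(
    survival = data.frame(sample_id = colnames(expr), time = time,
                          event = event, stringsAsFactors = FALSE),
    binary = data.frame(sample_id = colnames(expr), label = label,
                        stringsAsFactors = FALSE),
    score = score
  )
}

#' Gene-level mean of a marker-level matrix over gene intervals
#'
#' Internal workhorse shared by the generator (truth side) and the
#' gene-centric CNV table (observed side).
#' @noRd
gene_level_means <- function(mat, marker_map, genes) {
  out <- matrix(NA_real_, nrow(genes), ncol(mat),
                dimnames = list(genes$gene, colnames(mat)))
  n_used <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    sel <- marker_map$chromosome == genes$chromosome[i] &
      marker_map$position >= genes$start[i] &
      marker_map$position <= genes$end[i]
    n_used[i] <- sum(sel)
    if (n_used[i] > 0L)
      out[i, ] <- colMeans(mat[sel, , drop = FALSE])
  }
  attr(out, "n_markers") <- stats::setNames(n_used, genes$gene)
  out
}

#' Simulate one complete paired cohort
#'
#' Convenience wrapper running genome, CNV, expression and outcome
#' generation with a shared configuration. Layout (genome, concurrent set,
#' signature membership) can be supplied so several cohorts share truth.
#'
#' @param config a [sim_config()] object.
#' @param genome optional precomputed [simulate_genome()] output.
#' @param seed_offset substream offset (distinguishes cohorts).
#' @return list with elements `marker_map`, `genes`, `log_ratios`,
#'   `true_means`, `true_segments`, `gene_cn_true`, `expression`,
#'   `concurrent_genes`, `beta`, `signature_genes`, `survival`, `binary`,
#'   `score`.
#' @export
simulate_cohort <- function(config, genome = NULL, seed_offset = 0L) {
  if (is.null(genome)) genome <- simulate_genome(config)
  cnv <- simulate_cnv_profiles(genome$marker_map, config, seed_offset)
  gene_cn_true <- gene_level_means(cnv$true_means, genome$marker_map,
                                   genome$genes)
  ex <- simulate_expression(gene_cn_true, genome$genes, config, seed_offset)
  sig_n <- min(config$signature_size, length(ex$concurrent_genes))
  signature_genes <- utils::head(ex$concurrent_genes, sig_n)
  out <- simulate_outcomes(ex$expression, signature_genes, config, seed_offset)
  c(genome,
    cnv,
    list(gene_cn_true = gene_cn_true),
    ex,
    list(signature_genes = signature_genes),
    out)
}

#' Simulate multiple cohorts sharing one ground truth
#'
#' Emulates a multi-cohort design: a small and a large discovery cohort plus
#' optional validation sets. All cohorts share the genome layout and the
#' true concurrent/signature gene sets; noise, CNV events and outcomes are
#' independent per cohort. Expression platforms may carry several probes per
#' gene (probe 1 carries the signal; further probes are attenuated copies
#' with fresh noise, so IQR-based probe reduction prefers probe 1).
#'
#' @param config a [sim_config()] object (its `n_samples` is overridden per
#'   cohort).
#' @param cohort_sizes integer vector of sample sizes, length >= 2.
#' @param probes_per_gene probes per gene on the expression platform
#'   (1 = gene-level rows).
#' @return list of cohort lists as from [simulate_cohort()]; cohorts beyond
#'   the first reuse the first cohort's concurrent/signature sets. When
#'   `probes_per_gene > 1` each cohort also carries `probe_expression` and
#'   `probe_to_gene`.
#' @export
simulate_multi_cohort <- function(config, cohort_sizes, probes_per_gene = 1L) {
  if (length(cohort_sizes) < 2L)
    stop("need at least 2 cohort sizes", call. = FALSE)
  genome <- simulate_genome(config)
  cohorts <- vector("list", length(cohort_sizes))
  shared_conc <- NULL; shared_sig <- NULL; shared_beta_genes <- NULL
  for (i in seq_along(cohort_sizes)) {
    cfg_i <- config
    cfg_i$n_samples <- as.integer(cohort_sizes[i])
    co <- simulate_cohort(cfg_i, genome = genome, seed_offset = i * 1000L)
    if (i == 1L) {
      shared_conc <- co$concurrent_genes
      shared_sig <- co$signature_genes
    } else {
      # re-express with the FIRST cohort's concurrent set so truth is shared
      set.seed(sub_seed(config$seed, 211L + i * 1000L + 7L))
      cn_sd <- apply(co$gene_cn_true, 1, stats::sd)
      beta <- rep(0, nrow(co$gene_cn_true))
      names(beta) <- rownames(co$gene_cn_true)
      usable <- intersect(shared_conc, names(beta)[cn_sd > 0])
      if (!is.null(config$target_rho)) {
        rho <- config$target_rho
        beta[usable] <- rho / sqrt(1 - rho^2) *
          config$expr_noise_sd / cn_sd[usable]
      } else beta[usable] <- config$dosage_beta
      noise <- matrix(stats::rnorm(length(beta) * cfg_i$n_samples, 0,
                                   config$expr_noise_sd),
                      length(beta), cfg_i$n_samples)
      co$expression <- config$expr_baseline + beta * co$gene_cn_true + noise
      dimnames(co$expression) <- dimnames(co$gene_cn_true)
      co$concurrent_genes <- shared_conc
      co$beta <- beta
      co$signature_genes <- shared_sig
      oc <- simulate_outcomes(co$expression, shared_sig, cfg_i,
                              seed_offset = i * 1000L + 13L)
      co$survival <- oc$survival; co$binary <- oc$binary; co$score <- oc$score
    }
    if (probes_per_gene > 1L) {
      set.seed(sub_seed(config$seed, 401L + i * 1000L))
      ng <- nrow(co$expression)
      probe_ids <- paste0(rep(rownames(co$expression), each = probes_per_gene),
                          "_p", rep(seq_len(probes_per_gene), ng))
      pe <- matrix(NA_real_, ng * probes_per_gene, ncol(co$expression),
                   dimnames = list(probe_ids, colnames(co$expression)))
      for (p in seq_len(probes_per_gene)) {
        rows <- seq(p, ng * probes_per_gene, by = probes_per_gene)
        att <- if (p == 1L) 1 else 0.4
        pe[rows, ] <- config$expr_baseline +
          att * (co$expression - config$expr_baseline) +
          matrix(stats::rnorm(ng * ncol(co$expression), 0,
                              if (p == 1L) 0 else 0.2 * config$expr_noise_sd),
                 ng, ncol(co$expression))
      }
      co$probe_expression <- pe
      co$probe_to_gene <- stats::setNames(
        rep(rownames(co$expression), each = probes_per_gene), probe_ids)
    }
    cohorts[[i]] <- co
  }
  cohorts
}
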