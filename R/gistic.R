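#' Per-marker G scores for recurrent gains and losses
#'
#' Amplitude-weighted aberration frequency: at each marker,
#' `G_gain = sum over samples of max(seg_value - theta_gain, 0)` and
#' `G_loss = sum of max(theta_loss - seg_value, 0)`, where `seg_value` is
#' the sample's segmented log ratio at that marker.
#'
#' @param seg_values markers x samples matrix of segmented log ratios.
#' @param theta_gain,theta_loss amplitude thresholds (defaults +0.1 / -0.1).
#' @return data.frame: marker (row index or rowname), g_gain, g_loss.
#' @export
g_scores <- function(seg_values, theta_gain = 0.1, theta_loss = -0.1) {
  g_gain <- rowSums(pmax(seg_values - theta_gain, 0))
  g_loss <- rowSums(pmax(theta_loss - seg_values, 0))
  data.frame(
    marker = if (!is.null(rownames(seg_values))) rownames(seg_values)
             else as.character(seq_len(nrow(seg_values))),
    g_gain = g_gain, g_loss = g_loss,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Resampled null for G scores with per-marker p/q and significant regions
#'
#' The null is built by independently permuting each sample's marker values
#' across the genome `n_perm` times and recomputing G scores; all null
#' values (across markers and resamples) are pooled per direction, and each
#' observed marker's p is the fraction of the pooled null at or above it.
#' q-values are Benjamini-Hochberg over markers; significant regions are
#' maximal runs of markers with `q < q_cut` on one chromosome.
#'
#' @param seg_values markers x samples matrix of segmented log ratios.
#' @param marker_map matching marker map (chromosome, position).
#' @param n_perm number of resamplings (>= 100 recommended).
#' @param seed integer seed.
#' @param theta_gain,theta_loss amplitude thresholds passed to [g_scores()].
#' @param q_cut q-value cutoff defining significant regions.
#' @return list with `scores` (data.frame marker, chromosome, position,
#'   g_gain, g_loss, p_gain, p_loss, q_gain, q_loss) and `regions`
#'   (data.frame chromosome, start, end, direction, min_q).
#' @export
gistic_null <- function(seg_values, marker_map, n_perm = 10000, seed = 1L,
                        theta_gain = 0.1, theta_loss = -0.1, q_cut = 0.25) {
  if (ncol(seg_values) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: unstable null tail")
  set.seed(sub_seed(seed, 17L))
  obs <- g_scores(seg_values, theta_gain, theta_loss)
  n_mark <- nrow(seg_values)
  # accumulate pooled-null exceedance counts against sorted observed scores
  og <- sort(obs$g_gain); ol <- sort(obs$g_loss)
  cnt_g <- numeric(n_mark); cnt_l <- numeric(n_mark)
  perm <- seg_values
  for (b in seq_len(n_perm)) {
    for (s in seq_len(ncol(seg_values)))
      perm[, s] <- seg_values[sample.int(n_mark), s]
    ng <- rowSums(pmax(perm - theta_gain, 0))
    nl <- rowSums(pmax(theta_loss - perm, 0))
    # of the n_mark null values this round, how many are >= each sorted obs
    cnt_g <- cnt_g + (n_mark - findInterval(og, sort(ng), left.open = TRUE))
    cnt_l <- cnt_l + (n_mark - findInterval(ol, sort(nl), left.open = TRUE))
  }
  total <- as.double(n_mark) * n_perm
  p_sorted_g <- cnt_g / total
  p_sorted_l <- cnt_l / total
  # map back from sorted order to marker order
  p_gain <- p_sorted_g[match(obs$g_gain, og)]
  p_loss <- p_sorted_l[match(obs$g_loss, ol)]
  q_gain <- stats::p.adjust(p_gain, "BH")
  q_loss <- stats::p.adjust(p_loss, "BH")
  scores <- data.frame(
    marker = obs$marker, chromosome = marker_map$chromosome,
    position = marker_map$position,
    g_gain = obs$g_gain, g_loss = obs$g_loss,
    p_gain = p_gain, p_loss = p_loss,
    q_gain = q_gain, q_loss = q_loss,
    stringsAsFactors = FALSE)
  regions <- rbind(
    sig_regions(scores, scores$q_gain < q_cut, "gain"),
    sig_regions(scores, scores$q_loss < q_cut, "loss"))
  list(scores = scores, regions = regions)
}

# maximal runs of flagged markers within a chromosome
sig_regions <- function(scores, flag, direction) {
  out <- list(); k <- 0L
  for (ch in unique(scores$chromosome)) {
    idx <- which(scores$chromosome == ch & flag)
    if (length(idx) == 0L) next
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (r in runs) {
      k <- k + 1L
      qcol <- if (direction == "gain") scores$q_gain else scores$q_loss
      out[[k]] <- data.frame(
        chromosome = ch,
        start = scores$position[r[1L]],
        end = scores$position[r[length(r)]],
        direction = direction,
        min_q = min(qcol[r]),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), direction = character(),
                      min_q = double(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Gene-set enrichment in recurrent-CNV regions by random sampling
#'
#' The observed statistic for a set is the number of member genes whose
#' interval overlaps any region; the null redraws gene sets of equal size
#' uniformly from the universe of genes with coordinates. Empirical p uses
#' the add-one correction `(1 + #null >= observed) / (1 + n_perm)`.
#'
#' @param regions data.frame (chromosome, start, end), e.g. from
#'   [gistic_null()].
#' @param genes gene table (gene, chromosome, start, end) — the universe.
#' @param gene_sets named list of character vectors of gene symbols.
#' @param n_perm random samplings.
#' @param seed integer seed.
#' @return data.frame: set, size (members in universe), overlap, p. Sets
#'   with no gene in the universe get NA p.
#' @export
region_enrichment <- function(regions, genes, gene_sets, n_perm = 1000,
                              seed = 1L) {
  set.seed(sub_seed(seed, 29L))
  in_region <- rep(FALSE, nrow(genes))
  if (nrow(regions) > 0L) {
    for (r in seq_len(nrow(regions))) {
      in_region <- in_region |
        (genes$chromosome == regions$chromosome[r] &
           genes$start <= regions$end[r] & genes$end >= regions$start[r])
    }
  }
  universe <- genes$gene
  res <- data.frame(set = names(gene_sets), size = NA_integer_,
                    overlap = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(gene_sets)) {
    members <- intersect(gene_sets[[i]], universe)
    res$size[i] <- length(members)
    if (length(members) == 0L) next
    obs <- sum(in_region[match(members, universe)])
    res$overlap[i] <- obs
    null_ge <- 0L
    for (b in seq_len(n_perm)) {
      draw <- sample.int(length(universe), length(members))
      if (sum(in_region[draw]) >= obs) null_ge <- null_ge + 1L
    }
    res$p[i] <- perm_pvalue(null_ge, n_perm)
  }
  res
}
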