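#' Smooth singleton outliers in a log-ratio profile
#'
#' Points lying more than `k` SD above (or below) BOTH neighbours are shrunk
#' toward the nearer neighbour, landing `offset` SD away from it; everything
#' else is unchanged. Applied per chromosome; chromosomes with fewer than 3
#' markers are returned unchanged. The noise SD defaults to a robust
#' estimate (1.4826 x MAD of first differences / sqrt(2)), falling back to
#' the sample SD when that is zero.
#'
#' @param profile numeric vector of log ratios, aligned to `marker_map`.
#' @param marker_map data.frame with columns chromosome, position.
#' @param k outlier threshold in SD units.
#' @param offset shrink target distance from the nearer neighbour, in SD.
#' @param sd_estimate optional fixed SD; overrides the robust estimate.
#' @return smoothed numeric vector.
#' @export
smooth_outliers <- function(profile, marker_map, k = 4, offset = 2,
                            sd_estimate = NULL) {
  stopifnot(length(profile) == nrow(marker_map))
  out <- profile
  for (ch in unique(marker_map$chromosome)) {
    idx <- which(marker_map$chromosome == ch)
    m <- length(idx)
    if (m < 3L) next
    x <- profile[idx]
    s <- sd_estimate
    if (is.null(s)) {
      s <- 1.4826 * stats::median(abs(diff(x))) / sqrt(2)
      if (!is.finite(s) || s == 0) s <- stats::sd(x)
      if (!is.finite(s) || s == 0) next
    }
    for (i in 2:(m - 1L)) {
      dl <- x[i] - x[i - 1L]; dr <- x[i] - x[i + 1L]
      if ((dl > k * s && dr > k * s) || (dl < -k * s && dr < -k * s)) {
        nb <- if (abs(dl) <= abs(dr)) x[i - 1L] else x[i + 1L]
        out[idx[i]] <- nb + sign(x[i] - nb) * offset * s
      }
    }
  }
  out
}

# max arc statistic for circular binary segmentation on one segment.
# Arcs are contiguous runs (i, j] on the circle formed by joining the two
# ends; with cumulative sums every proper arc statistic is
#   Z(i,j) = (mean_arc - mean_rest) / sqrt(1/k + 1/(m-k))
# (constant-variance form; the permutation reference makes the scale
# irrelevant). Returns the maximizing arc and |Z|.
arc_stat <- function(x, pairs) {
  S <- c(0, cumsum(x))
  m <- length(x)
  tot <- S[m + 1L]
  k <- pairs$k
  arcsum <- S[pairs$j + 1L] - S[pairs$i + 1L]
  z <- (arcsum / k - (tot - arcsum) / (m - k)) / sqrt(1 / k + 1 / (m - k))
  az <- abs(z)
  best <- which.max(az)
  list(stat = az[best], i = pairs$i[best], j = pairs$j[best], all = az)
}

arc_pairs <- function(m) {
  # all proper arcs (i, j], 0 <= i < j <= m, excluding the full segment
  i <- rep.int(0:(m - 1L), m:1)
  j <- sequence(m:1) + i
  keep <- !(i == 0L & j == m)
  list(i = i[keep], j = j[keep], k = (j - i)[keep])
}

# permutation p-value of the max arc statistic with early stopping:
# once enough null maxima exceed the observed to force p > alpha the
# remaining draws cannot change the accept/reject decision.
arc_perm_test <- function(x, pairs, obs, alpha, n_perm) {
  cut <- floor(alpha * (n_perm + 1))  # exceedances allowed while p <= alpha
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    xp <- x[sample.int(length(x))]
    S <- c(0, cumsum(xp))
    m <- length(xp)
    arcsum <- S[pairs$j + 1L] - S[pairs$i + 1L]
    z <- abs((arcsum / pairs$k - (S[m + 1L] - arcsum) / (m - pairs$k)) /
               sqrt(1 / pairs$k + 1 / (m - pairs$k)))
    if (max(z) >= obs) {
      n_ge <- n_ge + 1L
      if (n_ge > cut) return(1)  # decision fixed: not significant
    }
  }
  n_ge / n_perm
}

#' Circular binary segmentation of one sample's profile
#'
#' Recursive change-point detection per chromosome: the candidate split is
#' the arc maximizing the two-sample statistic over all arcs of the circled
#' segment; it is accepted iff its within-segment permutation p-value is at
#' most `alpha`, and the procedure recurses on the resulting pieces until no
#' split is accepted. Segment means are arithmetic means of member markers.
#'
#' @param profile numeric log-ratio vector aligned to `marker_map`; must be
#'   finite.
#' @param marker_map data.frame with chromosome, position (positions
#'   strictly increasing within chromosome).
#' @param alpha significance level for accepting a change point.
#' @param n_perm permutations for the reference distribution.
#' @param seed integer seed for the permutation stream.
#' @param sample_id label stored on the output segments.
#' @return data.frame of segments: sample_id, chromosome, start_pos,
#'   end_pos, n_markers, seg_mean; contiguous and exhaustive per chromosome.
#' @export
cbs_segment <- function(profile, marker_map, alpha = 0.01, n_perm = 1000,
                        seed = 1L, sample_id = "S1") {
  if (any(!is.finite(profile)))
    stop("profile contains non-finite values", call. = FALSE)
  stopifnot(length(profile) == nrow(marker_map))
  set.seed(sub_seed(seed, 7L))
  res <- list(); rn <- 0L
  for (ch in unique(marker_map$chromosome)) {
    idx <- which(marker_map$chromosome == ch)
    x <- profile[idx]
    pos <- marker_map$position[idx]
    bounds <- segment_recurse(x, alpha, n_perm)
    for (b in seq_len(nrow(bounds))) {
      a <- bounds[b, 1L]; z <- bounds[b, 2L]
      rn <- rn + 1L
      res[[rn]] <- data.frame(
        sample_id = sample_id, chromosome = ch,
        start_pos = pos[a], end_pos = pos[z],
        n_markers = z - a + 1L, seg_mean = mean(x[a:z]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# returns matrix of (start, end) marker offsets partitioning 1..length(x)
segment_recurse <- function(x, alpha, n_perm) {
  m <- length(x)
  if (m < 2L) return(matrix(c(1L, m), 1L))
  pairs <- arc_pairs(m)
  best <- arc_stat(x, pairs)
  if (!is.finite(best$stat) || best$stat == 0)
    return(matrix(c(1L, m), 1L))
  p <- arc_perm_test(x, pairs, best$stat, alpha, n_perm)
  if (p > alpha) return(matrix(c(1L, m), 1L))
  # split at the arc boundaries: up to three pieces
  cuts <- sort(unique(c(best$i, best$j)))
  cuts <- cuts[cuts > 0L & cuts < m]
  if (length(cuts) == 0L) return(matrix(c(1L, m), 1L))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, m)
  out <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    sub <- segment_recurse(x[starts[s]:ends[s]], alpha, n_perm)
    out[[s]] <- sub + starts[s] - 1L
  }
  do.call(rbind, out)
}

#' Merge statistically indistinguishable segment levels
#'
#' Genome-wide per sample: repeatedly find the pair of segment levels whose
#' member-marker distributions are least distinguishable (largest Wilcoxon
#' rank-sum p) and merge them while that p exceeds `merge_p`; means are
#' recomputed from the pooled markers. Adjacent segments that end up on the
#' same level are joined, so the output still tiles each chromosome.
#'
#' @param segments data.frame as returned by [cbs_segment()].
#' @param profile the log-ratio vector the segments were fitted to.
#' @param marker_map matching marker map.
#' @param merge_p merge threshold on the rank-sum p-value.
#' @return data.frame of segments, same columns as input.
#' @export
merge_levels <- function(segments, profile, marker_map, merge_p = 0.05) {
  if (nrow(segments) <= 1L) return(segments)
  seg_markers <- function(r) {
    which(marker_map$chromosome == segments$chromosome[r] &
            marker_map$position >= segments$start_pos[r] &
            marker_map$position <= segments$end_pos[r])
  }
  members <- lapply(seq_len(nrow(segments)), seg_markers)
  level <- seq_len(nrow(segments))  # each segment starts as its own level
  repeat {
    lv <- sort(unique(level))
    if (length(lv) <= 1L) break
    vals <- lapply(lv, function(l)
      profile[unlist(members[level == l], use.names = FALSE)])
    best_p <- -1; best_pair <- NULL
    for (a in seq_along(lv)[-length(lv)]) for (b in (a + 1L):length(lv)) {
      p <- suppressWarnings(
        stats::wilcox.test(vals[[a]], vals[[b]], exact = FALSE)$p.value)
      if (is.na(p)) p <- 1
      if (p > best_p) { best_p <- p; best_pair <- c(a, b) }
    }
    if (best_p <= merge_p) break
    level[level == lv[best_pair[2L]]] <- lv[best_pair[1L]]
  }
  # recompute means per level and join adjacent same-level segments
  out <- segments
  for (l in unique(level)) {
    mk <- unlist(members[level == l], use.names = FALSE)
    out$seg_mean[level == l] <- mean(profile[mk])
  }
  keep <- rep(TRUE, nrow(out))
  for (r in 2:nrow(out)) {
    prev <- max(which(keep[seq_len(r - 1L)]))
    if (out$chromosome[prev] == out$chromosome[r] &&
        level[prev] == level[r]) {
      out$end_pos[prev] <- out$end_pos[r]
      out$n_markers[prev] <- out$n_markers[prev] + out$n_markers[r]
      keep[r] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median absolute deviation of an array's log ratios
#'
#' Unscaled by default (no 1.4826 consistency factor): the median of
#' absolute deviations from the median.
#'
#' @param profile numeric vector (NAs dropped).
#' @param sample_id label for the result.
#' @param scaled apply the 1.4826 normal-consistency factor.
#' @return list with `sample_id` and `mad`.
#' @export
compute_mad <- function(profile, sample_id = "S1", scaled = FALSE) {
  x <- profile[is.finite(profile)]
  if (length(x) == 0L) stop("no finite values in profile", call. = FALSE)
  m <- stats::median(abs(x - stats::median(x)))
  if (scaled) m <- m * 1.4826
  list(sample_id = sample_id, mad = m)
}

#' Call five-state CNV from segment means and per-array MAD
#'
#' Strict thresholds on the segment mean: amplification above `1 * mad`,
#' homozygous deletion below `-1 * mad`, gain above `0.5 * mad`, loss below
#' `-0.5 * mad`, neutral otherwise. A mean exactly at a threshold falls to
#' the lower-magnitude state. `mad = 0` degenerates every nonzero mean to a
#' high-level call; a warning is emitted.
#'
#' @param segments data.frame with a `seg_mean` column.
#' @param noise list with `mad` as from [compute_mad()] (or a single number).
#' @param high_mult,low_mult MAD multipliers for high/low-level calls.
#' @return the segments data.frame with a `state` column appended
#'   (AMP/GAIN/NEUTRAL/LOSS/HOMDEL).
#' @export
call_cnv <- function(segments, noise, high_mult = 1, low_mult = 0.5) {
  mad <- if (is.list(noise)) noise$mad else noise
  if (mad == 0)
    warning("MAD is zero: every nonzero segment mean becomes a high-level call")
  sm <- segments$seg_mean
  state <- rep("NEUTRAL", length(sm))
  state[sm > low_mult * mad] <- "GAIN"
  state[sm > high_mult * mad] <- "AMP"
  state[sm < -low_mult * mad] <- "LOSS"
  state[sm < -high_mult * mad] <- "HOMDEL"
  segments$state <- state
  segments
}

#' Gene-centric copy-number table
#'
#' Per gene and sample, the arithmetic mean of log ratios over markers whose
#' position lies within the gene interval (1-based inclusive, containment,
#' strand ignored). Genes covering no marker — including genes on
#' chromosomes absent from the map — are rows of NA, never zero-filled.
#'
#' @param log_ratios markers x samples matrix aligned to `marker_map`.
#' @param marker_map data.frame with chromosome, position.
#' @param genes data.frame with gene, chromosome, start, end.
#' @return genes x samples matrix with attribute `n_markers` (markers used
#'   per gene).
#' @export
gene_centric_table <- function(log_ratios, marker_map, genes) {
  stopifnot(nrow(log_ratios) == nrow(marker_map))
  gene_level_means(log_ratios, marker_map, genes)
}

#' Per-marker gain and loss frequencies across samples
#'
#' For each marker, the fraction of samples whose covering segment is called
#' GAIN or AMP, and the fraction called LOSS or HOMDEL. The two are mutually
#' exclusive so their sum never exceeds 1.
#'
#' @param calls data.frame of called segments across samples (output of
#'   [call_cnv()], possibly row-bound over samples).
#' @param marker_map marker map covering all call coordinates.
#' @return data.frame: marker_id, chromosome, position, gain_freq,
#'   loss_freq.
#' @export
frequency_profile <- function(calls, marker_map) {
  samples <- unique(calls$sample_id)
  n <- length(samples)
  gain <- loss <- numeric(nrow(marker_map))
  for (r in seq_len(nrow(calls))) {
    if (calls$state[r] == "NEUTRAL") next
    sel <- marker_map$chromosome == calls$chromosome[r] &
      marker_map$position >= calls$start_pos[r] &
      marker_map$position <= calls$end_pos[r]
    if (calls$state[r] %in% c("GAIN", "AMP")) gain[sel] <- gain[sel] + 1
    else loss[sel] <- loss[sel] + 1
  }
  data.frame(marker_id = marker_map$marker_id,
             chromosome = marker_map$chromosome,
             position = marker_map$position,
             gain_freq = gain / n, loss_freq = loss / n,
             stringsAsFactors = FALSE)
}
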