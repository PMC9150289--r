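#' Read and write tab-delimited numeric matrices
#'
#' Matrices are stored with a header line (`id` then sample ids) and one
#' row per marker/probe/gene. Round-trips preserve values to full
#' precision and ids exactly.
#'
#' @param x numeric matrix with rownames and colnames.
#' @param path file path.
#' @return `read_matrix` returns the matrix; `write_matrix` its path,
#'   invisibly.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop(sprintf("duplicated row ids in %s (first at line %d)", path,
                 which(duplicated(df$id))[1L] + 1L), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Read and write segment (SEG-dialect) tables
#'
#' Columns: sample_id, chromosome, start_pos, end_pos, n_markers, seg_mean,
#' tab-delimited with a header; called segments carry a seventh `state`
#' column. Coordinates are 1-based inclusive.
#'
#' @param segments segment data.frame.
#' @param path file path.
#' @export
write_seg <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "chromosome", "start_pos", "end_pos", "n_markers",
            "seg_mean")
  if (!all(need %in% names(df)))
    stop("SEG file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  bad <- which(df$end_pos < df$start_pos)
  if (length(bad) > 0L)
    stop(sprintf("SEG parse error at line %d: end < start", bad[1L] + 1L),
         call. = FALSE)
  df
}

#' Read and write BED-like gene tables
#'
#' Columns: gene, chromosome, start, end (1-based inclusive; a zero-length
#' gene with start == end covers markers at exactly that position).
#'
#' @param genes gene data.frame.
#' @param path file path.
#' @export
write_bed_genes <- function(genes, path) {
  utils::write.table(genes[, c("gene", "chromosome", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_genes
#' @export
read_bed_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$gene))
    stop(sprintf("duplicated gene id at line %d",
                 which(duplicated(df$gene))[1L] + 1L), call. = FALSE)
  bad <- which(df$end < df$start)
  if (length(bad) > 0L)
    stop(sprintf("gene parse error at line %d: end < start", bad[1L] + 1L),
         call. = FALSE)
  df
}

#' Read and write outcome tables
#'
#' Survival outcomes: sample_id, time, event (0/1). Dichotomous outcomes:
#' sample_id, label (0/1).
#'
#' @param outcome outcome data.frame.
#' @param path file path.
#' @export
write_outcomes <- function(outcome, path) {
  utils::write.table(outcome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("outcome file missing sample_id column", call. = FALSE)
  if ("time" %in% names(df)) {
    if (any(df$time <= 0))
      stop(sprintf("outcome parse error at line %d: time <= 0",
                   which(df$time <= 0)[1L] + 1L), call. = FALSE)
    if (!all(df$event %in% c(0L, 1L)))
      stop("event must be 0/1", call. = FALSE)
  } else if ("label" %in% names(df)) {
    if (!all(df$label %in% c(0L, 1L)))
      stop("label must be 0/1", call. = FALSE)
  } else stop("outcome file needs time/event or label columns", call. = FALSE)
  df
}
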