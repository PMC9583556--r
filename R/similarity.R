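#' Overlap score between two extended peak datasets
#'
#' Symmetric score S_o = 1/2 * (o/|d_i| + o/|d_j|), where |d| is the number
#' of (extended) peaks in a dataset and o is a single symmetric overlap
#' count: the number of intersecting window pairs, capped at
#' min(|d_i|, |d_j|) so the score stays in [0, 1]. A base-pair variant is
#' available via `unit = "bp"`, where o is the overlap fraction numerator in
#' basepairs and |d| the dataset's covered basepairs.
#'
#' @param wi,wj BED-style data.frames of extended windows.
#' @param unit "pairs" (default) or "bp".
#' @return Score in [0, 1].
#' @export
overlap_score <- function(wi, wj, unit = c("pairs", "bp")) {
  unit <- match.arg(unit)
  if (nrow(wi) == 0L || nrow(wj) == 0L) {
    stop("overlap score undefined for an empty dataset")
  }
  if (unit == "pairs") {
    hits <- GenomicRanges::findOverlaps(bed_to_gr(wi), bed_to_gr(wj))
    o <- min(length(hits), nrow(wi), nrow(wj))
    0.5 * (o / nrow(wi) + o / nrow(wj))
  } else {
    o <- coverage_bp(interval_intersect(wi, wj))
    0.5 * (o / coverage_bp(wi) + o / coverage_bp(wj))
  }
}

#' Pairwise overlap matrix over many datasets
#'
#' @param window_sets Named list of BED-style window data.frames.
#' @param unit Passed to [overlap_score()].
#' @param file Optional path; if given, the matrix is written as TSV.
#' @param order_by_clustering If TRUE, rows/columns of the written TSV are
#'   ordered by average-linkage clustering on 1 - S_o (a QC convenience).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
overlap_matrix <- function(window_sets, unit = "pairs", file = NULL,
                           order_by_clustering = FALSE) {
  n <- length(window_sets)
  stopifnot(n >= 2L, !is.null(names(window_sets)))
  m <- diag(1, n)
  dimnames(m) <- list(names(window_sets), names(window_sets))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- overlap_score(window_sets[[i]], window_sets[[j]], unit = unit)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  if (!is.null(file)) {
    ord <- seq_len(n)
    if (order_by_clustering) {
      ord <- stats::hclust(stats::as.dist(1 - m), method = "average")$order
    }
    out <- data.frame(dataset_id = rownames(m)[ord],
                      m[ord, ord, drop = FALSE], check.names = FALSE)
    data.table::fwrite(out, file, sep = "\t", quote = FALSE)
  }
  m
}
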