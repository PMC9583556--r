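#' Read one ENCODE narrowPeak (BED6+4) dataset
#'
#' One file holds the called peaks of a single (TF, cell type) ChIP-seq
#' experiment. Coordinates are 0-based half-open. The per-peak enrichment
#' score is read from `enrichment_col` (default column 7, the narrowPeak
#' signalValue column); column 10 is the summit offset relative to `start`,
#' with -1 meaning "no summit called".
#'
#' @param path Path to a narrowPeak file (>= 10 tab-separated columns).
#' @param dataset_id Unique dataset label; defaults to the file name.
#' @param tf,cell_type Experiment annotation labels.
#' @param enrichment_col Column holding the enrichment score used for
#'   filtering (default 7).
#' @return A `PeakDataset`: list with `dataset_id`, `tf`, `cell_type` and a
#'   `peaks` data.frame (chrom, start, end, name, enrichment, summit_offset;
#'   `summit_offset` is `NA` when absent).
#' @export
read_narrowpeak <- function(path, dataset_id = NULL, tf = NA_character_,
                            cell_type = NA_character_, enrichment_col = 7L) {
  if (!file.exists(path)) {
    stop("narrowPeak file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 10L)
  if (length(bad)) {
    stop("narrowPeak parse error in ", path, ": line ", bad[1],
         " has ", ncol[bad[1]], " columns (>= 10 required)")
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("narrowPeak parse error in ", path, ": non-numeric coordinates at line ",
         bad[1])
  }
  enrichment <- suppressWarnings(as.numeric(get(enrichment_col)))
  summit <- suppressWarnings(as.numeric(get(10)))
  summit[!is.na(summit) & summit < 0] <- NA
  peaks <- data.frame(
    chrom = get(1), start = start, end = end, name = get(4),
    enrichment = enrichment, summit_offset = summit,
    stringsAsFactors = FALSE
  )
  if (any(peaks$start >= peaks$end)) {
    stop("narrowPeak parse error in ", path, ": start >= end at line ",
         which(peaks$start >= peaks$end)[1])
  }
  structure(
    list(dataset_id = dataset_id %||% basename(path), tf = tf,
         cell_type = cell_type, peaks = peaks),
    class = "PeakDataset"
  )
}

#' @export
print.PeakDataset <- function(x, ...) {
  cat(sprintf("<PeakDataset %s> tf=%s cell_type=%s peaks=%d\n",
              x$dataset_id, x$tf, x$cell_type, nrow(x$peaks)))
  invisible(x)
}

#' Filter a peak dataset by enrichment and minimum peak count
#'
#' Peaks with enrichment strictly below `min_enrichment` are removed; if
#' fewer than `min_peaks` peaks survive the whole dataset is rejected
#' (returned as `NULL`) and excluded from all downstream stages. Both
#' thresholds are strict inequalities: enrichment exactly 20 is retained and
#' exactly 20 surviving peaks keep the dataset.
#'
#' @param ds A `PeakDataset`.
#' @param min_enrichment Minimum enrichment score kept (default 20).
#' @param min_peaks Minimum surviving peak count (default 20).
#' @return The filtered `PeakDataset`, or `NULL` if rejected.
#' @export
filter_dataset <- function(ds, min_enrichment = 20, min_peaks = 20) {
  stopifnot(inherits(ds, "PeakDataset"))
  keep <- !is.na(ds$peaks$enrichment) & ds$peaks$enrichment >= min_enrichment
  ds$peaks <- ds$peaks[keep, , drop = FALSE]
  if (nrow(ds$peaks) < min_peaks) {
    message("dataset ", ds$dataset_id, " rejected: ", nrow(ds$peaks),
            " peaks survive enrichment >= ", min_enrichment,
            " (need >= ", min_peaks, ")")
    return(NULL)
  }
  ds
}

#' Replace peaks by fixed-length windows centered on summits
#'
#' Each peak becomes a window of `length` bp centered on its summit when a
#' summit offset is present, else on the interval midpoint. Windows are
#' clipped (not shifted) at chromosome ends, so clipped windows may be
#' shorter than `length`.
#'
#' @param ds A `PeakDataset`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param length Window length in bp (default 1000).
#' @return BED-style data.frame (chrom, start, end, name) of windows, one
#'   per peak, in input order.
#' @export
extend_peaks <- function(ds, chrom_sizes, length = 1000) {
  stopifnot(inherits(ds, "PeakDataset"))
  p <- ds$peaks
  unknown <- setdiff(unique(p$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("peak on unknown chromosome: ", unknown[1])
  }
  center <- ifelse(is.na(p$summit_offset),
                   floor((p$start + p$end) / 2),
                   p$start + p$summit_offset)
  start <- pmax(0, center - floor(length / 2))
  end <- pmin(unname(chrom_sizes[p$chrom]), center - floor(length / 2) + length)
  data.frame(chrom = p$chrom, start = start, end = end, name = p$name,
             stringsAsFactors = FALSE)
}
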