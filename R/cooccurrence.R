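#' Co-occurrence score of two motifs found in the same dataset
#'
#' Sc = o / max(|M_i|, |M_j|), where |M| is the number of distinct peaks
#' containing at least one site of the motif and o the number of distinct
#' peaks containing sites of both. Distinct peaks are counted, not site
#' occurrences.
#'
#' @param mi,mj `Motif` objects from the same dataset.
#' @return Score in [0, 1].
#' @export
cooccurrence_score <- function(mi, mj) {
  pi_ <- unique(mi$sites$peak_id)
  pj_ <- unique(mj$sites$peak_id)
  if (length(pi_) == 0L || length(pj_) == 0L) {
    stop("co-occurrence undefined: motif with zero peaks")
  }
  length(intersect(pi_, pj_)) / max(length(pi_), length(pj_))
}

#' Select co-occurring motif pairs (CPs) within one dataset
#'
#' All unordered motif pairs with Sc strictly greater than `cutoff` are
#' kept. Motifs appearing in no CP are discarded from downstream stages; a
#' dataset retaining no CP is excluded entirely (handled by the caller via
#' the empty return).
#'
#' @param motifs List of `Motif` objects of one dataset (>= 2 for any CP).
#' @param cutoff Sc cutoff, strict (default 0.7).
#' @return data.frame (dataset_id, motif_i, motif_j, sc), zero rows when no
#'   pair passes; attribute `kept_motifs` holds the motif ids in some CP.
#' @export
select_cps <- function(motifs, cutoff = 0.7) {
  empty <- data.frame(dataset_id = character(), motif_i = character(),
                      motif_j = character(), sc = numeric(),
                      stringsAsFactors = FALSE)
  if (length(motifs) < 2L) {
    attr(empty, "kept_motifs") <- character()
    return(empty)
  }
  ids <- vapply(motifs, `[[`, "", "motif_id")
  pairs <- utils::combn(length(motifs), 2)
  sc <- apply(pairs, 2, function(k) {
    cooccurrence_score(motifs[[k[1]]], motifs[[k[2]]])
  })
  keep <- sc > cutoff
  out <- data.frame(
    dataset_id = vapply(motifs, `[[`, "", "dataset_id")[pairs[1, keep]],
    motif_i = ids[pairs[1, keep]],
    motif_j = ids[pairs[2, keep]],
    sc = sc[keep], stringsAsFactors = FALSE
  )
  attr(out, "kept_motifs") <- unique(c(out$motif_i, out$motif_j))
  out
}

#' Histogram dump of within-dataset Sc scores
#'
#' QC view of the Sc distribution (the cutoff itself stays a fixed
#' parameter; no mode detection is attempted).
#'
#' @param cps_list List of [select_cps()]-style data.frames computed with
#'   `cutoff = -1` (i.e. all pairs), or any data.frames with an `sc` column.
#' @param breaks Passed to [graphics::hist()] breaks logic via [cut()].
#' @return data.frame (bin_lo, bin_hi, count).
#' @export
sc_histogram <- function(cps_list, breaks = seq(0, 1, by = 0.05)) {
  sc <- unlist(lapply(cps_list, function(d) d$sc), use.names = FALSE)
  h <- graphics::hist(sc, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = utils::head(h$breaks, -1), bin_hi = h$breaks[-1],
             count = h$counts)
}
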