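#' Recall of reference elements under the 50%-of-shorter rule
#'
#' A reference element is recalled iff some predicted element overlaps it
#' by at least half the length of the shorter of the two (inclusive).
#' When several predicted elements recall one reference, the one with the
#' longest overlap defines the recalling pair used for length-ratio
#' analysis.
#'
#' @param predicted,reference BED-style data.frames (chrom, start, end).
#' @param min_frac Overlap threshold as a fraction of the shorter element
#'   (default 0.5).
#' @return List: `sensitivity`, `flags` (per-reference data.frame with
#'   `recalled`), and `mapping` (ref_idx, pred_idx, overlap_bp, len_pred,
#'   len_ref for each recalled reference).
#' @export
recall_elements <- function(predicted, reference, min_frac = 0.5) {
  nref <- nrow(reference)
  flags <- data.frame(reference, recalled = FALSE)
  mapping <- data.frame(ref_idx = integer(), pred_idx = integer(),
                        overlap_bp = numeric(), len_pred = numeric(),
                        len_ref = numeric())
  if (nref > 0L && nrow(predicted) > 0L) {
    gp <- bed_to_gr(predicted)
    gref <- bed_to_gr(reference)
    hits <- GenomicRanges::findOverlaps(gref, gp)
    if (length(hits)) {
      ri <- S4Vectors::queryHits(hits)
      pi_ <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(gref[ri], gp[pi_]))
      len_r <- reference$end[ri] - reference$start[ri]
      len_p <- predicted$end[pi_] - predicted$start[pi_]
      good <- ov >= min_frac * pmin(len_r, len_p)
      if (any(good)) {
        tab <- data.frame(ref_idx = ri[good], pred_idx = pi_[good],
                          overlap_bp = ov[good], len_pred = len_p[good],
                          len_ref = len_r[good])
        ## longest-overlap predicted element per recalled reference
        tab <- tab[order(tab$ref_idx, -tab$overlap_bp), , drop = FALSE]
        mapping <- tab[!duplicated(tab$ref_idx), , drop = FALSE]
        rownames(mapping) <- NULL
        flags$recalled[mapping$ref_idx] <- TRUE
      }
    }
  }
  list(sensitivity = if (nref > 0) mean(flags$recalled) else NA_real_,
       flags = flags, mapping = mapping)
}

#' Random control elements with matched count and lengths
#'
#' Places elements with exactly the same multiset of lengths as `predicted`
#' uniformly at random within `universe`, without self-overlap.
#' Deterministic given `seed`; placement failure after `max_tries` retries
#' per element raises an error.
#'
#' @param predicted BED-style data.frame whose lengths are matched.
#' @param universe BED-style data.frame of placeable regions.
#' @param seed RNG seed.
#' @param max_tries Rejection-sampling retries per element (default 200).
#' @return BED-style data.frame of control elements.
#' @export
matched_controls <- function(predicted, universe, seed = 1, max_tries = 200) {
  set.seed(seed)
  universe <- interval_union(universe)
  lens <- sort(predicted$end - predicted$start, decreasing = TRUE)
  useg <- universe[order(universe$chrom, universe$start), , drop = FALSE]
  seg_len <- useg$end - useg$start
  placed <- vector("list", length(lens))
  occupied <- list()
  for (i in seq_along(lens)) {
    l <- lens[i]
    fit <- which(seg_len >= l)
    if (!length(fit)) stop("universe cannot host an element of length ", l)
    done <- FALSE
    for (try in seq_len(max_tries)) {
      slack <- seg_len[fit] - l + 1
      seg <- fit[findInterval(stats::runif(1) * sum(slack),
                              cumsum(slack)) + 1L]
      start <- useg$start[seg] + floor(stats::runif(1) * (seg_len[seg] - l + 1))
      cand <- data.frame(chrom = useg$chrom[seg], start = start,
                         end = start + l)
      occ <- occupied[[cand$chrom]]
      clash <- !is.null(occ) &&
        any(occ$start < cand$end & cand$start < occ$end)
      if (!clash) {
        placed[[i]] <- cand
        occupied[[cand$chrom]] <- rbind(occ, cand[, c("start", "end")])
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("could not place control element of length ", l, " after ",
           max_tries, " tries")
    }
  }
  out <- do.call(rbind, placed)
  rownames(out) <- NULL
  out
}

#' Proportion of selectively neutral positions of an interval set
#'
#' The fraction of scored positions whose conservation score lies within
#' the neutral band [-delta, +delta]. Missing positions (no score in the
#' profile) are excluded from the denominator, never imputed. Two
#' implementations are provided: `"rle"` intersects the intervals with the
#' run-length encoded score track, `"per_position"` counts base by base
#' (an independent cross-check, suitable for small inputs).
#'
#' @param intervals BED-style data.frame.
#' @param profile data.frame (chrom, start, end, score), e.g. from
#'   [read_bedgraph()].
#' @param delta Half-width of the neutral score band (default 1).
#' @param method "rle" (default) or "per_position".
#' @param min_scored Minimum fraction of queried positions that must be
#'   scored (default 0.99); below this a warning is raised.
#' @return Fraction in [0, 1].
#' @export
proportion_of_neutrality <- function(intervals, profile, delta = 1,
                                     method = c("rle", "per_position"),
                                     min_scored = 0.99) {
  method <- match.arg(method)
  stopifnot(delta > 0)
  total_bp <- coverage_bp(intervals)
  if (method == "rle") {
    scored_gr <- interval_intersect(intervals,
                                    profile[, c("chrom", "start", "end")])
    scored <- coverage_bp(scored_gr)
    neutral_runs <- profile[abs(profile$score) <= delta, , drop = FALSE]
    neutral <- coverage_bp(interval_intersect(intervals, neutral_runs))
  } else {
    pos <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
      paste0(intervals$chrom[i],
             ":", seq(intervals$start[i], intervals$end[i] - 1L))
    }))
    pos <- unique(pos)
    ppos <- unlist(lapply(seq_len(nrow(profile)), function(i) {
      paste0(profile$chrom[i],
             ":", seq(profile$start[i], profile$end[i] - 1L))
    }))
    pscore <- rep(profile$score, profile$end - profile$start)
    idx <- match(pos, ppos)
    scored <- sum(!is.na(idx))
    neutral <- sum(abs(pscore[idx[!is.na(idx)]]) <= delta)
  }
  if (scored == 0) stop("no queried position has a conservation score")
  if (scored < min_scored * total_bp) {
    warning(sprintf("only %.1f%% of queried positions are scored",
                    100 * scored / total_bp))
  }
  neutral / scored
}

#' Decompose two interval sets into shared and specific positions
#'
#' @param set_a,set_b BED-style data.frames.
#' @return List: `shared_bp`, `a_specific_bp`, `b_specific_bp`; satisfies
#'   shared + a_specific = total covered by A (and symmetrically for B).
#' @export
decompose_positions <- function(set_a, set_b) {
  shared <- coverage_bp(interval_intersect(set_a, set_b))
  list(shared_bp = shared,
       a_specific_bp = coverage_bp(set_a) - shared,
       b_specific_bp = coverage_bp(set_b) - shared)
}

#' Length-ratio summary of recalling vs recalled elements
#'
#' @param mapping The `mapping` data.frame from [recall_elements()].
#' @param probs Quantiles reported (default quartiles).
#' @return List: `ratios` (len_pred/len_ref per recalled reference),
#'   `median`, `quantiles`.
#' @export
length_ratio_stats <- function(mapping, probs = c(0.25, 0.5, 0.75)) {
  ratios <- mapping$len_pred / mapping$len_ref
  list(ratios = ratios,
       median = stats::median(ratios),
       quantiles = stats::quantile(ratios, probs = probs, names = TRUE))
}
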