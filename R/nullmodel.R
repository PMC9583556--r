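#' Fit a k-th order Markov chain sequence model
#'
#' Transition counts (next base given the preceding `order`-mer) are
#' regularized with an additive pseudocount; the initial distribution is the
#' observed frequency of all `order`-mers. Sequences shorter than
#' `order + 1` are skipped with a warning.
#'
#' @param seqs Character vector or `DNAStringSet` of training sequences.
#' @param order Markov order (default 3).
#' @param pseudocount Additive regularizer (default 1).
#' @return A `MarkovModel`: list(order, initial, transitions) where
#'   `initial` is a 4^order probability vector over contexts and
#'   `transitions` a 4^order x 4 row-stochastic matrix.
#' @export
fit_markov <- function(seqs, order = 3, pseudocount = 1) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- as.character(seqs)
  }
  codes_list <- lapply(seqs, encode_dna)
  short <- lengths(codes_list) < order + 1L
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than order + 1 skipped")
    codes_list <- codes_list[!short]
  }
  if (!length(codes_list)) stop("no usable training sequences")
  nctx <- 4L^order
  trans <- matrix(pseudocount, nctx, 4L)
  init <- rep(0, nctx)
  pow <- 4L^((order - 1L):0L)
  for (cc in codes_list) {
    cc <- cc[!is.na(cc)] # ambiguous bases break contexts; drop them
    if (length(cc) < order + 1L) next
    n <- length(cc)
    ctx <- rep(0L, n - order + 1L)
    for (j in seq_len(order)) {
      ctx <- ctx + (cc[j:(n - order + j)] - 1L) * pow[j]
    }
    ctx <- ctx + 1L
    init <- init + tabulate(ctx, nctx)
    nxt <- cc[(order + 1L):n]
    from <- ctx[seq_len(n - order)]
    idx <- from + (nxt - 1L) * nctx
    tab <- tabulate(idx, nctx * 4L)
    trans <- trans + matrix(tab, nctx, 4L)
  }
  init <- init + pseudocount
  structure(list(order = order,
                 initial = init / sum(init),
                 transitions = trans / rowSums(trans)),
            class = "MarkovModel")
}

#' Sample null sequences of given lengths from a Markov model
#'
#' One sequence per requested length, of exactly that length; deterministic
#' given `seed`. All sequences are advanced in lockstep so the cost is one
#' vectorized draw per output position.
#'
#' @param model A `MarkovModel`.
#' @param lengths Integer vector of sequence lengths (each > order).
#' @param seed RNG seed.
#' @return Character vector of sequences.
#' @export
sample_null_crmcs <- function(model, lengths, seed = 1) {
  stopifnot(inherits(model, "MarkovModel"), all(lengths > model$order))
  set.seed(seed)
  order <- model$order
  n <- length(lengths)
  lmax <- max(lengths)
  cumtrans <- t(apply(model$transitions, 1, cumsum))
  cuminit <- cumsum(model$initial)
  out <- matrix(NA_integer_, n, lmax)
  ## initial context
  ctx0 <- findInterval(stats::runif(n), cuminit) + 1L
  pow <- 4L^((order - 1L):0L)
  for (j in seq_len(order)) {
    out[, j] <- ((ctx0 - 1L) %/% pow[j]) %% 4L + 1L
  }
  ctx <- ctx0
  for (pos in seq(order + 1L, lmax)) {
    alive <- lengths >= pos
    u <- stats::runif(n) # one draw per sequence keeps the stream aligned
    cm <- cumtrans[ctx, , drop = FALSE]
    b <- 1L + (u > cm[, 1]) + (u > cm[, 2]) + (u > cm[, 3])
    out[alive, pos] <- b[alive]
    ctx <- (ctx - 1L) %% (4L^(order - 1L)) * 4L + b
  }
  vapply(seq_len(n), function(i) {
    paste(BASES[out[i, seq_len(lengths[i])]], collapse = "")
  }, "")
}

#' Scan sequences with UM PWMs and score them like CRM candidates
#'
#' Each sequence is scanned on both strands with every UM PWM; positions
#' with a positive log-odds score become candidate TFBSs, sites are linked
#' with the CRMC gap rule, and every linked run with at least two sites is
#' scored with the CRM score under `net` (normally a weight-shuffled
#' network). The sequence's score is the maximum run score, 0 if no run has
#' two sites.
#'
#' @param seqs Character vector of sequences.
#' @param ums Named list of `UniqueMotif` objects.
#' @param net An `InteractionNetwork` (e.g. from [shuffle_weights()]).
#' @param max_gap Site-linking gap (default 300).
#' @param score_frac Site acceptance threshold as a fraction of each PWM's
#'   maximum score (default 0 = any positive score). Pass the same fraction
#'   used when collecting sites in discovery so candidate and null site
#'   densities are comparable.
#' @return Numeric vector of null S_CRM scores, one per sequence.
#' @export
score_null_sequences <- function(seqs, ums, net, max_gap = 300,
                                 score_frac = 0) {
  codes_list <- lapply(seqs, encode_dna)
  codemat <- codes_to_matrix(codes_list)
  n <- length(seqs)
  widths <- vapply(ums, function(u) u$model$width, 0)
  ## shared-width fast path: rolling k-mer codes are computed once and each
  ## PWM/strand is scored by one lookup into its 4^w score table
  shared_codes <- NULL
  if (length(unique(widths)) == 1L && widths[1] <= 12L &&
        ncol(codemat) >= widths[1]) {
    shared_codes <- kmer_codes_fwd(codemat, widths[1]) + 1
    ## (NA where any base is ambiguous/padding; the reverse strand is
    ## handled by scoring the same codes under the reverse-complement PWM)
  }
  hits <- vector("list", length(ums))
  for (k in seq_along(ums)) {
    um <- ums[[k]]
    lod <- pwm_logodds(um$model)
    w <- um$model$width
    thr <- max(0, score_frac * sum(apply(lod, 2, max)))
    if (ncol(codemat) < w) next
    for (strand in c("+", "-")) {
      m <- if (strand == "+") lod else lod[4:1, w:1, drop = FALSE]
      if (!is.null(shared_codes)) {
        tab <- pwm_score_table(m)
        sc <- tab[shared_codes]
        pos <- which(sc > thr)
        sc_val <- sc[pos]
        pos <- arrayInd(pos, dim(shared_codes))
      } else {
        sc <- scan_code_matrix(m, codemat)
        idx <- which(sc > thr)
        sc_val <- sc[idx]
        pos <- arrayInd(idx, dim(sc))
      }
      if (nrow(pos)) {
        hits[[k]] <- rbind(hits[[k]], data.frame(
          seq_i = pos[, 1], start = pos[, 2] - 1L,
          end = pos[, 2] - 1L + w, um_id = um$um_id,
          score = sc_val, stringsAsFactors = FALSE
        ))
      }
    }
  }
  sites <- do.call(rbind, hits)
  scores <- numeric(n)
  if (is.null(sites) || nrow(sites) == 0L) {
    return(scores)
  }
  for (g in split(sites, sites$seq_i)) {
    i <- g$seq_i[1]
    g <- g[order(g$start, g$end), , drop = FALSE]
    run_end <- cummax(g$end)
    grp <- cumsum(c(TRUE, g$start[-1] - run_end[-nrow(g)] > max_gap))
    best <- 0
    for (gi in unique(grp)) {
      sg <- g[grp == gi, , drop = FALSE]
      if (nrow(sg) >= 2L) best <- max(best, crm_score(sg, net))
    }
    scores[i] <- best
  }
  scores
}

#' Matched CRMC / null score distributions
#'
#' @param crmc_scores,null_scores Equal-length numeric vectors.
#' @param bin_width Score bin width for FDR estimation (default 1).
#' @return A `ScoreDistributions` list.
#' @export
score_distributions <- function(crmc_scores, null_scores, bin_width = 1) {
  if (length(crmc_scores) != length(null_scores)) {
    stop("null set must be matched in number to the CRMC set (",
         length(crmc_scores), " vs ", length(null_scores), ")")
  }
  stopifnot(bin_width > 0)
  structure(list(crmc_scores = as.numeric(crmc_scores),
                 null_scores = as.numeric(null_scores),
                 bin_width = bin_width),
            class = "ScoreDistributions")
}

#' Empirical p-value of CRM scores against the null distribution
#'
#' p = n(s)/M, where n(s) is the number of null scores strictly greater
#' than s and M the number of CRMCs (equal to the number of null scores by
#' matched construction). Non-increasing in s; a score above every null
#' score gives 0 (reported as "< 1/M" in text output).
#'
#' @param s Numeric vector of S_CRM scores.
#' @param dist A `ScoreDistributions`.
#' @return Numeric vector of p-values in [0, 1].
#' @export
empirical_pvalue <- function(s, dist) {
  stopifnot(inherits(dist, "ScoreDistributions"))
  nulls <- sort(dist$null_scores)
  m <- length(dist$crmc_scores)
  if (m == 0L) stop("empty null distribution")
  ## count of nulls > s  =  m - count of nulls <= s
  (m - findInterval(s, nulls)) / m
}

#' Semi-theoretic FDR estimation from matched score distributions
#'
#' In each score bin b, the expected true positives among the CRMCs are
#' TP(b) = max(0, CRMC count - null count) and the expected false positives
#' FP(b) = min(null count, CRMC count), so that TP + FP equals the CRMC
#' count in every bin and overall. The raw null count per bin is also
#' reported. Cumulative TP/FP curves are accumulated over decreasing score
#' cutoffs, and FDR at cutoff alpha is cumulative FP / cumulative CRMC
#' count above alpha.
#'
#' @param dist A `ScoreDistributions`.
#' @return data.frame (bin_lo, bin_hi, crmc_count, null_count, expected_tp,
#'   expected_fp, cum_crmc, cum_tp, cum_fp, fdr) ordered by decreasing bin.
#' @export
estimate_fdr <- function(dist) {
  stopifnot(inherits(dist, "ScoreDistributions"))
  bw <- dist$bin_width
  hi <- max(dist$crmc_scores, dist$null_scores)
  breaks <- seq(0, (floor(hi / bw) + 1) * bw, by = bw)
  cbin <- findInterval(dist$crmc_scores, breaks, rightmost.closed = FALSE)
  nbin <- findInterval(dist$null_scores, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1L
  ccnt <- tabulate(cbin, nb)
  ncnt <- tabulate(nbin, nb)
  tp <- pmax(0, ccnt - ncnt)
  fp <- pmin(ncnt, ccnt)
  ord <- rev(seq_len(nb)) # decreasing score cutoff
  out <- data.frame(
    bin_lo = breaks[ord], bin_hi = breaks[ord + 1L],
    crmc_count = ccnt[ord], null_count = ncnt[ord],
    expected_tp = tp[ord], expected_fp = fp[ord]
  )
  out$cum_crmc <- cumsum(out$crmc_count)
  out$cum_tp <- cumsum(out$expected_tp)
  out$cum_fp <- cumsum(out$expected_fp)
  out$fdr <- ifelse(out$cum_crmc > 0, out$cum_fp / out$cum_crmc, 0)
  out
}
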