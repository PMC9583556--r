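#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Encode a DNA sequence as integer codes A=1, C=2, G=3, T=4
#'
#' Ambiguous or non-ACGT letters become `NA`.
#' @keywords internal
encode_dna <- function(x) {
  codes <- if (inherits(x, "DNAString")) as.integer(x)
  else as.integer(Biostrings::DNAString(as.character(x)))
  ## Biostrings byte codes: A=1, C=2, G=4, T=8
  map <- rep(NA_integer_, 16L)
  map[c(1L, 2L, 4L, 8L)] <- 1:4
  map[codes]
}

decode_dna <- function(codes) paste(BASES[codes], collapse = "")

rc_codes <- function(codes) rev(5L - codes)

#' Build a position weight matrix model from a count matrix
#'
#' @param counts 4 x width non-negative matrix (rows A, C, G, T).
#' @param background Length-4 background base distribution.
#' @param pseudocount Added to every cell before normalization (default 0.5).
#' @return A `PWMModel`: list with `probabilities` (columns sum to 1),
#'   `background`, `pseudocount`, `width`.
#' @export
pwm_model <- function(counts, background = rep(0.25, 4), pseudocount = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, all(counts >= 0), pseudocount > 0,
            length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  p <- counts + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  rownames(p) <- BASES
  structure(list(probabilities = p, background = background,
                 pseudocount = pseudocount, width = ncol(p)),
            class = "PWMModel")
}

#' Log2-odds matrix of a PWM model
#' @keywords internal
pwm_logodds <- function(model) {
  log2(model$probabilities / model$background)
}

#' Reverse complement of a PWM model
#' @keywords internal
pwm_revcomp <- function(model) {
  p <- model$probabilities[4:1, rev(seq_len(model$width)), drop = FALSE]
  rownames(p) <- BASES
  model$probabilities <- p
  model
}

#' Consensus sequence of a PWM model
#' @export
pwm_consensus <- function(model) {
  paste(BASES[apply(model$probabilities, 2, which.max)], collapse = "")
}

#' Score one k-mer against a PWM model (log2-odds, bits)
#'
#' Sum over columns of log2(p_col(base)/background(base)). A k-mer with an
#' ambiguous base scores `-Inf` (the site is skipped).
#'
#' @param model A `PWMModel`.
#' @param kmer Character sequence of length `model$width`.
#' @return Log-odds score in bits.
#' @export
score_site <- function(model, kmer) {
  codes <- encode_dna(kmer)
  if (length(codes) != model$width) {
    stop("k-mer length ", length(codes), " != motif width ", model$width)
  }
  if (anyNA(codes)) {
    message("ambiguous base in site '", kmer, "': scored -Inf")
    return(-Inf)
  }
  lod <- pwm_logodds(model)
  sum(lod[cbind(codes, seq_len(model$width))])
}

## Score every window start of every row of an integer code matrix.
## codemat: N x L (NA = pad/ambiguous); returns N x (L - w + 1), NA -> -Inf.
scan_code_matrix <- function(lod, codemat) {
  w <- ncol(lod)
  n <- nrow(codemat)
  lm <- ncol(codemat) - w + 1L
  if (lm < 1L) {
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  }
  out <- matrix(0, n, lm)
  for (j in seq_len(w)) {
    idx <- (j - 1L) * 4L + codemat[, j:(j + lm - 1L), drop = FALSE]
    out <- out + lod[idx]
  }
  out[is.na(out)] <- -Inf
  out
}

## stack variable-length code vectors into an NA-padded matrix
codes_to_matrix <- function(codes_list) {
  n <- length(codes_list)
  lmax <- max(lengths(codes_list))
  m <- matrix(NA_integer_, n, lmax)
  for (i in seq_len(n)) {
    ci <- codes_list[[i]]
    if (length(ci)) m[i, seq_along(ci)] <- ci
  }
  m
}

## rolling forward-strand k-mer codes (0 .. 4^w-1) from a code matrix
kmer_codes_fwd <- function(codemat, w) {
  lm <- ncol(codemat) - w + 1L
  fwd <- matrix(0, nrow(codemat), lm)
  for (j in seq_len(w)) {
    fwd <- fwd * 4 + (codemat[, j:(j + lm - 1L), drop = FALSE] - 1L)
  }
  fwd
}

## rolling k-mer codes (0 .. 4^w-1) for both strands from a code matrix
kmer_codes_both_strands <- function(codemat, w) {
  lm <- ncol(codemat) - w + 1L
  fwd <- matrix(0, nrow(codemat), lm)
  rc <- matrix(0, nrow(codemat), lm)
  for (j in seq_len(w)) {
    block <- codemat[, j:(j + lm - 1L), drop = FALSE]
    fwd <- fwd * 4 + (block - 1L)
    rcblock <- codemat[, (w - j + 1L):(w - j + lm), drop = FALSE]
    rc <- rc * 4 + (4L - rcblock)
  }
  list(fwd = fwd, rc = rc)
}

## full score table over all 4^w k-mers: scoretab[code + 1] = PWM score
pwm_score_table <- function(lod) {
  s <- 0
  for (j in seq_len(ncol(lod))) {
    s <- rep(s, each = 4L) + lod[, j]
  }
  s
}

## P(random background k-mer scores >= thr) by exact per-column convolution
## of the discretized log-odds distribution
pwm_match_prob <- function(model, thr, gran = 0.05) {
  lod <- pwm_logodds(model)
  bg <- model$background
  q <- round(lod / gran)
  lo <- sum(apply(q, 2, min))
  hi <- sum(apply(q, 2, max))
  dist <- c(1, numeric(hi - lo))
  offset <- 0
  for (j in seq_len(ncol(q))) {
    nd <- numeric(length(dist) + max(q[, j]) - min(q[, j]))
    for (b in 1:4) {
      sh <- q[b, j] - min(q[, j])
      nd[seq_along(dist) + sh] <- nd[seq_along(dist) + sh] + dist * bg[b]
    }
    dist <- nd
    offset <- offset + min(q[, j])
  }
  scores <- (seq_along(dist) - 1 + offset) * gran
  sum(dist[scores >= thr])
}

decode_kmer <- function(code, w) {
  out <- integer(w)
  for (j in seq(w, 1L)) {
    out[j] <- code %% 4 + 1
    code <- code %/% 4
  }
  as.integer(out)
}

#' Discover motifs in a set of extended peak window sequences
#'
#' A documented baseline finder behind a pluggable interface (an external
#' finder's sites can be loaded with [motifs_from_sites_tsv()]): (i) count
#' all k-mers on both strands; (ii) seed with k-mers whose count exceeds a
#' 0th-order Markov expectation by at least `z_min` standard deviations;
#' (iii) greedily collect at most one best-scoring site per sequence above a
#' log-odds threshold (`score_frac` of the PWM's maximum attainable score);
#' (iv) iterate PWM re-estimation until convergence; (v) drop motifs with
#' fewer than `min_sites` sites or nearly duplicating an accepted motif.
#' Deterministic given `seed`.
#'
#' @param seqs Window sequences (`DNAStringSet` or character vector),
#'   optionally named by peak id.
#' @param width Motif width in bp (default 10).
#' @param z_min Seed z-score cutoff (default 6).
#' @param score_frac Site acceptance threshold as a fraction of the PWM's
#'   maximum score (default 0.6).
#' @param min_bits Absolute floor (bits) on the site acceptance threshold
#'   (default = `width`); keeps a low-information interim PWM from
#'   accreting spurious background sites during re-estimation.
#' @param min_sites Minimum site count to keep a motif; default
#'   `max(5, ceiling(0.2 * length(seqs)))`.
#' @param max_motifs Maximum motifs reported per dataset (default 6).
#' @param max_iter,tol Re-estimation iteration cap (50) and convergence
#'   tolerance on max probability change (1e-4).
#' @param min_peaks Fewer sequences than this returns an empty list (default 20).
#' @param dataset_id Label attached to reported motifs.
#' @param seed RNG seed (the baseline is deterministic; kept for contract).
#' @return List of `Motif` objects: `motif_id`, `dataset_id`, `width`,
#'   `counts` (4 x width; column sums equal the site count), `model`
#'   (`PWMModel`), and `sites` (peak_id, offset, strand, seq, score; offset
#'   is the 0-based site start within its window).
#' @export
discover_motifs <- function(seqs, width = 10, z_min = 6, score_frac = 0.6,
                            min_sites = NULL, max_motifs = 6, max_iter = 50,
                            tol = 1e-4, min_peaks = 20, min_bits = width,
                            dataset_id = NA_character_, seed = 1) {
  set.seed(seed)
  stopifnot(width >= 6, width <= 30)
  if (inherits(seqs, "DNAStringSet")) {
    peak_ids <- names(seqs) %||% as.character(seq_along(seqs))
    codes_list <- lapply(seq_along(seqs), function(i) encode_dna(seqs[[i]]))
  } else {
    peak_ids <- names(seqs) %||% as.character(seq_along(seqs))
    codes_list <- lapply(seqs, encode_dna)
  }
  n <- length(codes_list)
  if (n < min_peaks) {
    message("motif discovery skipped: ", n, " sequences < min_peaks = ", min_peaks)
    return(list())
  }
  min_sites <- min_sites %||% max(5, ceiling(0.2 * n))
  codemat <- codes_to_matrix(codes_list)
  if (ncol(codemat) < width) {
    message("motif discovery skipped: all sequences shorter than width ", width)
    return(list())
  }
  all_codes <- codemat[!is.na(codemat)]
  bg <- tabulate(all_codes, 4L)
  bg <- bg / sum(bg)

  ## --- seeding: over-represented k-mers vs 0th-order expectation ---
  km <- kmer_codes_both_strands(codemat, width)
  vals <- c(km$fwd, km$rc)
  vals <- vals[!is.na(vals)]
  npos <- sum(!is.na(km$fwd))
  counts <- tabulate(vals + 1L, nbins = 4^width)
  ## a seed whose own k-mer count cannot plausibly reach min_sites is not
  ## worth an EM run; this prunes the long tail of marginal-count k-mers
  ## before any z-score is computed
  cand <- which(counts >= max(3, ceiling(min_sites / 2)))
  if (!length(cand)) {
    return(list())
  }
  cand_codes <- cand - 1L
  zscore <- vapply(seq_along(cand), function(i) {
    b <- decode_kmer(cand_codes[i], width)
    e <- npos * (prod(bg[b]) + prod(bg[5L - b]))
    (counts[cand[i]] - e) / sqrt(e)
  }, numeric(1))
  keep <- zscore >= z_min
  seeds <- cand_codes[keep][order(-counts[cand][keep], cand_codes[keep])]
  max_trials <- 5L * max_motifs

  hamming <- function(a, b) sum(a != b)
  motifs <- list()
  consensi <- list()
  trials <- 0L
  for (sd_code in seeds) {
    if (length(motifs) >= max_motifs || trials >= max_trials) break
    trials <- trials + 1L
    seed_codes <- decode_kmer(sd_code, width)
    near <- any(vapply(consensi, function(cc) {
      hamming(cc, seed_codes) <= 2 || hamming(cc, rc_codes(seed_codes)) <= 2
    }, logical(1)))
    if (near) next

    ## initial sharp PWM from the seed k-mer
    cnt <- matrix(0, 4, width)
    cnt[cbind(seed_codes, seq_len(width))] <- 8
    model <- pwm_model(cnt, background = bg)

    sites <- NULL
    for (iter in seq_len(max_iter)) {
      lod <- pwm_logodds(model)
      thr <- max(score_frac * sum(apply(lod, 2, max)), min_bits)
      sf <- scan_code_matrix(lod, codemat)
      sr <- scan_code_matrix(lod[4:1, width:1, drop = FALSE], codemat)
      best_f <- max.col(sf, ties.method = "first")
      best_r <- max.col(sr, ties.method = "first")
      vf <- sf[cbind(seq_len(n), best_f)]
      vr <- sr[cbind(seq_len(n), best_r)]
      use_r <- vr > vf
      score <- ifelse(use_r, vr, vf)
      pos <- ifelse(use_r, best_r, best_f)
      hit <- which(score >= thr)
      ## the first collection under the sharp seed PWM is an upper-bound
      ## screen: a seed that cannot reach min_sites now never will
      if (length(hit) < 2L || (iter == 1L && length(hit) < min_sites)) {
        sites <- NULL
        break
      }
      site_codes <- lapply(hit, function(i) {
        cc <- codemat[i, pos[i]:(pos[i] + width - 1L)]
        if (use_r[i]) rc_codes(cc) else cc
      })
      cnt <- matrix(0L, 4, width)
      for (cc in site_codes) {
        cnt[cbind(cc, seq_len(width))] <- cnt[cbind(cc, seq_len(width))] + 1L
      }
      new_model <- pwm_model(cnt, background = bg)
      delta <- max(abs(new_model$probabilities - model$probabilities))
      model <- new_model
      sites <- data.frame(
        peak_id = peak_ids[hit],
        offset = pos[hit] - 1L,
        strand = ifelse(use_r[hit], "-", "+"),
        seq = vapply(site_codes, decode_dna, ""),
        score = score[hit],
        stringsAsFactors = FALSE
      )
      if (delta < tol) break
    }
    if (is.null(sites) || nrow(sites) < min_sites) next
    ## over-representation guard: the site count must exceed what the
    ## converged PWM would collect from background sequence by z_min SDs
    thr <- max(score_frac * sum(apply(pwm_logodds(model), 2, max)), min_bits)
    p_pos <- pwm_match_prob(model, thr)
    pos_per_seq <- 2 * npos / n
    p_win <- 1 - (1 - p_pos)^pos_per_seq
    expected <- n * p_win
    sdev <- max(sqrt(n * p_win * (1 - p_win)), 0.5)
    if (nrow(sites) < expected + z_min * sdev) next
    dup <- any(vapply(motifs, function(m) {
      motif_similarity(m$model, model) > 0.8
    }, logical(1)))
    if (dup) next
    motif <- structure(list(
      motif_id = sprintf("%s_m%02d", dataset_id, length(motifs) + 1L),
      dataset_id = dataset_id, width = width, counts = cnt,
      model = model, sites = sites
    ), class = "Motif")
    motifs[[length(motifs) + 1L]] <- motif
    consensi[[length(consensi) + 1L]] <-
      apply(model$probabilities, 2, which.max)
  }
  motifs
}

#' @export
print.Motif <- function(x, ...) {
  cat(sprintf("<Motif %s> width=%d sites=%d consensus=%s\n",
              x$motif_id, x$width, nrow(x$sites), pwm_consensus(x$model)))
  invisible(x)
}

#' Write PWM models in MEME minimal text format
#'
#' @param models Named list of `PWMModel` objects.
#' @param path Output path.
#' @export
write_meme <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- models[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", BASES, bg), collapse = " "), ""), con)
  for (nm in names(models)) {
    m <- models[[nm]]
    writeLines(c(sprintf("MOTIF %s", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         m$width)), con)
    writeLines(apply(m$probabilities, 2, function(p) {
      paste(sprintf("%.6f", p), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write motif site occurrences as TSV
#' @param motifs List of `Motif` objects.
#' @param path Output path.
#' @export
write_motif_sites <- function(motifs, path) {
  tabs <- lapply(motifs, function(m) {
    cbind(motif_id = m$motif_id, dataset_id = m$dataset_id, m$sites)
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Load motifs from an external finder's site table
#'
#' Adapter for swapping in any motif finder without code change: the tool's
#' sites are supplied as a TSV with columns `motif_id`, `dataset_id`,
#' `peak_id`, `offset`, `strand`, `seq` (one aligned site sequence per row,
#' all the same width per motif). Count matrices and PWM models are rebuilt
#' from the site sequences.
#'
#' @param path TSV path.
#' @param background Background base distribution for the rebuilt models.
#' @return List of `Motif` objects.
#' @export
motifs_from_sites_tsv <- function(path, background = rep(0.25, 4)) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("motif_id", "dataset_id", "peak_id", "offset", "strand", "seq")
  if (!all(need %in% names(tab))) {
    stop("site TSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(tab, tab$motif_id), function(g) {
    codes <- lapply(g$seq, encode_dna)
    w <- unique(lengths(codes))
    if (length(w) != 1L) stop("motif ", g$motif_id[1], ": mixed site widths")
    cnt <- matrix(0L, 4, w)
    for (cc in codes) {
      cnt[cbind(cc, seq_len(w))] <- cnt[cbind(cc, seq_len(w))] + 1L
    }
    g$score <- NA_real_
    structure(list(motif_id = g$motif_id[1], dataset_id = g$dataset_id[1],
                   width = w, counts = cnt,
                   model = pwm_model(cnt, background = background),
                   sites = g[c("peak_id", "offset", "strand", "seq", "score")]),
              class = "Motif")
  })
}
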