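#' Project pooled UM sites to genomic coordinates and re-score them
#'
#' Each pooled UM site (already carrying genomic coordinates derived from
#' its peak window offset) is re-scored against the UM's PWM on the genome
#' sequence, deduplicated on (chrom, start, end, um_id), and sites with a
#' non-positive log-odds score are dropped: only positively scoring TFBSs
#' enter CRM scoring.
#'
#' @param ums Named list of usable `UniqueMotif` objects.
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @return data.frame (chrom, start, end, strand, um_id, score) sorted by
#'   chrom then start; 0-based half-open.
#' @export
project_sites <- function(ums, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom_codes <- lapply(seq_along(genome), function(i) encode_dna(genome[[i]]))
  names(chrom_codes) <- names(genome)
  out <- lapply(ums, function(um) {
    s <- um$sites
    if (nrow(s) == 0L) {
      return(NULL)
    }
    w <- um$model$width
    lod <- pwm_logodds(um$model)
    bad <- !(s$chrom %in% names(chrom_codes))
    if (any(bad)) stop("site on unknown chromosome: ", s$chrom[which(bad)[1]])
    lens <- lengths(chrom_codes)[s$chrom]
    if (any(s$start < 0 | s$end > lens)) {
      stop("site beyond chromosome bounds in UM ", um$um_id)
    }
    score <- vapply(seq_len(nrow(s)), function(i) {
      cc <- chrom_codes[[s$chrom[i]]][(s$start[i] + 1L):s$end[i]]
      if (s$strand[i] == "-") cc <- rc_codes(cc)
      if (anyNA(cc)) {
        return(-Inf)
      }
      sum(lod[cbind(cc, seq_len(w))])
    }, numeric(1))
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               strand = s$strand, um_id = um$um_id, score = score,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  sites <- sites[!duplicated(paste(sites$chrom, sites$start, sites$end,
                                   sites$um_id)), , drop = FALSE]
  sites <- sites[sites$score > 0, , drop = FALSE]
  sites[order(sites$chrom, sites$start, sites$end), , drop = FALSE]
}

#' Partition peak-covered regions into CRM candidates and non-CRMCs
#'
#' Adjacent projected TFBSs are linked when their edge-to-edge distance is
#' at most `max_gap` bp (inclusive); each maximal linked run becomes a CRM
#' candidate (CRMC) spanning first-site start to last-site end. Lone sites
#' form single-site CRMCs. Every covered position outside all CRMC spans
#' becomes non-CRMC, so CRMCs and non-CRMCs exactly partition the covered
#' regions. Sites outside the covered regions are kept with a warning.
#'
#' @param sites data.frame from [project_sites()].
#' @param covered BED-style data.frame of the extended-peak union.
#' @param max_gap Maximum inter-site gap within a CRMC (default 300).
#' @return A `GenomePartition`: list with `crmcs` (data.frame: crmc_id,
#'   chrom, start, end, n_sites), `crmc_sites` (list of per-CRMC site
#'   data.frames), `non_crmcs` and `covered` (BED-style data.frames).
#' @export
partition_crmcs <- function(sites, covered, max_gap = 300) {
  covered <- interval_union(covered)
  ## plain sorted-vector arithmetic throughout: this function runs on many
  ## small instances, where per-call container overhead would dominate
  crmcs <- list()
  crmc_sites <- list()
  non <- list()
  n_outside <- 0L
  for (ch in unique(c(sites$chrom, covered$chrom))) {
    segs <- covered[covered$chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    s <- sites[sites$chrom == ch, , drop = FALSE]
    spans_start <- numeric(0)
    spans_end <- numeric(0)
    span_seg <- integer(0)
    if (nrow(s)) {
      s <- s[order(s$start, s$end), , drop = FALSE]
      ## runs never straddle covered-segment boundaries, so every CRMC
      ## span stays inside the covered regions and the partition is exact
      seg_of <- findInterval(s$start, segs$start)
      outside <- seg_of == 0L |
        s$end > segs$end[pmax(seg_of, 1L)] |
        s$start >= segs$end[pmax(seg_of, 1L)]
      n_outside <- n_outside + sum(outside)
      seg_of[outside] <- 0L # off-covered sites link only among themselves
      run_end <- cummax(s$end)
      new_run <- c(TRUE, s$start[-1] - run_end[-nrow(s)] > max_gap |
                     seg_of[-1] != seg_of[-nrow(s)])
      grp <- cumsum(new_run)
      spans_start <- as.numeric(tapply(s$start, grp, min))
      spans_end <- as.numeric(tapply(s$end, grp, max))
      span_seg <- as.integer(tapply(seg_of, grp, `[`, 1))
      crmc_sites <- c(crmc_sites, split(s, grp))
      crmcs[[length(crmcs) + 1L]] <- data.frame(
        chrom = ch, start = spans_start, end = spans_end,
        n_sites = as.integer(table(grp)), stringsAsFactors = FALSE
      )
    }
    ## complement of the CRMC spans within each covered segment
    for (k in seq_len(nrow(segs))) {
      in_seg <- which(span_seg == k)
      bounds_lo <- c(segs$start[k], spans_end[in_seg])
      bounds_hi <- c(spans_start[in_seg], segs$end[k])
      keep <- bounds_hi > bounds_lo
      if (any(keep)) {
        non[[length(non) + 1L]] <- data.frame(
          chrom = ch, start = bounds_lo[keep], end = bounds_hi[keep],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (n_outside > 0L) {
    warning(n_outside, " site(s) fall outside the covered regions; ",
            "sites kept")
  }
  if (length(crmcs)) {
    crmc_df <- do.call(rbind, crmcs)
    ord <- order(crmc_df$chrom, crmc_df$start)
    crmc_df <- crmc_df[ord, , drop = FALSE]
    crmc_sites <- crmc_sites[ord]
    crmc_df$crmc_id <- sprintf("CRMC%05d", seq_len(nrow(crmc_df)))
    crmc_df <- crmc_df[, c("crmc_id", "chrom", "start", "end", "n_sites")]
    rownames(crmc_df) <- NULL
  } else {
    crmc_df <- data.frame(crmc_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_sites = integer())
  }
  non <- if (length(non)) {
    out <- do.call(rbind, non)
    out[order(out$chrom, out$start), , drop = FALSE]
  } else {
    covered[0, , drop = FALSE]
  }
  if (n_outside > 0L && nrow(crmc_df) > 0L && nrow(non) > 0L) {
    ## spans holding off-covered sites may reach into covered segments;
    ## keep the partition disjoint on the rare path
    non <- interval_setdiff(non, crmc_df)
  }
  rownames(non) <- NULL
  structure(list(crmcs = crmc_df, crmc_sites = crmc_sites,
                 non_crmcs = non, covered = covered),
            class = "GenomePartition")
}

#' @export
print.GenomePartition <- function(x, ...) {
  cat(sprintf(paste0("<GenomePartition> covered=%.0f bp, %d CRMCs (%.0f bp),",
                     " non-CRMC=%.0f bp\n"),
              coverage_bp(x$covered), nrow(x$crmcs), coverage_bp(x$crmcs),
              coverage_bp(x$non_crmcs)))
  invisible(x)
}

#' Merge overlapping TFBSs into non-overlapping islands
#'
#' Sites sharing at least one bp are transitively merged; abutting
#' half-open intervals share no bp and stay separate.
#'
#' @param sites data.frame with chrom, start, end (and optionally um_id).
#' @return data.frame (chrom, start, end, n_sites, um_ids).
#' @export
merge_islands <- function(sites) {
  out <- lapply(unique(sites$chrom), function(ch) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    run_end <- cummax(s$end)
    grp <- cumsum(c(TRUE, s$start[-1] >= run_end[-nrow(s)]))
    data.frame(
      chrom = ch,
      start = tapply(s$start, grp, min),
      end = tapply(s$end, grp, max),
      n_sites = as.integer(table(grp)),
      um_ids = if ("um_id" %in% names(s)) {
        vapply(split(s$um_id, grp),
               function(u) paste(unique(u), collapse = ","), "")
      } else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CRM score of a candidate from its constituent TFBSs
#'
#' S_CRM = 2/(n-1) * sum_{i<j} w[U(b_i), U(b_j)] * (S(b_i) + S(b_j)) over
#' the n positively scoring sites; a single-site CRMC scores 0 by
#' convention (the pair sum is empty and 1/(n-1) undefined).
#'
#' @param crmc_sites data.frame with columns um_id and score.
#' @param net An `InteractionNetwork` containing every site's UM.
#' @return Non-negative score.
#' @export
crm_score <- function(crmc_sites, net) {
  n <- nrow(crmc_sites)
  if (n == 0L) stop("CRMC with zero sites")
  if (n == 1L) {
    return(0)
  }
  w <- net$weights[crmc_sites$um_id, crmc_sites$um_id, drop = FALSE]
  s <- crmc_sites$score
  pair_sum <- outer(s, s, "+")
  ut <- upper.tri(w)
  2 / (n - 1) * sum(w[ut] * pair_sum[ut])
}

#' Score every CRMC of a partition
#' @param partition A `GenomePartition`.
#' @param net An `InteractionNetwork`.
#' @return The partition with a `s_crm` column added to `crmcs`.
#' @export
score_crmcs <- function(partition, net) {
  partition$crmcs$s_crm <- vapply(partition$crmc_sites, crm_score,
                                  numeric(1), net = net)
  partition
}

#' Functional state of a CRMC in one cell type
#'
#' A CRMC is called bound in a cell type iff at least one constituent TFBS
#' overlaps at least one original (unextended) peak of that cell type by at
#' least 1 bp.
#'
#' @param crmc_sites data.frame of the CRMC's sites (chrom, start, end).
#' @param cell_type_peaks BED-style data.frame of the cell type's original
#'   peaks.
#' @return "bound" or "unbound".
#' @export
functional_state <- function(crmc_sites, cell_type_peaks) {
  if (nrow(crmc_sites) == 0L || nrow(cell_type_peaks) == 0L) {
    return("unbound")
  }
  hits <- GenomicRanges::findOverlaps(bed_to_gr(crmc_sites),
                                      bed_to_gr(cell_type_peaks))
  if (length(hits) > 0) "bound" else "unbound"
}
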