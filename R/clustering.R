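#' Ungapped alignment and similarity of two PWM models
#'
#' Similarity is the maximum, over all ungapped column offsets and over the
#' reverse-complement orientation of the second motif, of the mean
#' per-aligned-column similarity, where column similarity is the
#' total-variation complement 1 - 1/2 * sum_base |p_a - p_b|. Overhanging
#' columns are excluded; alignments with fewer than `min_overlap` columns
#' score 0.
#'
#' @param ma,mb `PWMModel` objects.
#' @param min_overlap Minimum aligned columns (default 6).
#' @return For [motif_similarity()], the score in [0, 1]. [motif_align()]
#'   additionally returns the maximizing `offset` (column 1 of `mb`, in
#'   `ma`'s column frame, possibly negative) and `rc` flag.
#' @export
motif_align <- function(ma, mb, min_overlap = 6) {
  wa <- ma$width
  wb <- mb$width
  pa <- ma$probabilities
  best <- list(score = 0, offset = 0L, rc = FALSE, overlap = 0L)
  ## ties (e.g. periodic motifs) resolve toward larger overlap, then the
  ## more central offset, then the forward orientation
  for (rc in c(FALSE, TRUE)) {
    pb <- if (rc) pwm_revcomp(mb)$probabilities else mb$probabilities
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      ia <- max(1L, 1L + off):min(wa, wb + off)
      if (length(ia) < min_overlap) next
      ib <- ia - off
      colsim <- 1 - 0.5 * colSums(abs(pa[, ia, drop = FALSE] -
                                        pb[, ib, drop = FALSE]))
      s <- mean(colsim)
      better <- s > best$score + 1e-12 ||
        (abs(s - best$score) <= 1e-12 &&
           (length(ia) > best$overlap ||
              (length(ia) == best$overlap && abs(off) < abs(best$offset))))
      if (better) {
        best <- list(score = s, offset = off, rc = rc, overlap = length(ia))
      }
    }
  }
  best
}

#' @rdname motif_align
#' @export
motif_similarity <- function(ma, mb, min_overlap = 6) {
  motif_align(ma, mb, min_overlap)$score
}

#' Build the motif similarity graph
#'
#' Nodes are motifs surviving CP selection; an edge joins every pair with
#' similarity strictly greater than `edge_cutoff`.
#'
#' @param motifs List of `Motif` objects.
#' @param edge_cutoff Strict similarity cutoff (default 0.8).
#' @return An `igraph` undirected graph; vertices named by motif id, edges
#'   weighted by similarity.
#' @export
build_motif_graph <- function(motifs, edge_cutoff = 0.8) {
  ids <- vapply(motifs, `[[`, "", "motif_id")
  g <- igraph::make_empty_graph(n = length(motifs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(motifs) >= 2L) {
    pairs <- utils::combn(length(motifs), 2)
    sim <- apply(pairs, 2, function(k) {
      motif_similarity(motifs[[k[1]]]$model, motifs[[k[2]]]$model)
    })
    keep <- sim > edge_cutoff
    if (any(keep)) {
      g <- igraph::add_edges(g, rbind(pairs[1, keep], pairs[2, keep]),
                             weight = sim[keep])
    }
  }
  g
}

## edge density inside clusters vs density of the cut, for the acceptance test
partition_density <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- membership[el[, 1]] == membership[el[, 2]]
  sizes <- table(membership)
  intra_pairs <- sum(choose(as.numeric(sizes), 2))
  n <- length(membership)
  inter_pairs <- choose(n, 2) - intra_pairs
  intra <- if (intra_pairs > 0) sum(same) / intra_pairs else 1
  cut <- if (inter_pairs > 0) sum(!same) / inter_pairs else 0
  list(intra = intra, cut = cut)
}

#' Partition the motif graph into dense clusters
#'
#' Greedy modularity clustering is applied per connected component; the
#' resulting partition is accepted only if the mean intra-cluster edge
#' density is at least the density of the cut edges, otherwise the
#' partition falls back to connected components (for which the cut density
#' is zero). Deterministic; `seed` is accepted for interface stability.
#'
#' @param g Graph from [build_motif_graph()].
#' @param seed Unused by the deterministic algorithm; kept for contract.
#' @return List of character vectors of motif ids (disjoint, covering all
#'   nodes; singletons allowed).
#' @export
cluster_graph <- function(g, seed = 1) {
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(list())
  }
  comp <- igraph::components(g)$membership
  member <- comp
  for (ci in unique(comp)) {
    vs <- which(comp == ci)
    if (length(vs) < 4L) next # a split of <4 nodes can't beat its own density
    sub <- igraph::induced_subgraph(g, vs)
    ## modularity on the thresholded graph itself (unweighted): a dense
    ## near-clique then never splits, a bridged pair of cliques does
    cl <- igraph::membership(igraph::cluster_fast_greedy(sub, weights = NA))
    if (max(cl) > 1L) {
      dens <- partition_density(sub, as.integer(cl))
      if (dens$intra > dens$cut) {
        member[vs] <- max(member) + as.integer(cl)
      }
    }
  }
  member <- match(member, unique(member))
  split(igraph::V(g)$name, member)
}

#' Derive the unique motif (UM) of a motif cluster
#'
#' Pools all member sites, deduplicates sites at identical genomic
#' coordinates (chrom, start, end, strand), aligns members to the cluster's
#' reference member (the one with most sites, of the modal width) at the
#' similarity-maximizing offset/orientation, and rebuilds the count matrix
#' and PWM model from the aligned site sequences. Clusters whose pooled
#' site count falls below `min_sites` are flagged (`ok = FALSE`) rather
#' than silently dropped.
#'
#' @param cluster Character vector of member motif ids.
#' @param motifs Named list of `Motif` objects whose `sites` carry genomic
#'   coordinates (columns chrom, start, end, strand, seq).
#' @param um_id Label for the UM.
#' @param min_sites Below this pooled-site count the UM is flagged not
#'   usable (default 2).
#' @return A `UniqueMotif`: list(um_id, member_motifs, model, counts,
#'   sites, ok, drop_reason).
#' @export
derive_um <- function(cluster, motifs, um_id = "UM1", min_sites = 2) {
  members <- motifs[cluster]
  stopifnot(length(members) >= 1L)
  widths <- vapply(members, `[[`, 0, "width")
  modal_w <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
  cand <- members[widths == modal_w]
  ref <- cand[[which.max(vapply(cand, function(m) nrow(m$sites), 0))]]
  wr <- ref$width

  pooled <- lapply(members, function(m) {
    s <- m$sites
    s$member <- m$motif_id
    al <- motif_align(ref$model, m$model)
    if (al$rc) {
      s$strand <- ifelse(s$strand == "+", "-", "+")
      s$seq <- vapply(s$seq, function(x) decode_dna(rc_codes(encode_dna(x))), "")
      al2 <- motif_align(ref$model, pwm_revcomp(m$model))
      al$offset <- al2$offset
    }
    off <- al$offset # member column 1 sits at ref column 1 + off... shift sites
    lo <- 1L - off
    plus <- s$strand == "+"
    s$start <- ifelse(plus, s$start + (lo - 1L), s$end - (lo - 1L) - wr)
    s$end <- s$start + wr
    s$seq <- ifelse(lo >= 1L & (lo + wr - 1L) <= m$width,
                    substr(s$seq, lo, lo + wr - 1L), NA_character_)
    s
  })
  sites <- do.call(rbind, pooled)
  rownames(sites) <- NULL
  if (all(c("chrom", "start", "end") %in% names(sites))) {
    key <- paste(sites$chrom, sites$start, sites$end, sites$strand)
  } else {
    key <- paste(sites$peak_id, sites$offset, sites$strand)
  }
  sites <- sites[!duplicated(key), , drop = FALSE]

  seqs <- sites$seq[!is.na(sites$seq) & nchar(sites$seq) == wr]
  cnt <- matrix(0L, 4, wr)
  for (x in seqs) {
    cc <- encode_dna(x)
    if (anyNA(cc)) next
    cnt[cbind(cc, seq_len(wr))] <- cnt[cbind(cc, seq_len(wr))] + 1L
  }
  ok <- nrow(sites) >= min_sites && sum(cnt) > 0
  structure(list(
    um_id = um_id, member_motifs = cluster,
    model = if (sum(cnt) > 0) pwm_model(cnt, background = ref$model$background)
            else ref$model,
    counts = cnt, sites = sites, ok = ok,
    drop_reason = if (ok) NA_character_ else
      sprintf("pooled sites (%d) below min_sites (%d)", nrow(sites), min_sites)
  ), class = "UniqueMotif")
}

#' @export
print.UniqueMotif <- function(x, ...) {
  cat(sprintf("<UniqueMotif %s> members=%d sites=%d ok=%s consensus=%s\n",
              x$um_id, length(x$member_motifs), nrow(x$sites), x$ok,
              pwm_consensus(x$model)))
  invisible(x)
}
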