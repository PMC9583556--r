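#' Interaction score between two unique motifs
#'
#' Over the datasets D containing sites of both UMs, accumulate
#' (1/|d(U_i)| + 1/|d(U_j)|) * sum_{s in S} 150/r(s), where |d(U_k)| is the
#' number of peaks in dataset d with at least one U_k site, S the peaks of d
#' containing sites of both UMs, and r(s) the shortest edge-to-edge distance
#' in bp between any U_i site and any U_j site in peak s, floored at 1 bp
#' (overlapping or abutting sites would otherwise make 150/r undefined or
#' unbounded). The accumulated total is divided by |D|. UMs that never
#' co-occur in any dataset score 0.
#'
#' Site tables must carry `dataset_id`, `peak_id`, `start`, `end` columns.
#'
#' @param ui,uj `UniqueMotif` objects.
#' @return Non-negative weight.
#' @export
interaction_score <- function(ui, uj) {
  si <- ui$sites
  sj <- uj$sites
  shared_ds <- intersect(unique(si$dataset_id), unique(sj$dataset_id))
  total <- 0
  n_shared <- 0L
  for (d in shared_ds) {
    di <- si[si$dataset_id == d, , drop = FALSE]
    dj <- sj[sj$dataset_id == d, , drop = FALSE]
    shared_peaks <- intersect(unique(di$peak_id), unique(dj$peak_id))
    if (!length(shared_peaks)) next
    n_shared <- n_shared + 1L
    inv <- 1 / length(unique(di$peak_id)) + 1 / length(unique(dj$peak_id))
    dist_sum <- sum(vapply(shared_peaks, function(p) {
      a <- di[di$peak_id == p, , drop = FALSE]
      b <- dj[dj$peak_id == p, , drop = FALSE]
      ## shortest edge-to-edge gap over all site pairs in this peak
      gaps <- outer(a$start, b$end, "-")
      gaps2 <- outer(a$end, b$start, function(x, y) y - x)
      r <- min(pmax(gaps, gaps2)) # elementwise max of the two one-sided gaps
      150 / max(r, 1)
    }, numeric(1)))
    total <- total + inv * dist_sum
  }
  if (n_shared == 0L) {
    return(0)
  }
  total / n_shared
}

#' Build the fully connected UM interaction network
#'
#' @param ums Named list of `UniqueMotif` objects (usable ones).
#' @return An `InteractionNetwork`: list with `um_ids` and a symmetric
#'   non-negative `weights` matrix (diagonal 0).
#' @export
build_network <- function(ums) {
  ids <- vapply(ums, `[[`, "", "um_id")
  n <- length(ums)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s <- interaction_score(ums[[i]], ums[[j]])
        w[i, j] <- s
        w[j, i] <- s
      }
    }
  }
  structure(list(um_ids = ids, weights = w), class = "InteractionNetwork")
}

#' Shuffle the weights of an interaction network
#'
#' The multiset of off-diagonal upper-triangle weights is permuted;
#' symmetry is preserved. Deterministic given `seed`.
#'
#' @param net An `InteractionNetwork`.
#' @param seed RNG seed.
#' @return A new `InteractionNetwork` with permuted weights.
#' @export
shuffle_weights <- function(net, seed = 1) {
  stopifnot(inherits(net, "InteractionNetwork"))
  w <- net$weights
  ut <- upper.tri(w)
  vals <- w[ut]
  set.seed(seed)
  vals <- vals[sample.int(length(vals))]
  w[ut] <- vals
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  net$weights <- w
  net
}

#' Write an interaction network as edge-list and matrix TSVs
#' @param net An `InteractionNetwork`.
#' @param edge_file,matrix_file Output paths (either may be NULL).
#' @export
write_network <- function(net, edge_file = NULL, matrix_file = NULL) {
  if (!is.null(edge_file)) {
    idx <- which(upper.tri(net$weights), arr.ind = TRUE)
    el <- data.frame(um_i = net$um_ids[idx[, 1]], um_j = net$um_ids[idx[, 2]],
                     weight = net$weights[idx])
    data.table::fwrite(el, edge_file, sep = "\t", quote = FALSE)
  }
  if (!is.null(matrix_file)) {
    out <- data.frame(um_id = net$um_ids, net$weights, check.names = FALSE)
    data.table::fwrite(out, matrix_file, sep = "\t", quote = FALSE)
  }
  invisible(net)
}
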