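sharp_model_from <- function(consensus, sharpness = 0.9) {
  codes <- crmscout:::encode_dna(consensus)
  p <- matrix((1 - sharpness) / 3, 4, length(codes))
  p[cbind(codes, seq_along(codes))] <- sharpness
  pwm_model(round(p * 1000))
}

test_that("motif similarity is maximal for self and reverse complement", {
  m <- sharp_model_from("ACGTACGTAC")
  expect_equal(motif_similarity(m, m), 1.0)
  rc <- crmscout:::pwm_revcomp(m)
  expect_equal(motif_similarity(m, rc), 1.0)
  ## disjoint single-base columns have total-variation similarity 0
  a <- pwm_model(matrix(rep(c(1000, 0, 0, 0), 6), 4), pseudocount = 1e-9)
  b <- pwm_model(matrix(rep(c(0, 1000, 0, 0), 6), 4), pseudocount = 1e-9)
  expect_lt(motif_similarity(a, b), 1e-5)
  ## too little overlap scores 0
  short_a <- sharp_model_from("ACGTAC")
  wide_b <- sharp_model_from("GGGGGGGGGGGGGGGGGGGG")
  expect_equal(motif_similarity(short_a, wide_b, min_overlap = 21), 0)
})

test_that("shifted copies of one motif align at the shifting offset", {
  m1 <- sharp_model_from("AACGTACGTT")
  m2 <- sharp_model_from("ACGTACGTTG") # m1 shifted left by one
  al <- motif_align(m1, m2)
  expect_equal(al$offset, 1L)
  expect_false(al$rc)
  expect_gt(al$score, 0.85)
})

test_that("graph edges obey the strict similarity cutoff", {
  m <- toy_motif("m1", paste0("p", 1:5))
  m2 <- toy_motif("m2", paste0("q", 1:5))
  g <- build_motif_graph(list(m, m2), edge_cutoff = 0.8)
  expect_equal(igraph::ecount(g), 1) # identical PWMs, similarity 1
  ## a pair at exactly the cutoff gets no edge
  g2 <- build_motif_graph(list(m, m2), edge_cutoff = 1.0)
  expect_equal(igraph::ecount(g2), 0)
  dis <- list(toy_motif("a", paste0("p", 1:10), consensus = "AAAAAAAAAA"),
              toy_motif("b", paste0("q", 1:10), consensus = "CCCCCCCCCC"),
              toy_motif("c", paste0("r", 1:10), consensus = "GCGCGTTCGC"))
  expect_equal(igraph::ecount(build_motif_graph(dis)), 0)
})

test_that("two cliques joined by a bridge split into exactly two clusters", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("m", 1:10)
  cl <- cluster_graph(g, seed = 1)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], paste0("m", 1:5))
  expect_setequal(cl[[2]], paste0("m", 6:10))
  ## density oracle: exhaustive bipartition confirms this is the best cut
  dens_gap <- function(side) {
    memb <- ifelse(seq_len(10) %in% side, 1L, 2L)
    d <- crmscout:::partition_density(g, memb)
    d$intra - d$cut
  }
  best <- -Inf
  best_side <- NULL
  for (mask in 1:510) { # proper non-trivial subsets containing node 1
    side <- which(bitwAnd(2^(0:9), mask * 2) > 0)
    side <- union(1L, side)
    if (length(side) == 10) next
    gap <- dens_gap(side)
    if (gap > best) {
      best <- gap
      best_side <- side
    }
  }
  expect_setequal(paste0("m", best_side), cl[[1]])
})

test_that("cliques stay whole and isolated nodes become singletons", {
  clique <- igraph::make_full_graph(6)
  igraph::V(clique)$name <- paste0("c", 1:6)
  expect_length(cluster_graph(clique), 1)
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("x", "y", "z")
  cl <- cluster_graph(lone)
  expect_length(cl, 3)
  ## partition property: disjoint cover of the node set
  expect_setequal(unlist(cl), c("x", "y", "z"))
})

test_that("clustering output is always a partition of the graph nodes", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    g <- igraph::sample_gnp(n, 0.3)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    cl <- cluster_graph(g, seed = rep)
    expect_setequal(unlist(cl), paste0("v", seq_len(n)))
    expect_equal(sum(lengths(cl)), n) # disjoint
    ## every cluster is connected
    for (cc in cl) {
      sub <- igraph::induced_subgraph(g, cc)
      expect_true(igraph::is_connected(sub) || length(cc) == 1L)
    }
  }
})

test_that("a cluster of identical motifs yields that motif as its UM", {
  ms <- list(m1 = toy_motif("m1", paste0("p", 1:8), gstart = seq(0, 700, 100)),
             m2 = toy_motif("m2", paste0("q", 1:8), dataset_id = "ds2",
                            gstart = seq(0, 700, 100) + 5000))
  um <- derive_um(c("m1", "m2"), ms, um_id = "UM1")
  expect_true(um$ok)
  expect_equal(nrow(um$sites), 16) # distinct genomic coordinates
  expect_equal(pwm_consensus(um$model), "ACGTACGTAC")
  ## duplicated genomic sites collapse
  ms$m2$sites$start <- ms$m1$sites$start
  ms$m2$sites$end <- ms$m1$sites$end
  um2 <- derive_um(c("m1", "m2"), ms)
  expect_equal(nrow(um2$sites), 8)
})

test_that("a planted motif family collapses to the planted consensus UM", {
  set.seed(22)
  consensus <- "TTGACGTCAA"
  mk_jittered <- function(id, ds, n) {
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(consensus, "")[[1]]
      j <- sample(10, 1)
      if (i %% 4 == 0) s[j] <- sample(c("A", "C", "G", "T"), 1)
      paste(s, collapse = "")
    }, "")
    codes <- lapply(seqs, crmscout:::encode_dna)
    cnt <- matrix(0L, 4, 10)
    for (cc in codes) cnt[cbind(cc, 1:10)] <- cnt[cbind(cc, 1:10)] + 1L
    sites <- data.frame(peak_id = paste0(id, "_p", seq_len(n)), offset = 0L,
                        strand = "+", seq = seqs, score = NA_real_,
                        dataset_id = ds, chrom = "chr1",
                        start = seq_len(n) * 1000 + match(id, letters) * 13)
    sites$end <- sites$start + 10
    structure(list(motif_id = id, dataset_id = ds, width = 10L, counts = cnt,
                   model = pwm_model(cnt), sites = sites), class = "Motif")
  }
  ms <- list(a = mk_jittered("a", "d1", 20), b = mk_jittered("b", "d2", 20),
             c = mk_jittered("c", "d3", 20))
  um <- derive_um(c("a", "b", "c"), ms)
  expect_equal(pwm_consensus(um$model), consensus)
  expect_equal(nrow(um$sites), 60)
})

test_that("clusters with too few pooled sites are flagged, not dropped", {
  ms <- list(m1 = toy_motif("m1", "p1", gstart = 0))
  um <- derive_um("m1", ms, min_sites = 5)
  expect_false(um$ok)
  expect_match(um$drop_reason, "below min_sites")
})
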