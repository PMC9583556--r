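test_that("site projection maps offsets, deduplicates and drops weak sites", {
  set.seed(41)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(1, 20000)))
  consensus <- "TTGACGTCAA"
  s <- as.character(genome[[1]])
  substr(s, 10038, 10047) <- consensus # 0-based [10037, 10047)
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  sites <- data.frame(peak_id = c("p1", "p2"), offset = c(37L, 37L),
                      strand = "+", seq = consensus, score = NA_real_,
                      dataset_id = c("d1", "d2"), chrom = "chr1",
                      start = 10037, end = 10047)
  um <- toy_um("UM1", sites, consensus = consensus, sharpness = 0.95)
  proj <- project_sites(list(um), genome)
  ## duplicate genomic site from two datasets collapses to one record
  expect_equal(nrow(proj), 1)
  expect_equal(proj$start, 10037)
  expect_equal(proj$end, 10047)
  expect_gt(proj$score, 0)
  ## a site whose genome sequence scores non-positively is dropped
  um_bad <- um
  um_bad$sites$start <- c(500, 600)
  um_bad$sites$end <- c(510, 610)
  expect_equal(nrow(project_sites(list(um_bad), genome)), 0)
  ## out-of-bounds coordinates raise
  um_oob <- um
  um_oob$sites$start <- 19995
  um_oob$sites$end <- 20005
  expect_error(project_sites(list(um_oob), genome), "bounds")
})

test_that("the 300-bp linking rule forms CRMCs with an exact complement", {
  covered <- data.frame(chrom = "chr1", start = 0, end = 1000)
  two <- data.frame(chrom = "chr1", start = c(100, 400), end = c(110, 410),
                    strand = "+", um_id = "U1", score = 1)
  ## gap 290 <= 300 -> one CRMC spanning [100, 410)
  p <- partition_crmcs(two, covered, max_gap = 300)
  expect_equal(nrow(p$crmcs), 1)
  expect_equal(p$crmcs$start, 100)
  expect_equal(p$crmcs$end, 410)
  expect_equal(p$non_crmcs,
               data.frame(chrom = "chr1", start = c(0, 410),
                          end = c(100, 1000)))
  ## gap 301 -> two CRMCs
  two$start[2] <- 411
  two$end[2] <- 421
  expect_equal(nrow(partition_crmcs(two, covered)$crmcs), 2)
  ## a site outside the covered region is kept with a warning
  expect_warning(partition_crmcs(
    data.frame(chrom = "chr1", start = 5000, end = 5010, strand = "+",
               um_id = "U1", score = 1), covered), "outside")
})

test_that("partition exactness holds bp-by-bp on randomized instances", {
  set.seed(42)
  for (rep in 1:50) {
    L <- 3000
    nc <- sample(1:4, 1)
    cs <- sort(sample(seq(0, L - 200, 10), nc))
    covered <- data.frame(chrom = "chrT", start = cs,
                          end = pmin(cs + sample(100:600, nc, TRUE), L))
    npos <- sample(0:12, 1)
    sites <- if (npos > 0) {
      cov_pos <- unlist(mapply(seq, covered$start, covered$end - 10,
                               SIMPLIFY = FALSE))
      st <- sample(cov_pos, min(npos, length(cov_pos)))
      data.frame(chrom = "chrT", start = st, end = st + 10, strand = "+",
                 um_id = "U1", score = 1)
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 strand = character(), um_id = character(), score = numeric())
    }
    p <- partition_crmcs(sites, covered, max_gap = sample(c(50, 300), 1))
    ## per-bp brute-force set arithmetic oracle
    bp <- function(df) {
      v <- logical(L)
      for (i in seq_len(nrow(df))) {
        if (df$end[i] > df$start[i]) v[(df$start[i] + 1):df$end[i]] <- TRUE
      }
      v
    }
    cov_v <- bp(p$covered)
    crm_v <- bp(p$crmcs)
    non_v <- bp(p$non_crmcs)
    expect_identical(crm_v | non_v, cov_v)
    expect_false(any(crm_v & non_v))
  }
})

test_that("islands merge on shared bp only, never on abutment", {
  s <- data.frame(chrom = "chr1",
                  start = c(100, 105, 200, 210), end = c(110, 117, 210, 220),
                  um_id = c("U1", "U2", "U1", "U3"))
  isl <- merge_islands(s)
  ## [100,110) + [105,117) share bp -> one island; the abutting pair at 210
  ## shares no bp under half-open coordinates -> two islands
  expect_equal(nrow(isl), 3)
  expect_equal(isl$start, c(100, 200, 210))
  expect_equal(isl$end, c(117, 210, 220))
  expect_equal(isl$um_ids[1], "U1,U2")
  ## non-overlapping sites stay as-is
  apart <- data.frame(chrom = "chr1", start = c(0, 50), end = c(10, 60),
                      um_id = "U1")
  expect_equal(nrow(merge_islands(apart)), 2)
})

test_that("the CRM score matches hand-evaluated cases and its invariants", {
  net <- fake_net(c("U1", "U2", "U3"), 1)
  ## n = 2, weight 1.5, scores 3 and 5 -> (2/1) * 1.5 * 8 = 24
  net2 <- fake_net(c("U1", "U2"), 1.5)
  two <- data.frame(um_id = c("U1", "U2"), score = c(3, 5))
  expect_equal(crm_score(two, net2), 24.0)
  ## n = 3, all weights 1, all scores 1 -> (2/2) * (2 + 2 + 2) = 6
  three <- data.frame(um_id = c("U1", "U2", "U3"), score = 1)
  expect_equal(crm_score(three, net), 6.0)
  ## single-site convention and empty error
  expect_equal(crm_score(three[1, ], net), 0)
  expect_error(crm_score(three[0, ], net), "zero sites")
  ## invariance under site reordering
  expect_equal(crm_score(two[2:1, ], net2), 24.0)
})

test_that("the pair sum grows when a positive site joins, vs brute force", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    ids <- paste0("U", 1:6)
    w <- matrix(runif(36), 6, 6, dimnames = list(ids, ids))
    w <- (w + t(w)) / 2
    diag(w) <- 0
    net <- structure(list(um_ids = ids, weights = w),
                     class = "InteractionNetwork")
    sites <- data.frame(um_id = sample(ids, n, TRUE),
                        score = runif(n, 0.1, 5))
    ## brute-force pair-sum oracle
    brute <- function(s) {
      tot <- 0
      for (i in seq_len(nrow(s) - 1)) {
        for (j in seq(i + 1, nrow(s))) {
          tot <- tot + w[s$um_id[i], s$um_id[j]] * (s$score[i] + s$score[j])
        }
      }
      2 / (nrow(s) - 1) * tot
    }
    expect_equal(crm_score(sites, net), brute(sites))
    bigger <- rbind(sites, data.frame(um_id = sample(ids, 1),
                                      score = runif(1, 0.1, 5)))
    ## the raw pair sum (score * (n-1)/2) never decreases with a new site
    expect_gte(crm_score(bigger, net) * (nrow(bigger) - 1),
               crm_score(sites, net) * (nrow(sites) - 1))
  }
})

test_that("functional state calls need a single bp of peak overlap", {
  sites <- data.frame(chrom = "chr1", start = 100, end = 110)
  expect_equal(functional_state(sites,
                                data.frame(chrom = "chr1", start = 105,
                                           end = 400)), "bound")
  expect_equal(functional_state(sites,
                                data.frame(chrom = "chr1", start = 109,
                                           end = 400)), "bound")
  expect_equal(functional_state(sites,
                                data.frame(chrom = "chr1", start = 110,
                                           end = 400)), "unbound")
  expect_equal(functional_state(sites, data.frame(chrom = character(),
                                                  start = numeric(),
                                                  end = numeric())),
               "unbound")
})
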