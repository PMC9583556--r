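bed <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end)
}

test_that("recall applies the 50%-of-shorter rule inclusively", {
  ## identical intervals recall trivially
  r <- recall_elements(bed(0, 100), bed(0, 100))
  expect_equal(r$sensitivity, 1)
  ## overlap 50 = exactly 50% of the shorter (100) -> recalled
  expect_equal(recall_elements(bed(0, 100), bed(50, 200))$sensitivity, 1)
  ## overlap 49 with both elements 100 bp long -> below half, not recalled
  expect_equal(recall_elements(bed(51, 151), bed(0, 100))$sensitivity, 0)
  ## monotone: adding predictions never lowers sensitivity
  ref <- bed(c(0, 1000, 2000), c(300, 1300, 2300))
  few <- bed(0, 300)
  more <- bed(c(0, 1000), c(300, 1300))
  expect_gte(recall_elements(more, ref)$sensitivity,
             recall_elements(few, ref)$sensitivity)
})

test_that("multi-recalls resolve to the longest-overlap predicted element", {
  pred <- bed(c(0, 40), c(50, 200))
  ref <- bed(0, 100)
  r <- recall_elements(pred, ref)
  expect_equal(nrow(r$mapping), 1)
  expect_equal(r$mapping$pred_idx, 2) # overlap 60 beats overlap 50
  lr <- length_ratio_stats(r$mapping)
  expect_equal(lr$median, 160 / 100)
})

test_that("length ratios summarize the recalling/recalled pairs", {
  pred <- bed(c(0, 1000), c(200, 1400))
  ref <- bed(c(0, 1000), c(200, 1200))
  r <- recall_elements(pred, ref)
  lr <- length_ratio_stats(r$mapping)
  expect_equal(sort(lr$ratios), c(1, 2))
  expect_equal(lr$median, 1.5)
  same <- recall_elements(ref, ref)
  expect_true(all(length_ratio_stats(same$mapping)$ratios == 1))
})

test_that("matched controls preserve the length multiset deterministically", {
  set.seed(61)
  universe <- bed(c(0, 50000), c(30000, 90000))
  for (rep in 1:5) {
    lens <- sample(100:2000, 20)
    pred <- bed(seq(0, by = 3000, length.out = 20),
                seq(0, by = 3000, length.out = 20) + lens)
    ctrl <- matched_controls(pred, universe, seed = rep)
    expect_equal(sort(ctrl$end - ctrl$start), sort(lens))
    expect_identical(matched_controls(pred, universe, seed = rep), ctrl)
    ## no self-overlap
    expect_equal(coverage_bp(ctrl), sum(lens))
    ## all inside the universe
    expect_equal(coverage_bp(crmscout:::interval_setdiff(ctrl, universe)), 0)
  }
  expect_error(matched_controls(bed(0, 5e6), universe), "cannot host")
})

test_that("controls recall planted elements only at the chance level", {
  set.seed(62)
  G <- 1e6
  universe <- bed(0, G)
  refs <- bed(seq(0, by = 5000, length.out = 150),
              seq(0, by = 5000, length.out = 150) + 400)
  pred <- refs # perfect predictor
  expect_equal(recall_elements(pred, refs)$sensitivity, 1)
  ctrl <- matched_controls(pred, universe, seed = 3)
  ctrl_rec <- recall_elements(ctrl, refs)
  ## analytic chance expectation for >= 50%-of-shorter hits
  a <- 400 + 400 - 400 + 1 # favorable starts per (control, ref) pair
  p_one <- 1 - (1 - a / G)^nrow(ctrl)
  expected <- nrow(refs) * p_one
  expect_lte(sum(ctrl_rec$flags$recalled), 3 * expected + 3)
  expect_lt(ctrl_rec$sensitivity, recall_elements(pred, refs)$sensitivity)
})

test_that("neutrality proportions agree across both implementations", {
  prof <- data.frame(chrom = "chr1", start = 0:3, end = 1:4,
                     score = c(-2, 0, 2, 0.5))
  iv <- bed(0, 4)
  expect_equal(proportion_of_neutrality(iv, prof, delta = 1), 0.5)
  all_zero <- data.frame(chrom = "chr1", start = 0:9, end = 1:10, score = 0)
  expect_equal(proportion_of_neutrality(bed(0, 10), all_zero), 1.0)
  ## dual implementation on a 10-kb fixture, agreement to 1e-12
  set.seed(63)
  prof2 <- data.frame(chrom = "chr1", start = 0:9999, end = 1:10000,
                      score = round(rnorm(10000, 0, 1.2), 3))
  ivs <- bed(c(100, 4000, 9000), c(1500, 6000, 9900))
  expect_equal(proportion_of_neutrality(ivs, prof2, method = "rle"),
               proportion_of_neutrality(ivs, prof2, method = "per_position"),
               tolerance = 1e-12)
  ## missing positions are excluded, with a warning below 99% scored
  gap_prof <- prof2[prof2$start < 5000, ]
  expect_warning(p <- proportion_of_neutrality(ivs, gap_prof), "scored")
  expect_equal(p, proportion_of_neutrality(bed(c(100, 4000), c(1500, 5000)),
                                           prof2))
  expect_error(proportion_of_neutrality(bed(90000, 90100), prof2),
               "no queried position")
})

test_that("position decomposition is exact and symmetric", {
  a <- bed(0, 100)
  b <- bed(50, 150)
  d <- decompose_positions(a, b)
  expect_equal(d, list(shared_bp = 50, a_specific_bp = 50, b_specific_bp = 50))
  expect_equal(decompose_positions(a, bed(500, 600))$shared_bp, 0)
  set.seed(64)
  for (rep in 1:10) {
    mk <- function() {
      s <- sort(sample(0:9000, 5))
      bed(s, s + sample(100:800, 5, TRUE))
    }
    x <- mk()
    y <- mk()
    d <- decompose_positions(x, y)
    ## brute-force per-bp oracle
    pos <- function(df) unique(unlist(mapply(function(s, e) seq(s, e - 1),
                                             df$start, df$end,
                                             SIMPLIFY = FALSE)))
    px <- pos(x)
    py <- pos(y)
    expect_equal(d$shared_bp, length(intersect(px, py)))
    expect_equal(d$a_specific_bp, length(setdiff(px, py)))
    expect_equal(d$shared_bp + d$a_specific_bp, coverage_bp(x))
    ## symmetry under swapping the sets
    ds <- decompose_positions(y, x)
    expect_equal(ds$shared_bp, d$shared_bp)
    expect_equal(ds$a_specific_bp, d$b_specific_bp)
  }
})
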