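test_that("fixture configs validate their fields", {
  expect_s3_class(fixture_config(), "FixtureConfig")
  expect_error(fixture_config(motif_width = 4))
  expect_error(fixture_config(decoy_peak_fraction = 1.2))
  expect_error(fixture_config(n_crms = 0))
  expect_error(fixture_config(cooperation_pairs = cbind(1, 99)))
})

test_that("same seed and config give byte-identical fixtures", {
  cfg <- fixture_config(seed = 101, n_chroms = 1, chrom_length = 30000,
                        n_tfs = 4, n_cell_types = 1, n_crms = 6,
                        peaks_per_dataset = 25)
  d1 <- file.path(tempdir(), "fx_det1")
  d2 <- file.path(tempdir(), "fx_det2")
  unlink(c(d1, d2), recursive = TRUE)
  make_fixture(cfg, d1)
  make_fixture(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("ground truth respects the configured structure", {
  fx <- small_fixture()
  gt <- fx$ground_truth
  cfg <- fx$config
  ## CRM intervals are mutually disjoint
  expect_equal(coverage_bp(gt$crms), sum(gt$crms$end - gt$crms$start))
  expect_equal(nrow(gt$crms), cfg$n_crms)
  ## site counts bounded by the per-CRM range
  expect_gte(nrow(gt$sites), cfg$n_crms * cfg$sites_per_crm[1])
  expect_lte(nrow(gt$sites), cfg$n_crms * cfg$sites_per_crm[2])
  ## every site lies within exactly one CRM
  inside <- crmscout:::interval_setdiff(gt$sites[, c("chrom", "start", "end")],
                                        gt$crms)
  expect_equal(nrow(inside), 0)
  ## per-CRM sites never overlap each other
  expect_equal(coverage_bp(gt$sites[, c("chrom", "start", "end")]),
               nrow(gt$sites) * cfg$motif_width)
})

test_that("noise-free peaks sit on planted sites and cover all of them", {
  cfg <- fixture_config(seed = 103, n_chroms = 1, chrom_length = 50000,
                        n_tfs = 4, n_cell_types = 2, n_crms = 8,
                        decoy_peak_fraction = 0, summit_jitter_sd = 0,
                        peaks_per_dataset = 40)
  dir <- file.path(tempdir(), "fx_clean")
  unlink(dir, recursive = TRUE)
  fx <- make_fixture(cfg, dir)
  gt <- fx$ground_truth
  mids <- floor((gt$sites$start + gt$sites$end) / 2)
  man <- read.delim(fx$paths$manifest)
  windows <- list()
  for (i in seq_len(nrow(man))) {
    ds <- read_narrowpeak(file.path(fx$dir, man$path[i]),
                          dataset_id = man$dataset_id[i])
    summit <- ds$peaks$start + ds$peaks$summit_offset
    tf_mids <- mids[sprintf("TF%02d", gt$sites$tf) == man$tf[i]]
    ## every peak summit equals a planted site midpoint of its own TF
    expect_true(all(summit %in% tf_mids), label = man$dataset_id[i])
    windows[[i]] <- extend_peaks(ds, c(chr1 = cfg$chrom_length))
  }
  ## union of extended peaks covers 100% of planted site positions
  uncovered <- crmscout:::interval_setdiff(
    gt$sites[, c("chrom", "start", "end")], do.call(rbind, windows))
  expect_equal(nrow(uncovered), 0)
})

test_that("decoy peaks fall outside planted CRMs", {
  fx <- small_fixture()
  man <- read.delim(fx$paths$manifest)
  ds <- read_narrowpeak(file.path(fx$dir, man$path[1]))
  n_decoy <- round(fx$config$peaks_per_dataset *
                     fx$config$decoy_peak_fraction)
  decoys <- utils::tail(ds$peaks, n_decoy)
  hits <- GenomicRanges::findOverlaps(
    crmscout:::bed_to_gr(decoys), crmscout:::bed_to_gr(fx$ground_truth$crms))
  expect_length(hits, 0)
})

test_that("background composition matches the configured base frequencies", {
  fx <- small_fixture()
  bg <- crmscout:::interval_setdiff(
    data.frame(chrom = names(fx$genome), start = 0,
               end = Biostrings::width(fx$genome)),
    fx$ground_truth$crms)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(bg)), function(i) {
    as.character(Biostrings::subseq(fx$genome[[bg$chrom[i]]],
                                    bg$start[i] + 1, bg$end[i]))
  }, ""))
  ## non-overlapping 3-mers are independent draws under the i.i.d. model
  f <- Biostrings::oligonucleotideFrequency(seqs, 3, step = 3,
                                            simplify.as = "collapsed")
  p <- f / sum(f)
  ## uniform default: every 3-mer expected at 1/64
  se <- sqrt(1 / 64 * (1 - 1 / 64) / sum(f))
  expect_true(all(abs(p - 1 / 64) < 3 * se))
})

test_that("the conservation track separates CRM from background positions", {
  fx <- small_fixture()
  prof <- read_bedgraph(fx$paths$conservation)
  crm_neut <- proportion_of_neutrality(fx$ground_truth$crms, prof)
  bg <- crmscout:::interval_setdiff(
    data.frame(chrom = names(fx$genome), start = 0,
               end = Biostrings::width(fx$genome)),
    fx$ground_truth$crms)
  bg_neut <- proportion_of_neutrality(bg, prof)
  expect_lt(crm_neut, 0.2)
  expect_gt(bg_neut, 0.8)
})
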