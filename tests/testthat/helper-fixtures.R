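## Shared builders for in-code fixtures; heavyweight objects are memoized so
## several test files can reuse one pipeline run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, maker) {
  if (!exists(key, envir = .cache)) assign(key, maker(), envir = .cache)
  get(key, envir = .cache)
}

## a Motif whose sites are identical copies of `consensus` on the given peaks
toy_motif <- function(id, peak_ids, consensus = "ACGTACGTAC",
                      dataset_id = "ds1", offset = 0L,
                      chrom = "chr1", gstart = NULL) {
  codes <- crmscout:::encode_dna(consensus)
  w <- length(codes)
  cnt <- matrix(0L, 4, w)
  cnt[cbind(codes, seq_len(w))] <- length(peak_ids)
  n <- length(peak_ids)
  sites <- data.frame(peak_id = peak_ids, offset = rep(offset, n),
                      strand = rep("+", n), seq = rep(consensus, n),
                      score = rep(NA_real_, n), stringsAsFactors = FALSE)
  sites$dataset_id <- rep(dataset_id, n)
  sites$chrom <- rep(chrom, n)
  sites$start <- if (is.null(gstart)) seq(0, by = 100, length.out = n)
                 else gstart
  sites$end <- sites$start + w
  structure(list(motif_id = id, dataset_id = dataset_id, width = w,
                 counts = cnt, model = pwm_model(cnt), sites = sites),
            class = "Motif")
}

## a UniqueMotif with explicit genomic sites and a sharp PWM on `consensus`
toy_um <- function(id, sites, consensus = "ACGTACGTAC", sharpness = 0.9) {
  codes <- crmscout:::encode_dna(consensus)
  w <- length(codes)
  p <- matrix((1 - sharpness) / 3, 4, w)
  p[cbind(codes, seq_len(w))] <- sharpness
  cnt <- round(p * 100)
  structure(list(um_id = id, member_motifs = character(),
                 model = pwm_model(cnt), counts = cnt, sites = sites,
                 ok = TRUE, drop_reason = NA_character_),
            class = "UniqueMotif")
}

## UM site rows for interaction-score tests
um_site <- function(dataset_id, peak_id, start, end, chrom = "chr1") {
  data.frame(dataset_id = dataset_id, peak_id = peak_id, chrom = chrom,
             start = start, end = end, strand = "+", stringsAsFactors = FALSE)
}

## a fully connected network with constant off-diagonal weight
fake_net <- function(ids, w) {
  m <- matrix(w, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  structure(list(um_ids = ids, weights = m), class = "InteractionNetwork")
}

random_sharp_model <- function(width = 10, sharpness = 0.985) {
  consensus <- sample.int(4L, width, replace = TRUE)
  p <- matrix((1 - sharpness) / 3, 4, width)
  p[cbind(consensus, seq_len(width))] <- sharpness
  pwm_model(round(p * 1000))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

## one small end-to-end pipeline run shared by pipeline/evaluation tests
small_fixture <- function() {
  memo("small_fixture", function() {
    dir <- file.path(tempdir(), "crmscout_small_fixture")
    unlink(dir, recursive = TRUE)
    cfg <- fixture_config(seed = 7, n_chroms = 2, chrom_length = 100000,
                          n_tfs = 6, n_cell_types = 2, n_crms = 20,
                          peaks_per_dataset = 40)
    make_fixture(cfg, dir)
  })
}

small_pipeline_run <- function() {
  memo("small_pipeline_run", function() {
    fx <- small_fixture()
    out <- file.path(tempdir(), "crmscout_small_run")
    unlink(out, recursive = TRUE)
    run_pipeline(fx$paths$manifest, fx$paths$genome, fx$paths$chrom_sizes,
                 out, conservation = fx$paths$conservation,
                 truth_crms = fx$ground_truth$crms)
  })
}

write_lines_np <- function(lines, path = tempfile(fileext = ".narrowPeak")) {
  writeLines(lines, path)
  path
}

np_line <- function(chrom = "chr1", start = 100, end = 400, name = "p1",
                    enrich = 25, summit = -1) {
  paste(chrom, start, end, name, 0, ".", enrich, -1, -1, summit, sep = "\t")
}
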