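#' Configuration of the synthetic ChIP-seq fixture generator
#'
#' The generator emulates the statistical structure the pipeline exploits:
#' cooperative TF motifs co-planted inside compact CRMs that are reused
#' across cell types, peaks centered near planted sites, decoy peaks
#' outside CRMs, and a conservation track concentrated away from the
#' neutral band over CRM positions.
#'
#' @param seed RNG seed; same seed + same config gives byte-identical files.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_tfs,n_cell_types One peak dataset is generated per (TF, cell
#'   type) pair.
#' @param motif_width Planted motif width in bp (>= 6; default 10).
#' @param motif_sharpness Probability of the consensus base at each motif
#'   column (default 0.985; the off bases share the remainder).
#' @param n_crms Number of planted CRMs.
#' @param crm_length_mean Mean CRM length in bp (default 400).
#' @param sites_per_crm Length-2 range of TFBS counts per CRM (default 4:8).
#' @param cooperation_pairs 2-column matrix of cooperative TF index pairs;
#'   default pairs TF 1-2, 3-4, ...
#' @param coplant_fraction Fraction of a pair's CRMs carrying both members
#'   (default 0.8).
#' @param peaks_per_dataset Peaks per (TF, cell type) file (default 60).
#' @param peak_length_mean Mean called-peak length in bp (default 300).
#' @param decoy_peak_fraction Fraction of peaks placed outside all CRMs.
#' @param summit_jitter_sd SD (bp) of Gaussian jitter between a peak summit
#'   and its planted site midpoint (default 0).
#' @param conservation_neutral_sd SD of the neutral conservation score.
#' @param conservation_constrained_shift Mean shift of CRM-position scores
#'   away from 0 (default 2).
#' @param base_freqs Background base distribution (A, C, G, T).
#' @return A validated `FixtureConfig` list.
#' @export
fixture_config <- function(seed = 1, n_chroms = 2, chrom_length = 100000,
                           n_tfs = 6, n_cell_types = 2, motif_width = 10,
                           motif_sharpness = 0.985, n_crms = 20,
                           crm_length_mean = 400, sites_per_crm = c(4, 8),
                           cooperation_pairs = NULL, coplant_fraction = 0.8,
                           peaks_per_dataset = 60, peak_length_mean = 300,
                           decoy_peak_fraction = 0.1, summit_jitter_sd = 0,
                           conservation_neutral_sd = 0.5,
                           conservation_constrained_shift = 2,
                           base_freqs = rep(0.25, 4)) {
  if (is.null(cooperation_pairs)) {
    k <- n_tfs %/% 2
    cooperation_pairs <- cbind(seq(1, 2 * k - 1, by = 2),
                               seq(2, 2 * k, by = 2))
  }
  cooperation_pairs <- matrix(as.integer(cooperation_pairs), ncol = 2)
  cfg <- list(seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
              n_tfs = n_tfs, n_cell_types = n_cell_types,
              motif_width = motif_width, motif_sharpness = motif_sharpness,
              n_crms = n_crms, crm_length_mean = crm_length_mean,
              sites_per_crm = sites_per_crm,
              cooperation_pairs = cooperation_pairs,
              coplant_fraction = coplant_fraction,
              peaks_per_dataset = peaks_per_dataset,
              peak_length_mean = peak_length_mean,
              decoy_peak_fraction = decoy_peak_fraction,
              summit_jitter_sd = summit_jitter_sd,
              conservation_neutral_sd = conservation_neutral_sd,
              conservation_constrained_shift = conservation_constrained_shift,
              base_freqs = base_freqs / sum(base_freqs))
  counts <- c(n_chroms, chrom_length, n_tfs, n_cell_types, n_crms,
              crm_length_mean, peaks_per_dataset, peak_length_mean)
  stopifnot(all(counts > 0), motif_width >= 6,
            decoy_peak_fraction >= 0, decoy_peak_fraction <= 1,
            coplant_fraction >= 0, coplant_fraction <= 1,
            length(sites_per_crm) == 2, sites_per_crm[1] <= sites_per_crm[2],
            all(cooperation_pairs >= 1), all(cooperation_pairs <= n_tfs),
            motif_sharpness > 0.25, motif_sharpness < 1,
            summit_jitter_sd >= 0, conservation_neutral_sd > 0)
  structure(cfg, class = "FixtureConfig")
}

sample_motif_site <- function(prob, strand) {
  w <- ncol(prob)
  bases <- vapply(seq_len(w), function(j) {
    sample.int(4L, 1L, prob = prob[, j])
  }, integer(1))
  if (strand == "-") bases <- rc_codes(bases)
  bases
}

#' Generate a complete synthetic fixture on disk
#'
#' Writes a miniature genome (FASTA), a chromosome sizes table, one
#' narrowPeak file per (TF, cell type) with a dataset manifest, a
#' conservation bedGraph at 1-bp resolution (run-length merged), and
#' ground-truth BED files for planted CRMs and TFBSs. Real peaks cycle
#' through the TF's planted sites (so every site is peak-covered whenever
#' a dataset has at least as many non-decoy peaks as the TF has sites);
#' decoy peaks avoid all CRMs.
#'
#' @param config A `FixtureConfig`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `config`, file `paths`, the
#'   in-memory `genome` (`DNAStringSet`) and `ground_truth` (list: `crms`,
#'   `sites`, `cooperation_pairs`, `motif_matrices`).
#' @export
make_fixture <- function(config, dir) {
  stopifnot(inherits(config, "FixtureConfig"))
  set.seed(config$seed)
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms), chroms)

  ## planted motifs: sharp PWM around a random consensus per TF
  w <- config$motif_width
  s <- config$motif_sharpness
  motif_matrices <- lapply(seq_len(config$n_tfs), function(t) {
    consensus <- sample.int(4L, w, replace = TRUE, prob = config$base_freqs)
    p <- matrix((1 - s) / 3, 4, w, dimnames = list(BASES, NULL))
    p[cbind(consensus, seq_len(w))] <- s
    p
  })

  ## i.i.d. background genome
  genome_codes <- lapply(chroms, function(ch) {
    sample.int(4L, config$chrom_length, replace = TRUE,
               prob = config$base_freqs)
  })
  names(genome_codes) <- chroms

  ## ---- place CRMs without overlap (bounded retries) ----
  min_len <- config$sites_per_crm[2] * (w + 20)
  crm_len <- pmax(min_len, round(stats::rnorm(config$n_crms,
                                              config$crm_length_mean,
                                              0.15 * config$crm_length_mean)))
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)
  crms <- vector("list", config$n_crms)
  for (i in seq_len(config$n_crms)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      ch <- chroms[sample.int(length(chroms), 1L)]
      start <- floor(stats::runif(1) * (config$chrom_length - crm_len[i]))
      end <- start + crm_len[i]
      occ <- occupied[[ch]]
      if (is.null(occ) || !any(occ$start < end + 50 & start < occ$end + 50)) {
        crms[[i]] <- data.frame(chrom = ch, start = start, end = end)
        occupied[[ch]] <- rbind(occ, data.frame(start = start, end = end))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("CRM placement failed after bounded retries; ",
           "reduce n_crms or crm_length_mean")
    }
  }
  crms <- do.call(rbind, crms)
  crms$name <- sprintf("crm%04d", seq_len(nrow(crms)))

  ## ---- plant TFBSs: a cooperative pair per CRM plus random fillers ----
  npair <- nrow(config$cooperation_pairs)
  sites <- list()
  for (i in seq_len(nrow(crms))) {
    nsite <- sample(seq(config$sites_per_crm[1], config$sites_per_crm[2]), 1L)
    pair <- config$cooperation_pairs[(i - 1L) %% npair + 1L, ]
    if (stats::runif(1) < config$coplant_fraction) {
      ## cooperative CRM: the pair's sites alternate along the module
      tfs <- rep(pair, length.out = nsite)
    } else {
      ## solitary CRM: one lone site of one pair member (alternating),
      ## the rest filled by random other TFs at single copy
      lone <- pair[1L + (i - 1L) %/% npair %% 2L]
      others <- setdiff(seq_len(config$n_tfs), lone)
      tfs <- c(lone, sample(others, min(nsite - 1L, length(others))))
      tfs <- rep(tfs, length.out = nsite)
    }
    ## one site per equal slot keeps sites disjoint inside the CRM
    slot <- (crms$end[i] - crms$start[i]) %/% nsite
    for (k in seq_len(nsite)) {
      off <- floor(stats::runif(1) * (slot - w))
      start <- crms$start[i] + (k - 1L) * slot + off
      strand <- sample(c("+", "-"), 1L)
      codes <- sample_motif_site(motif_matrices[[tfs[k]]], strand)
      genome_codes[[crms$chrom[i]]][(start + 1L):(start + w)] <- codes
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = crms$chrom[i], start = start, end = start + w,
        tf = tfs[k], strand = strand, crm = crms$name[i]
      )
    }
  }
  sites <- do.call(rbind, sites)

  ## ---- per-(TF, cell type) narrowPeak datasets ----
  manifest <- list()
  n_decoy <- round(config$peaks_per_dataset * config$decoy_peak_fraction)
  n_real <- config$peaks_per_dataset - n_decoy
  for (t in seq_len(config$n_tfs)) {
    tf_sites <- sites[sites$tf == t, , drop = FALSE]
    for (ct in seq_len(config$n_cell_types)) {
      id <- sprintf("TF%02d_CT%d", t, ct)
      ## cycle through the TF's sites so none is systematically missed
      idx <- rep(sample.int(nrow(tf_sites)),
                 length.out = max(n_real, 0L))
      plen <- pmax(50, round(stats::rnorm(config$peaks_per_dataset,
                                          config$peak_length_mean,
                                          0.2 * config$peak_length_mean)))
      rows <- list()
      for (k in seq_len(n_real)) {
        st <- tf_sites[idx[k], ]
        summit <- floor((st$start + st$end) / 2)
        if (config$summit_jitter_sd > 0) {
          summit <- summit + round(stats::rnorm(1, 0,
                                                config$summit_jitter_sd))
          summit <- min(max(summit, 0), sizes[[st$chrom]] - 1)
        }
        start <- max(0, summit - plen[k] %/% 2)
        end <- min(sizes[[st$chrom]], start + plen[k])
        rows[[k]] <- data.frame(chrom = st$chrom, start = start, end = end,
                                summit = summit)
      }
      for (k in seq_len(n_decoy)) {
        repeat {
          ch <- chroms[sample.int(length(chroms), 1L)]
          start <- floor(stats::runif(1) *
                           (config$chrom_length - plen[n_real + k]))
          end <- start + plen[n_real + k]
          occ <- occupied[[ch]]
          if (is.null(occ) || !any(occ$start < end & start < occ$end)) break
        }
        rows[[n_real + k]] <- data.frame(chrom = ch, start = start,
                                         end = end,
                                         summit = start + (end - start) %/% 2)
      }
      pk <- do.call(rbind, rows)
      enr <- 20 + stats::rexp(nrow(pk), rate = 1 / 30)
      np <- data.frame(
        chrom = pk$chrom, start = pk$start, end = pk$end,
        name = sprintf("%s_p%03d", id, seq_len(nrow(pk))),
        score = pmin(1000L, round(enr * 10)), strand = ".",
        signal = round(enr, 3), p = -1, q = -1,
        summit = pk$summit - pk$start
      )
      path <- file.path(dir, "peaks", paste0(id, ".narrowPeak"))
      write_bed(np, path)
      ## manifest paths are relative to the manifest so the fixture is
      ## relocatable and byte-identical across output directories
      manifest[[length(manifest) + 1L]] <- data.frame(
        dataset_id = id, tf = sprintf("TF%02d", t),
        cell_type = sprintf("CT%d", ct),
        path = file.path("peaks", basename(path))
      )
    }
  }
  manifest <- do.call(rbind, manifest)

  ## ---- conservation track: CRM positions shifted off the neutral band ----
  cons_path <- file.path(dir, "conservation.bedGraph")
  unlink(cons_path)
  for (ch in chroms) {
    score <- stats::rnorm(config$chrom_length, 0,
                          config$conservation_neutral_sd)
    in_crm <- crms[crms$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(in_crm))) {
      span <- (in_crm$start[i] + 1L):in_crm$end[i]
      score[span] <- score[span] + config$conservation_constrained_shift
    }
    tmp <- tempfile()
    write_bedgraph(ch, seq_len(config$chrom_length) - 1L,
                   round(score, 3), tmp)
    file.append(cons_path, tmp)
    unlink(tmp)
  }

  ## ---- genome, sizes, manifest, ground truth ----
  genome <- Biostrings::DNAStringSet(vapply(genome_codes, decode_dna, ""))
  names(genome) <- chroms
  genome_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_path)
  sizes_path <- file.path(dir, "chrom.sizes")
  write_chrom_sizes(sizes, sizes_path)
  manifest_path <- file.path(dir, "manifest.tsv")
  data.table::fwrite(manifest, manifest_path, sep = "\t", quote = FALSE)
  crm_bed <- file.path(dir, "truth", "crms.bed")
  write_bed(data.frame(crms[c("chrom", "start", "end", "name")],
                       score = 0, strand = "+"), crm_bed)
  site_bed <- file.path(dir, "truth", "sites.bed")
  write_bed(data.frame(sites[c("chrom", "start", "end")],
                       name = sprintf("TF%02d", sites$tf), score = 0,
                       strand = sites$strand), site_bed)

  invisible(list(
    dir = dir, config = config,
    paths = list(genome = genome_path, chrom_sizes = sizes_path,
                 manifest = manifest_path, conservation = cons_path,
                 crms = crm_bed, sites = site_bed),
    genome = genome,
    ground_truth = list(crms = crms, sites = sites,
                        cooperation_pairs = config$cooperation_pairs,
                        motif_matrices = motif_matrices)
  ))
}
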