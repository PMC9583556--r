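#' Pipeline configuration with the method's default thresholds
#'
#' @param min_enrichment,min_peaks Peak-filter thresholds (20, 20).
#' @param window Extended peak window length (1000 bp).
#' @param sc_cutoff Co-occurrence cutoff for CPs (0.7, strict).
#' @param sim_cutoff Motif-graph edge cutoff (0.8, strict).
#' @param max_gap TFBS linking distance for CRMCs (300 bp, inclusive).
#' @param delta Neutral conservation band half-width (1).
#' @param p_cutoff Empirical p-value cutoff for calling CRMs (0.05).
#' @param motif_width,z_min,score_frac,max_motifs Motif-finder settings
#'   (see [discover_motifs()]).
#' @param seed Base seed; per-stage seeds are derived from it.
#' @return A `RunConfig` list.
#' @export
pipeline_config <- function(min_enrichment = 20, min_peaks = 20,
                            window = 1000, sc_cutoff = 0.7, sim_cutoff = 0.8,
                            max_gap = 300, delta = 1, p_cutoff = 0.05,
                            motif_width = 10, z_min = 6, score_frac = 0.6,
                            max_motifs = 6, seed = 1) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value` (comments with `#`); numeric values are
#' converted. Unknown keys raise an error.
#'
#' @param path Config file path.
#' @return A `RunConfig`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1)
  vals <- lapply(kv, function(x) {
    v <- x[[2]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else gsub("[\"']", "", v)
  })
  known <- names(formals(pipeline_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, stats::setNames(vals, keys))
}

write_flat_config <- function(config, path) {
  flat <- config[!vapply(config, is.null, TRUE)]
  writeLines(sprintf("%s = %s", names(flat),
                     vapply(flat, function(v) paste(format(v), collapse = ","),
                            "")), path)
}

PIPELINE_STAGES <- c("ingest", "motifs", "cps", "cluster", "network",
                     "predict", "calibrate", "evaluate")

needs <- function(state, keys, producer) {
  miss <- keys[!keys %in% names(state)]
  if (length(miss)) {
    stop("missing prerequisite '", miss[1], "': run stage '", producer,
         "' first", call. = FALSE)
  }
}

#' Run the CRM prediction pipeline
#'
#' Orchestrates the stages: ingest (read, filter, extend peaks), motifs
#' (per-dataset discovery), cps (co-occurring pair selection), cluster
#' (motif clustering into UMs), network (UM interaction network), predict
#' (site projection, CRMC partition, scoring, islands), calibrate (Markov
#' null, shuffled network, empirical p-values, FDR table), and evaluate
#' (recall of truth elements and conservation analysis, when inputs are
#' given). Intermediate state is saved in `out_dir` so later stages can be
#' run in separate calls; a JSON run summary with per-stage counts is
#' written at the end.
#'
#' @param manifest Path to a dataset manifest TSV (dataset_id, tf,
#'   cell_type, path).
#' @param genome Path to the genome FASTA (or a named `DNAStringSet`).
#' @param chrom_sizes Path to a chrom-sizes table (or named vector).
#' @param out_dir Output directory.
#' @param config A `RunConfig`.
#' @param stages Character vector of stages to run, in order; `"all"` runs
#'   everything.
#' @param conservation Optional bedGraph path for the evaluate stage.
#' @param truth_crms Optional BED path of reference elements for recall.
#' @return Invisibly, the pipeline state (list); `state$summary` holds the
#'   per-stage counts written to `run_summary.json`.
#' @export
run_pipeline <- function(manifest, genome, chrom_sizes, out_dir,
                         config = pipeline_config(), stages = "all",
                         conservation = NULL, truth_crms = NULL) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  stopifnot(all(stages %in% PIPELINE_STAGES))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(out_dir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  state$summary <- state$summary %||% list()
  write_flat_config(config, file.path(out_dir, "config.txt"))

  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)

  for (stage in stages) {
    state <- switch(stage,
      ingest = stage_ingest(state, manifest, chrom_sizes, config),
      motifs = stage_motifs(state, genome, config),
      cps = stage_cps(state, config, out_dir),
      cluster = stage_cluster(state, config, out_dir),
      network = stage_network(state, config),
      predict = stage_predict(state, genome, config, out_dir),
      calibrate = stage_calibrate(state, genome, config, out_dir),
      evaluate = stage_evaluate(state, config, conservation, truth_crms)
    )
    saveRDS(state, state_path)
  }
  jsonlite::write_json(state$summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(state)
}

stage_ingest <- function(state, manifest, chrom_sizes, config) {
  man <- data.table::fread(manifest, sep = "\t", data.table = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(manifest), man$path[rel])
  datasets <- list()
  dropped <- 0L
  for (i in seq_len(nrow(man))) {
    ds <- read_narrowpeak(man$path[i], dataset_id = man$dataset_id[i],
                          tf = man$tf[i], cell_type = man$cell_type[i])
    ds <- filter_dataset(ds, config$min_enrichment, config$min_peaks)
    if (is.null(ds)) {
      dropped <- dropped + 1L
      next
    }
    ds$windows <- extend_peaks(ds, chrom_sizes, config$window)
    datasets[[ds$dataset_id]] <- ds
  }
  covered <- interval_union(
    do.call(rbind, lapply(datasets, function(d) {
      d$windows[c("chrom", "start", "end")]
    }))
  )
  state$datasets <- datasets
  state$covered <- covered
  state$chrom_sizes <- chrom_sizes
  state$summary$datasets_kept <- length(datasets)
  state$summary$datasets_dropped_filter <- dropped
  state$summary$covered_bp <- coverage_bp(covered)
  state
}

stage_motifs <- function(state, genome, config) {
  needs(state, "datasets", "ingest")
  chrom_seqs <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(chrom_seqs) <- names(genome)
  motifs_by_ds <- list()
  for (k in seq_along(state$datasets)) {
    ds <- state$datasets[[k]]
    wdf <- ds$windows
    seqs <- vapply(seq_len(nrow(wdf)), function(i) {
      substr(chrom_seqs[[wdf$chrom[i]]], wdf$start[i] + 1L, wdf$end[i])
    }, "")
    names(seqs) <- wdf$name
    motifs <- discover_motifs(
      seqs, width = config$motif_width, z_min = config$z_min,
      score_frac = config$score_frac, max_motifs = config$max_motifs,
      min_peaks = config$min_peaks, dataset_id = ds$dataset_id,
      seed = config$seed + k
    )
    ## attach genomic coordinates to the window-relative site offsets
    motifs <- lapply(motifs, function(m) {
      wi <- match(m$sites$peak_id, wdf$name)
      m$sites$chrom <- wdf$chrom[wi]
      m$sites$start <- wdf$start[wi] + m$sites$offset
      m$sites$end <- m$sites$start + m$width
      m$sites$dataset_id <- ds$dataset_id
      m
    })
    if (length(motifs)) motifs_by_ds[[ds$dataset_id]] <- motifs
  }
  state$motifs_by_ds <- motifs_by_ds
  state$summary$datasets_with_motifs <- length(motifs_by_ds)
  state$summary$motifs <- sum(lengths(motifs_by_ds))
  state
}

stage_cps <- function(state, config, out_dir = NULL) {
  needs(state, "motifs_by_ds", "motifs")
  cps <- list()
  kept <- list()
  for (id in names(state$motifs_by_ds)) {
    tab <- select_cps(state$motifs_by_ds[[id]], cutoff = config$sc_cutoff)
    if (nrow(tab) == 0L) next
    cps[[id]] <- tab
    keep <- attr(tab, "kept_motifs")
    kept[[id]] <- Filter(function(m) m$motif_id %in% keep,
                         state$motifs_by_ds[[id]])
  }
  state$cps <- cps
  state$cp_motifs <- unlist(unname(kept), recursive = FALSE)
  names(state$cp_motifs) <- vapply(state$cp_motifs, `[[`, "", "motif_id")
  state$summary$datasets_with_cps <- length(cps)
  state$summary$cps <- sum(vapply(cps, nrow, 0L))
  state$summary$cp_motifs <- length(state$cp_motifs)
  if (!is.null(out_dir) && length(cps)) {
    data.table::fwrite(data.table::rbindlist(cps),
                       file.path(out_dir, "cps.tsv"), sep = "\t")
  }
  state
}

stage_cluster <- function(state, config, out_dir = NULL) {
  needs(state, "cp_motifs", "cps")
  g <- build_motif_graph(state$cp_motifs, edge_cutoff = config$sim_cutoff)
  clusters <- cluster_graph(g, seed = config$seed + 1000L)
  ums <- lapply(seq_along(clusters), function(i) {
    derive_um(clusters[[i]], state$cp_motifs, um_id = sprintf("UM%03d", i))
  })
  names(ums) <- vapply(ums, `[[`, "", "um_id")
  state$clusters <- clusters
  state$ums <- Filter(function(u) u$ok, ums)
  state$summary$clusters <- length(clusters)
  state$summary$ums <- length(state$ums)
  if (!is.null(out_dir) && length(state$ums)) {
    membership <- data.frame(
      um_id = rep(names(ums), lengths(clusters)),
      motif_id = unlist(clusters, use.names = FALSE)
    )
    data.table::fwrite(membership, file.path(out_dir, "clusters.tsv"),
                       sep = "\t")
    write_meme(lapply(state$ums, `[[`, "model"),
               file.path(out_dir, "ums.meme"))
    um_sites <- do.call(rbind, lapply(state$ums, function(u) {
      data.frame(chrom = u$sites$chrom, start = u$sites$start,
                 end = u$sites$end, name = u$um_id, score = 0,
                 strand = u$sites$strand)
    }))
    write_bed(um_sites, file.path(out_dir, "um_sites.bed"))
  }
  state
}

stage_network <- function(state, config) {
  needs(state, "ums", "cluster")
  state$network <- build_network(state$ums)
  state$summary$network_edges <- sum(state$network$weights[
    upper.tri(state$network$weights)] > 0)
  state
}

stage_predict <- function(state, genome, config, out_dir) {
  needs(state, c("ums", "network", "covered"), "network")
  sites <- project_sites(state$ums, genome)
  partition <- partition_crmcs(sites, state$covered, max_gap = config$max_gap)
  partition <- score_crmcs(partition, state$network)
  state$sites <- sites
  state$partition <- partition
  state$islands <- merge_islands(sites)
  write_bed(partition$crmcs[c("chrom", "start", "end", "crmc_id",
                              "s_crm", "n_sites")],
            file.path(out_dir, "crmcs.bed"))
  write_bed(state$islands[c("chrom", "start", "end", "um_ids")],
            file.path(out_dir, "islands.bed"))
  state$summary$projected_sites <- nrow(sites)
  state$summary$crmcs <- nrow(partition$crmcs)
  state$summary$crmc_bp <- coverage_bp(partition$crmcs)
  state$summary$non_crmc_bp <- coverage_bp(partition$non_crmcs)
  state$summary$tfbs_islands <- nrow(state$islands)
  state
}

stage_calibrate <- function(state, genome, config, out_dir) {
  needs(state, c("partition", "network"), "predict")
  crmcs <- state$partition$crmcs
  chrom_seqs <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(chrom_seqs) <- names(genome)
  crmc_seqs <- vapply(seq_len(nrow(crmcs)), function(i) {
    substr(chrom_seqs[[crmcs$chrom[i]]], crmcs$start[i] + 1L, crmcs$end[i])
  }, "")
  mm <- fit_markov(crmc_seqs, order = 3)
  lens <- pmax(crmcs$end - crmcs$start, mm$order + 1L)
  null_seqs <- sample_null_crmcs(mm, lens, seed = config$seed + 2000L)
  shuf <- shuffle_weights(state$network, seed = config$seed + 3000L)
  null_scores <- score_null_sequences(null_seqs, state$ums, shuf,
                                      max_gap = config$max_gap,
                                      score_frac = config$score_frac)
  dist <- score_distributions(crmcs$s_crm, null_scores)
  state$partition$crmcs$p_value <- empirical_pvalue(crmcs$s_crm, dist)
  state$dist <- dist
  state$fdr_table <- estimate_fdr(dist)
  data.table::fwrite(data.frame(null_score = null_scores),
                     file.path(out_dir, "null_scores.tsv"), sep = "\t")
  data.table::fwrite(state$fdr_table, file.path(out_dir, "fdr_table.tsv"),
                     sep = "\t")
  crm <- state$partition$crmcs
  state$summary$crms_at_p_cutoff <- sum(crm$p_value <= config$p_cutoff)
  state$summary$expected_fp <- sum(state$fdr_table$expected_fp)
  state
}

stage_evaluate <- function(state, config, conservation = NULL,
                          truth_crms = NULL) {
  needs(state, "partition", "predict")
  crm <- state$partition$crmcs
  if (!is.null(crm$p_value)) {
    crm <- crm[crm$p_value <= config$p_cutoff, , drop = FALSE]
  }
  if (!is.null(truth_crms)) {
    truth <- if (is.character(truth_crms)) {
      stats::setNames(utils::read.table(truth_crms, sep = "\t")[, 1:3],
                      c("chrom", "start", "end"))
    } else truth_crms
    rec <- recall_elements(crm, truth)
    universe <- data.frame(chrom = names(state$chrom_sizes), start = 0,
                           end = unname(state$chrom_sizes))
    ctrl <- matched_controls(crm, universe, seed = config$seed + 4000L)
    rec_ctrl <- recall_elements(ctrl, truth)
    state$recall <- rec
    state$summary$truth_recall <- rec$sensitivity
    state$summary$control_recall <- rec_ctrl$sensitivity
  }
  if (!is.null(conservation)) {
    prof <- if (is.character(conservation)) read_bedgraph(conservation)
            else conservation
    state$summary$neutrality_crmc <- proportion_of_neutrality(
      state$partition$crmcs, prof, delta = config$delta)
    state$summary$neutrality_non_crmc <- proportion_of_neutrality(
      state$partition$non_crmcs, prof, delta = config$delta)
  }
  state
}
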