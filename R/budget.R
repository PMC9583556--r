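#' Ratio of CRM-candidate position density in uncovered vs covered regions
#'
#' From the proportions of neutrality (fraction of positions whose
#' conservation score lies in the neutral band) of the peak-covered regions
#' (`pc`), the peak-uncovered regions (`pu`) and the non-CRMCs (`pn`), the
#' excess of constrained positions over the non-CRMC baseline gives the
#' density ratio ((1-pu)-(1-pn)) / ((1-pc)-(1-pn)).
#'
#' @param pc,pu,pn Proportions of neutrality in [0, 1]; typically
#'   pn > pu > pc.
#' @return The density ratio (a fraction; multiply by 100 for percent).
#' @export
density_ratio <- function(pc, pu, pn) {
  den <- (1 - pc) - (1 - pn)
  if (den == 0) stop("density ratio undefined: pc equals pn")
  ((1 - pu) - (1 - pn)) / den
}

#' Fold-coverage of the genome by fixed-length peak windows
#'
#' @param total_window_bp Summed length of all extended peak windows.
#' @param genome_length Mappable genome length in bp.
#' @return Fold coverage (total / genome).
#' @export
coverage_fold <- function(total_window_bp, genome_length) {
  total_window_bp / genome_length
}

#' Assemble the inputs of the genome-budget estimator
#'
#' All scalar quantities feeding the semi-theoretic estimate of the genome
#' fraction encoding CRMs. False-positive input is accepted either as a
#' (count, mean length) pair or directly as a genome fraction
#' (`fp_genome_fraction`).
#'
#' @param genome_length Mappable genome length in bp.
#' @param covered_fraction Fraction of the genome covered by extended peaks.
#' @param crmc_fraction,non_crmc_fraction Genome fractions of CRMCs and
#'   non-CRMCs.
#' @param neutrality_covered,neutrality_uncovered,neutrality_noncrmc
#'   Proportions of neutrality of covered, uncovered and non-CRMC positions.
#' @param expected_fp_count,fp_mean_length Expected false-positive CRMC
#'   count and their mean length in bp.
#' @param fp_genome_fraction Alternative direct FP genome fraction (used
#'   instead of count x length when not NULL).
#' @param fnr False negative rate for CRMC positions.
#' @param tfbs_fraction_of_crm Fraction of CRM length made of TFBSs.
#' @param mean_crm_length,mean_island_length Mean CRM and TFBS-island
#'   lengths in bp.
#' @param covered_fraction_denom Covered fraction used in the denominator
#'   of the uncovered-region term (defaults to `covered_fraction`).
#' @return A `BudgetInputs` list.
#' @export
budget_inputs <- function(genome_length = 2725521370,
                          covered_fraction = 0.799,
                          crmc_fraction = 0.555,
                          non_crmc_fraction = 0.244,
                          neutrality_covered = 0.78,
                          neutrality_uncovered = 0.83,
                          neutrality_noncrmc = 0.89,
                          expected_fp_count = 1486,
                          fp_mean_length = 64,
                          fp_genome_fraction = NULL,
                          fnr = 0.007,
                          tfbs_fraction_of_crm = 0.429,
                          mean_crm_length = 1893,
                          mean_island_length = 17,
                          covered_fraction_denom = covered_fraction) {
  x <- list(genome_length = genome_length,
            covered_fraction = covered_fraction,
            crmc_fraction = crmc_fraction,
            non_crmc_fraction = non_crmc_fraction,
            neutrality_covered = neutrality_covered,
            neutrality_uncovered = neutrality_uncovered,
            neutrality_noncrmc = neutrality_noncrmc,
            expected_fp_count = expected_fp_count,
            fp_mean_length = fp_mean_length,
            fp_genome_fraction = fp_genome_fraction,
            fnr = fnr,
            tfbs_fraction_of_crm = tfbs_fraction_of_crm,
            mean_crm_length = mean_crm_length,
            mean_island_length = mean_island_length,
            covered_fraction_denom = covered_fraction_denom)
  fr <- unlist(x[c("covered_fraction", "crmc_fraction", "non_crmc_fraction",
                   "neutrality_covered", "neutrality_uncovered",
                   "neutrality_noncrmc", "fnr", "tfbs_fraction_of_crm")])
  stopifnot(all(fr >= 0 & fr <= 1), genome_length > 0, fnr < 1)
  structure(x, class = "BudgetInputs")
}

#' Semi-theoretic estimate of the genome fraction encoding CRMs
#'
#' Follows a fixed arithmetic chain (all percentages of the genome unless
#' noted): FP fraction from the expected false-positive CRMCs; true CRMC
#' fraction = CRMC fraction - FP fraction; FN fraction = fnr x true CRMC
#' fraction / (1 - fnr); false omission rate of non-CRMCs = FN fraction /
#' non-CRMC fraction; true covered CRM fraction = CRMC - FP + FN; the
#' uncovered-region contribution = uncovered fraction x true covered CRM
#' fraction x density ratio / covered fraction; total = covered +
#' uncovered contributions; plus the derived share already predicted, the
#' TFBS genome fraction, and expected CRM / TFBS-island counts.
#'
#' Two rounding modes are provided. `"full"` propagates full precision.
#' `"printed"` rounds every intermediate to the precision at which the
#' chain's checkpoints are conventionally reported (percentages to 2
#' decimals, the FP fraction to 3 after an intermediate 4-decimal step --
#' which rounds 0.0035 up to 0.004 -- and the density ratio to 4 decimals),
#' so that downstream steps consume the reported values.
#'
#' @param inputs A `BudgetInputs`.
#' @param rounding "printed" (default) or "full".
#' @return A `BudgetEstimates` list; percent-scale fields end in `_pct`.
#' @export
budget <- function(inputs = budget_inputs(),
                   rounding = c("printed", "full")) {
  stopifnot(inherits(inputs, "BudgetInputs"))
  rounding <- match.arg(rounding)
  printed <- rounding == "printed"
  rnd <- function(x, d) if (printed) round_half_up(x, d) else x

  fp_pct_full <- if (!is.null(inputs$fp_genome_fraction)) {
    100 * inputs$fp_genome_fraction
  } else {
    100 * inputs$expected_fp_count * inputs$fp_mean_length /
      inputs$genome_length
  }
  fp_pct <- if (printed) round_half_up(round_half_up(fp_pct_full, 4), 3)
            else fp_pct_full

  crmc_pct <- 100 * inputs$crmc_fraction
  true_crmc_pct <- rnd(crmc_pct - fp_pct, 3)
  fdr_crmc_pct <- rnd(100 * fp_pct / crmc_pct, 3)

  fn_pct <- rnd(inputs$fnr * true_crmc_pct / (1 - inputs$fnr), 2)
  for_pct <- rnd(100 * fn_pct / (100 * inputs$non_crmc_fraction), 2)

  true_covered_pct <- rnd(crmc_pct - fp_pct + fn_pct, 2)

  ratio <- rnd(density_ratio(inputs$neutrality_covered,
                             inputs$neutrality_uncovered,
                             inputs$neutrality_noncrmc), 4)
  uncovered_fraction <- rnd(1 - inputs$covered_fraction, 3)
  uncovered_pct <- rnd(uncovered_fraction * (true_covered_pct / 100) * ratio /
                         inputs$covered_fraction_denom * 100, 2)

  total_pct <- rnd(true_covered_pct + uncovered_pct, 2)
  predicted_share_pct <- rnd(100 * true_covered_pct / total_pct, 2)
  tfbs_pct <- rnd(inputs$tfbs_fraction_of_crm * total_pct, 2)

  n_crms <- round(inputs$genome_length * rnd(total_pct / 100, 4) /
                    inputs$mean_crm_length)
  n_islands <- round(inputs$genome_length * rnd(tfbs_pct / 100, 4) /
                       inputs$mean_island_length)

  structure(list(
    density_ratio = ratio,
    density_ratio_pct = rnd(100 * ratio, 2),
    fp_pct = fp_pct,
    fp_pct_full = fp_pct_full,
    fdr_crmc_pct = fdr_crmc_pct,
    true_crmc_pct = true_crmc_pct,
    fn_pct = fn_pct,
    for_noncrmc_pct = for_pct,
    true_covered_crm_pct = true_covered_pct,
    uncovered_crm_pct = uncovered_pct,
    total_crm_pct = total_pct,
    predicted_share_pct = predicted_share_pct,
    tfbs_genome_pct = tfbs_pct,
    n_crms = n_crms,
    n_islands = n_islands,
    rounding = rounding
  ), class = "BudgetEstimates")
}

#' @export
print.BudgetEstimates <- function(x, ...) {
  cat(sprintf("<BudgetEstimates> (%s rounding)\n", x$rounding))
  cat(sprintf("  FP fraction of genome:        %.4g%% (full: %.5g%%)\n",
              x$fp_pct, x$fp_pct_full))
  cat(sprintf("  true CRMC fraction:           %.5g%%\n", x$true_crmc_pct))
  cat(sprintf("  FN fraction of genome:        %.4g%%\n", x$fn_pct))
  cat(sprintf("  FOR of non-CRMCs:             %.4g%%\n", x$for_noncrmc_pct))
  cat(sprintf("  true covered CRM fraction:    %.4f%%\n",
              x$true_covered_crm_pct))
  cat(sprintf("  uncovered/covered density:    %.2f%%\n",
              x$density_ratio_pct))
  cat(sprintf("  uncovered CRM fraction:       %.4g%%\n", x$uncovered_crm_pct))
  cat(sprintf("  total CRM fraction:           %.4f%%\n", x$total_crm_pct))
  cat(sprintf("  share already predicted:      %.2f%%\n",
              x$predicted_share_pct))
  cat(sprintf("  TFBS fraction of genome:      %.2f%%\n", x$tfbs_genome_pct))
  cat(sprintf("  expected CRMs:                %d\n", x$n_crms))
  cat(sprintf("  expected TFBS islands:        %d\n", x$n_islands))
  invisible(x)
}

#' Write budget estimates as a flat TSV
#' @param est A `BudgetEstimates`.
#' @param path Output path.
#' @export
write_budget <- function(est, path) {
  flat <- est[vapply(est, is.numeric, TRUE)]
  data.table::fwrite(data.frame(quantity = names(flat),
                                value = unlist(flat)),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
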