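---
title: "Predicting cis-regulatory modules from integrated TF ChIP-seq peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cis-regulatory modules from integrated TF ChIP-seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crmscout)
```

## The problem and the model

Enhancers, promoters and silencers — cis-regulatory modules (CRMs) — are
clusters of transcription factor binding sites (TFBSs) of cooperative TFs.
A single ChIP-seq experiment reveals where one TF binds in one cell type;
it says little about module structure. `crmscout` integrates *many* TF
ChIP-seq peak datasets at once and exploits a single biological
regularity: cooperative TFs are reused across cell types, so their binding
sites co-occur in the same stretches of DNA again and again, while
technical noise does not repeat.

The pipeline proceeds in stages, each with an explicit score:

1. **Peak ingestion.** Each narrowPeak dataset is filtered (enrichment
   score `>= 20`, at least 20 surviving peaks — both inequalities strict
   in the exclusion direction) and every surviving peak is replaced by a
   1,000-bp window centered on its summit (midpoint when no summit is
   called). Called peaks are much shorter than typical enhancers, and
   cooperative sites sit in the flanks, so fixed-width windows recover
   binding context that peak callers trim away. Windows are clipped, not
   shifted, at chromosome ends so the summit stays centered.
2. **Dataset overlap QC.** The symmetric overlap score
   `S_o(d_i, d_j) = 1/2 (o/|d_i| + o/|d_j|)` quantifies how much two
   datasets' windows coincide. The overlap numerator `o` is the count of
   intersecting window pairs, capped at `min(|d_i|, |d_j|)` so the score
   stays in [0, 1]; a base-pair variant is available behind the
   `unit = "bp"` flag. This stage is quality control, not a prediction
   step.
3. **Per-dataset motif discovery.** A deliberately simple, fully
   documented baseline finder: seed with k-mers over-represented against a
   0th-order background (z >= 6), collect at most one best site per window
   above a threshold set at 0.6 of the PWM's maximum attainable log-odds
   score (with an absolute floor of 1 bit per column), and iterate PWM
   re-estimation to convergence (max |dp| < 1e-4 or 50 iterations). A
   converged motif is kept only if its site count exceeds what its own
   PWM would collect from background sequence by the same z margin —
   computed exactly by per-column convolution of the discretized log-odds
   distribution. Any external finder can be substituted through a sites
   TSV (`motifs_from_sites_tsv()`); the discovery internals are
   intentionally not part of the method's contract.
4. **Co-occurring pairs (CPs).** Within each dataset,
   `S_c = o / max(|M_i|, |M_j|)` over *distinct peaks* containing each
   motif; pairs with `S_c > 0.7` (strict) are CPs. Motifs in no CP, and
   datasets retaining no CP, are dropped: a motif that does not co-occur
   with anything carries no module signal.
5. **Unique motifs (UMs).** CP motifs from all datasets are clustered by
   PWM similarity — the maximum over ungapped offsets and orientations of
   the mean per-column total-variation complement, minimum 6 aligned
   columns — with edges above 0.8 (strict). Dense subgraphs become
   clusters; each cluster's sites are pooled, deduplicated at identical
   genomic coordinates, and re-summarized as one UM. Clusters whose
   pooled sites fall below a minimum are flagged with a drop reason
   rather than silently removed.
6. **Interaction network.** Every UM pair is weighted by
   `S_INTER`, which rewards co-occurrence of two UMs across datasets,
   across shared peaks, and at short range: each shared peak contributes
   `150/r`, where `r` is the shortest edge-to-edge distance between sites
   of the two UMs in that peak, floored at 1 bp (the formula is undefined
   at zero distance, and overlapping sites do occur).
7. **CRM candidates.** UM sites are projected onto the genome, re-scored
   against their UM PWM, and kept only with a strictly positive log-odds
   score. Adjacent sites at most 300 bp apart (inclusive; roughly two
   nucleosomes) are linked; each maximal run is a CRM candidate (CRMC)
   spanning first-site start to last-site end, and every other covered
   position is a non-CRMC, so CRMCs and non-CRMCs exactly partition the
   peak-covered regions. Runs never straddle a gap between covered
   segments — without that rule a CRMC could annex never-covered
   sequence and the partition identity would fail. Lone sites form
   single-site CRMCs with score 0; overlapping sites merge into TFBS
   islands (abutting half-open intervals do not merge).
8. **Scoring and calibration.** A CRMC with sites `b_1..b_n` scores
   `S_CRM = 2/(n-1) * sum_{i<j} w[U(b_i),U(b_j)] (S(b_i)+S(b_j))`. The
   null model is a 3rd-order Markov chain fitted to the CRMC sequences
   themselves (a flag allows training on the whole covered region), from
   which one length-matched null sequence per CRMC is sampled. Null
   sequences are re-scanned with the UM PWMs — the only self-consistent
   reading — at the same site-acceptance threshold used during site
   collection, linked with the same 300-bp rule, and scored under a
   weight-shuffled network; when linking splits a null sequence into
   several runs, the null score is the maximum run score (0 when no run
   has two sites). Empirical p-values are `p = n(s)/M` with `n(s)` the
   count of null scores strictly above `s` and `M` the CRMC count (the
   null set is matched in number by construction, and the code asserts
   the match). A zero p-value is stored as 0 per the formula and rendered
   as "< 1/M" in reports.
9. **FDR estimation.** Per score bin (1 unit by default), expected true
   positives are `max(0, crmc - null)` and expected false positives
   `min(null, crmc)`, so TP + FP accounts for every CRMC; cumulative
   curves over decreasing cutoffs give the FDR at any score cutoff. The
   raw null count per bin is reported alongside.
10. **Genome budget.** A pure calculator chains the scalar estimates:
    FP fraction from expected FP count x mean length; true CRMC fraction;
    FN fraction from an assumed FNR; covered-region true CRM fraction;
    an uncovered-region term scaled by the conservation-derived density
    ratio `((1-p_u)-(1-p_n)) / ((1-p_c)-(1-p_n))`; and derived counts
    from mean CRM and island lengths.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_enrichment` | 20 | per-peak enrichment floor (narrowPeak col. 7) |
| `min_peaks` | 20 | minimum surviving peaks per dataset |
| `window` | 1000 bp | extended peak width |
| `sc_cutoff` | 0.7 | CP co-occurrence cutoff (strict) |
| `sim_cutoff` | 0.8 | motif-graph similarity cutoff (strict) |
| `max_gap` | 300 bp | TFBS linking distance (inclusive) |
| `delta` | 1 | neutral conservation band half-width |
| `p_cutoff` | 0.05 | p-value for calling CRMs from CRMCs |
| `motif_width` | 10 bp | baseline finder width (typical UM width) |
| `score_frac` | 0.6 | site threshold as fraction of max PWM score |

The narrowPeak enrichment column is configurable
(`read_narrowpeak(enrichment_col=)`): descriptions of per-peak scores
vary across repositories, and the filter should follow whatever column
carries the enrichment statistic; the standard signalValue column 7 is
the default.

`score_frac = 0.6` is a deliberate choice for sharp PWMs: with a
well-learned matrix it admits sites one mismatch from consensus while
excluding two-mismatch matches over a wide range of matrix sharpness;
at 0.65 the one-mismatch score sits exactly at the threshold boundary
and site capture becomes unstable to small re-estimation drift.

## What the synthetic generator emulates — and what it does not

`make_fixture()` builds a miniature genome with planted CRMs. Each CRM is
assigned a cooperative TF pair; in 80% of a pair's CRMs both members'
sites are planted in alternation (the cooperative signal), in the rest
one member appears alone with random other TFs at single copy. Site
sequences are drawn from sharp per-TF PWMs (consensus probability 0.985
per column). Per-(TF, cell type) narrowPeak files center non-decoy peaks
on the TF's planted sites — cycling through the sites so none is
systematically missed — with configurable summit jitter; decoy peaks
(10% by default) avoid all CRMs. The conservation track draws background
positions near zero and shifts CRM positions away from the neutral band.

This emulates: cooperative co-occurrence reused across cell types, decoy
peaks, summit noise, solitary binding, and the conservation contrast the
evaluation machinery consumes. It does not emulate: read-level noise or
peak calling, overlapping/competing sites of paralogous TFs, repeat
families, GC isochores, or motif families with degenerate/variable-width
matrices. Passing the end-to-end test therefore shows the pipeline's
stages compose correctly and recover clean planted structure; it is not
evidence about recovery rates on real chromatin data.

Generator defaults (2-Mb genome, 20 TFs, 5 cell types, 200 CRMs of mean
length 400 bp with 4–8 sites, 60 peaks per dataset of mean length 300 bp,
10% decoys) were chosen once to mirror the density regime the method
expects — CRMs a few hundred bp with a handful of cooperative sites,
peaks an order of magnitude sparser than the genome — and are not tuned
per test.

## Numerical choices

- **Coordinates.** All interval tables are 0-based half-open (BED);
  conversion to 1-based closed happens only at the `GenomicRanges`
  boundary. Abutting intervals share no base.
- **Ties in PWM alignment.** Periodic motifs make several offsets score
  identically; ties resolve toward larger column overlap, then the more
  central offset, then the forward orientation, keeping UM derivation
  stable.
- **Graph clustering.** The contract is a partition into connected,
  dense clusters. Greedy modularity (unweighted, on the thresholded
  graph) is applied per connected component, and a split is accepted only
  if intra-cluster edge density strictly exceeds the density of the cut;
  otherwise the component stays whole. A clique therefore never splits,
  while two cliques joined by a bridge do.
- **Pseudocounts.** 0.5 per PWM cell; 1 per Markov transition cell.
- **Distance floor.** `r := max(r, 1)` bp in the interaction score.
- **p-value ties.** Strictly-greater counting makes `empirical_pvalue`
  non-increasing and assigns single-site (score 0) CRMCs the largest
  p-value the null allows.
- **Null scanning threshold.** Null sequences are scanned at the same
  site-acceptance threshold as discovery-time site collection. Scanning
  at "any positive score" instead inflates the null site density
  relative to the candidates (whose sites all passed collection) and
  pushes every p-value toward 1.
- **FDR binning at small n.** The 1-unit default bin width mirrors
  genome-scale score densities; at the test scale (10^4 scores spread
  over hundreds of units) sparse bins would turn sampling noise into
  spurious TPs, so calibration checks use a bin width of 25.
- **Problem sizes in the test-suite.** The end-to-end check runs the
  2-Mb, 100-dataset fixture (about 4 minutes on one core); calibration
  checks use 5,000 null sequences of 3,000 bp (p-value uniformity) and
  2 x 10,000 of 500 bp (null-vs-null FDR); partition exactness is
  verified on 1,000 randomized instances against per-base set
  arithmetic.

## Design choices where the method statement is open

- **Overlap numerator.** "Overlap of two datasets" is counted in window
  pairs, capped to keep the score in [0, 1]; a bp-fraction variant is a
  flag. Neither count is canonical; the pair count is the one that makes
  the identical-dataset score exactly 1 regardless of window lengths.
- **Summit vs midpoint.** Extension centers on the summit when the
  narrowPeak summit column is non-negative, else on the midpoint — the
  summit is the more specific statement of a peak's binding position.
- **Cluster representatives.** Some motif clusters cannot yield a usable
  representative (too few distinct pooled sites); they are flagged with a
  recorded reason instead of being silently dropped, so UM counts are
  auditable.
- **FP decomposition.** Expected FPs per score bin are
  `min(null, crmc)`: expected falses among the candidates cannot exceed
  the candidates present, and only this reading makes TP + FP equal the
  total CRMC count.
- **Budget rounding.** The budget calculator reports both a
  full-precision chain and a "printed" chain whose intermediates are
  rounded at conventional reporting precision (the FP fraction passes
  through a 4-then-3-decimal rounding, which turns 0.0035% into 0.004%);
  the uncovered-region term takes its covered-fraction denominator as a
  separate input because reported chains sometimes carry a different
  rounding of the same quantity.
- **Sites outside covered regions.** Projected sites falling outside the
  extended-peak union are kept with a warning, not clipped: the union is
  a detection boundary, not a biological one.

## Known limitations

- The baseline motif finder is ZOOPS-like with a fixed width; it will
  fragment variable-width or multi-part motifs and reports at most six
  motifs per dataset by default. It exists so the pipeline is fully
  testable end to end; production users with a preferred discovery tool
  should feed its sites through the adapter.
- `S_INTER` is computed from pooled, deduplicated sites; extremely deep
  site lists in one dataset can dominate a UM pair's weight.
- The Markov null matches composition and length but not positional
  structure (e.g. CpG islands); p-values inherit that approximation.
- Matched controls are placed without self-overlap but independently of
  mappability or assembly gaps; on a real genome, supply a universe that
  excludes such regions.
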