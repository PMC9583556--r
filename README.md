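# crmscout

Genome-wide prediction of cis-regulatory modules (CRMs) and their
constituent transcription factor binding sites (TFBSs) by integrating many
TF ChIP-seq peak datasets.

A CRM — an enhancer, promoter or silencer — is a cluster of binding sites
of *cooperative* TFs. Because cooperative TFs are reused across cell
types, their sites co-occur in the same DNA repeatedly across independent
ChIP-seq experiments, while noise does not. `crmscout` turns that
regularity into predictions: it filters and extends peaks, finds motifs
per dataset, keeps only motif pairs that co-occur strongly, clusters them
across datasets into unique motifs (UMs), weights UM pairs by an
interaction score, links projected binding sites into CRM candidates
(CRMCs), and calibrates candidate scores against a sequence null.

The package is aimed at regulatory-genomics researchers who have (or can
simulate) a compendium of narrowPeak files for many TFs and cell types and
want auditable, score-based CRM calls plus the evaluation machinery to
judge them.

## The scores

With `|d|` the peak count of dataset `d`, `|M|` the number of peaks
containing motif `M`, and `o(...)` shared-peak counts:

- dataset overlap: `S_o(d_i, d_j) = 1/2 (o/|d_i| + o/|d_j|)`
- motif co-occurrence: `S_c(M_i, M_j) = o(M_i, M_j) / max(|M_i|, |M_j|)`;
  pairs with `S_c > 0.7` are co-occurring pairs (CPs)
- UM interaction:
  `S_INTER(U_i, U_j) = 1/|D| * sum_{d in D} (1/|d(U_i)| + 1/|d(U_j)|) *
  sum_{s} 150/r(s)`, over datasets `D` and peaks `s` holding both UMs,
  with `r(s)` the shortest site-to-site distance (floored at 1 bp)
- CRM score of a candidate with sites `b_1..b_n`:
  `S_CRM = 2/(n-1) * sum_{i<j} S_INTER[U(b_i), U(b_j)] (S(b_i) + S(b_j))`,
  where `S(b)` is the site's PWM log-odds (only positive-scoring sites
  count)
- empirical p-value: `p = n(s)/M` against length-matched 3rd-order Markov
  null sequences scored under a weight-shuffled network.

Sites at most 300 bp apart are linked into CRMCs; all other peak-covered
positions are non-CRMCs, an exact partition of the covered regions.

## Worked example

Everything is runnable without downloads: the package ships a synthetic
data generator that plants cooperative-motif CRMs in a miniature genome
and writes narrowPeak files, a conservation track and ground truth.

```r
library(crmscout)

cfg <- fixture_config(seed = 7, n_chroms = 2, chrom_length = 100000,
                      n_tfs = 6, n_cell_types = 2, n_crms = 20,
                      peaks_per_dataset = 40)
fx <- make_fixture(cfg, "fixture")

st <- run_pipeline(fx$paths$manifest, fx$paths$genome, fx$paths$chrom_sizes,
                   "run", conservation = fx$paths$conservation,
                   truth_crms = fx$ground_truth$crms)
str(st$summary)
```

```
List of 22
 $ datasets_kept          : int 12
 $ datasets_dropped_filter: int 0
 $ covered_bp             : num 66255
 $ datasets_with_motifs   : int 12
 $ motifs                 : int 25
 $ datasets_with_cps      : int 12
 $ cps                    : int 12
 $ cp_motifs              : int 24
 $ clusters               : int 5
 $ ums                    : int 5
 $ network_edges          : int 3
 $ projected_sites        : int 72
 $ crmcs                  : int 27
 $ crmc_bp                : num 4163
 $ non_crmc_bp            : num 62092
 $ tfbs_islands           : int 72
 $ crms_at_p_cutoff       : int 27
 $ expected_fp            : int 10
 $ truth_recall           : num 1
 $ control_recall         : num 0.1
 $ neutrality_crmc        : num 0.0382
 $ neutrality_non_crmc    : num 0.895
```

Reading the summary: all 12 simulated (TF, cell type) datasets pass the
enrichment filter; 25 motifs collapse through CP selection and clustering
into 5 unique motifs; their projected sites link into 27 CRM candidates
covering 4,163 of 66,255 peak-covered bp. Every planted CRM is recalled
by a candidate at p <= 0.05 (`truth_recall = 1`) while length-matched
random controls recall only 10% by chance; candidate positions sit far
outside the neutral conservation band (proportion of neutrality 0.04 vs
0.90 for non-candidates) — the signature expected of genuine regulatory
sequence.

```r
print(st$partition)
#> <GenomePartition> covered=66255 bp, 27 CRMCs (4163 bp), non-CRMC=62092 bp
head(subset(st$partition$crmcs, p_value <= 0.05), 3)
#>     crmc_id chrom start   end n_sites    s_crm p_value
#> 1 CRMC00001  chr1  6649  6957       3 420.9084       0
#> 2 CRMC00002  chr1 29478 29589       3 644.5179       0
#> 3 CRMC00003  chr1 33507 33865       3 185.9096       0
```

The genome-budget calculator chains the semi-theoretic scalar estimates —
false-positive and false-negative corrections, the conservation-derived
density of CRM positions in peak-uncovered regions, and expected CRM /
TFBS-island counts:

```r
budget(budget_inputs(covered_fraction_denom = 0.779))
#> <BudgetEstimates> (printed rounding)
#>   FP fraction of genome:        0.004% (full: 0.0034894%)
#>   true CRMC fraction:           55.496%
#>   FN fraction of genome:        0.39%
#>   FOR of non-CRMCs:             1.6%
#>   true covered CRM fraction:    55.8900%
#>   uncovered/covered density:    54.55%
#>   uncovered CRM fraction:       7.87%
#>   total CRM fraction:           63.7600%
#>   share already predicted:      87.66%
#>   TFBS fraction of genome:      27.35%
#>   expected CRMs:                918010
#>   expected TFBS islands:        43848829
```

A thin command-line wrapper with per-stage subcommands (`simulate`,
`ingest`, `motifs`, ..., `all`) is installed at
`system.file("cli", "crmscout.R", package = "crmscout")`.

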