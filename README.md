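# ntve

Analysis toolkit for **non-destructive transcriptomics via vesicular
export** (NTVE): RNA-seq of transcripts exported from living cells in
membrane vesicles, sampled from the culture supernatant and compared
against conventional cell-lysate controls.

Exported-RNA libraries are scarce-input libraries: they carry PCR
duplicates and low-complexity artifacts, and the poly(A)-binding export
adapter biases fragments toward transcript 3' ends. This package
implements the complete computational chain for such experiments, for
anyone running paired supernatant/lysate RNA-seq:

* **Read filtering** — k-mer complexity filter (pairs dropped when fewer
  than 80% of a mate's k-mer positions are unique within the read), a
  longest-consecutive-mapped-stretch CIGAR check (≥ 80 nt), proper-pair
  enforcement, and exact duplicate-pair removal.
* **3'-anchored coverage** — per-position depth in transcript coordinates,
  area-under-the-curve normalization
  `C'_ij = C_ij / (Σ_m C_mj) · L_j` (normalized coverage averages exactly
  1 per position), metagene aggregation into 10-nt bins up to 3000 nt
  upstream of the transcript end site, and supernatant/lysate coverage
  ratios.
* **Export statistics** — CPM/TPM normalization, log10 export-ratio
  distributions with replicate confidence bands, detection rates across 50
  expression quantiles, length-binned Spearman concordance, replicate CV,
  detection overlap (intersection-over-union), and absolute RNA
  quantification from a known-mass spike-in (mass → molecules →
  per-cell-per-day export rates → mRNAs per particle).
* **NB GLM testing engine** — negative-binomial GLMs
  (`Var = μ + αμ²`, log link, median-of-ratios size-factor offsets) with
  Cox–Reid dispersion estimation and empirical-Bayes moderation;
  likelihood-ratio tests `Λ = 2(ℓ_F − ℓ_R) ~ χ²` for one-vs-rest lineage
  effects, lineage-specific natural-cubic-spline trajectories, and
  spline-vs-constant time courses; interval-null Wald tests
  (`greaterAbs`/`lessAbs` at |log2 FC| = 1); BH correction; adaptive-prior
  fold-change shrinkage.
* **Evaluation** — ground-truth construction from interval tests, ROC/PR
  curves with trapezoidal AUCs, sliding-window differential expression
  (two-day bins, one-day stride), preranked GSEA (weighted running sum,
  permutation null), time-to-peak ordering, and contraction-frequency
  estimation from bright-field intensity traces.
* **Synthetic data** — generators for every input above with full ground
  truth (export ratios, effect classes, spline coefficients), so the whole
  pipeline is testable end to end without any external data.

## Worked example

Simulate a small paired experiment, push reads through the filter, and
compare 3'-anchored coverage between compartments:

```r
library(ntve)

cfg <- simulation_config(n_genes = 300, length_range = c(1000, 5000),
                         three_prime_decay_length = 500, seed = 5)
txo <- simulate_transcriptome(cfg)

rec <- simulate_aligned_reads(cfg, txo$annotations, "supernatant",
                              n_pairs = 30000, sequences = txo$sequences)
filt <- filter_pairs(rec)
str(filt$report)
#> List of 6
#>  $ pairs_in              : int 30000
#>  $ pairs_out             : int 29394
#>  $ dropped_low_complexity: int 606
#>  $ dropped_short_stretch : int 0
#>  $ dropped_improper_pair : int 0
#>  $ dropped_unpaired      : int 0

dedup <- dedup_pairs(filt$records)
prof <- auc_normalize_all(per_position_depth(dedup$records, txo$annotations))
mg <- metagene_3prime(prof, window = 3000, bin_size = 10,
                      group = "supernatant")
```

Every normalized profile averages 1 per position; in the supernatant the
binned mean coverage decays with distance from the 3' end (Spearman trend
≈ −1 beyond one fragment length), while the same pipeline on lysate reads
is flat. The `analysis/` directory holds the full numbered workflow:

| script | what it does | key output |
| --- | --- | --- |
| `01_simulate_data.R` | transcriptome + paired counts + reads | `scratch/sim/` |
| `02_filter_reads.R` | complexity/CIGAR filter + dedup | `results/filter_report.tsv` |
| `03_coverage_profiles.R` | metagene coverage + ratios | `results/metagene_coverage.tsv` |
| `04_export_statistics.R` | export ratios, CV, IoU, spike-in | `results/export_summary.tsv` |
| `05_perturbation_de.R` | interval-null ground truth + ROC/PR | `results/classifier_summary.tsv` |
| `06_lineage_timecourse.R` | one-vs-rest + trajectory LRTs | `results/lineage_tests.tsv` |
| `07_cardiomyocyte_timecourse.R` | time-course LRT, GSEA, contraction | `results/timecourse_lrt.tsv` |

Running `Rscript analysis/05_perturbation_de.R` prints, for example:

```
ground truth: 49 positives, 730 negatives, 21 unlabeled
ROC AUC 0.959, PR AUC 0.962, prevalence 0.063
supernatant-lysate fold-change Pearson r = 0.837 over 800 genes
```

i.e. supernatant fold changes recover the lysate-defined strong responders
almost perfectly on this synthetic perturbation, at a realistic unbalanced
6-vs-3 design.

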