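#!/usr/bin/env Rscript
# Supernatant-vs-lysate summary statistics on the simulated paired counts:
# export-ratio distribution, detection rate by expression quantile,
# replicate CV, detection overlap, and spike-in absolute quantification.

library(ntve)

counts <- read_count_matrix("scratch/sim/paired_counts.tsv")
truth <- read.delim("scratch/sim/paired_truth.tsv", stringsAsFactors = FALSE)
cpm <- cpm_normalize(counts)
sn <- cpm$values[, 1:3]
lys <- cpm$values[, 4:6]

erd <- export_ratio_distribution(sn, lys, min_lysate = 1, bins = 70)
hist_tab <- data.frame(bin_mid = (head(erd$breaks, -1) + tail(erd$breaks, -1)) / 2,
                       mean_density = erd$mean_density,
                       ci_lower = erd$ci_lower, ci_upper = erd$ci_upper)
write.table(hist_tab, "results/export_ratio_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("log10 export ratios: pooled sd %.3f (generator truth %.3f)",
                erd$pooled_sd, sd(truth$log10_export_ratio)))

rates <- detection_rate_by_quantile(lys, sn, n_quantiles = 50,
                                    direction = "desc")
write.table(rates, "results/detection_rate_by_quantile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("detection rate: %.0f%% in the top quantile, %.0f%% in the bottom",
                rates$rate_percent[1], tail(rates$rate_percent, 1)))

cv_sn <- cv_per_gene(sn)
cv_lys <- cv_per_gene(lys)
message(sprintf("median CV: supernatant %.3f, lysate %.3f",
                cv_sn$median_cv, cv_lys$median_cv))

det_sn <- rownames(sn)[rowSums(sn >= 1) == 3]
det_lys <- rownames(lys)[rowSums(lys >= 1) == 3]
ov <- detection_overlap(det_sn, det_lys)
message(sprintf("detected genes: %d shared, %d supernatant-only, %d lysate-only, IoU %.1f%%",
                ov$both, ov$only_a, ov$only_b, ov$iou_percent))

# spike-in absolute quantification from the filtered supernatant alignments
rec <- read_sam("scratch/sim/supernatant.filtered.sam")
ann <- read.delim("scratch/sim/annotations.tsv", stringsAsFactors = FALSE)
spike_id <- ann$transcript_id[ann$is_spikein][1]
n_pairs_spike <- length(unique(rec$query_name[rec$reference_name == spike_id]))
n_pairs_total <- length(unique(rec$query_name))
abs_rna <- spikein_absolute_rna(
  spike_fragments = n_pairs_spike,
  sample_fragments = n_pairs_total - n_pairs_spike,
  config = spikein_config(spike_id = spike_id),
  seeded_cells = 7.5e5,
  particle_monomers = 2.5e9
)
message(sprintf(
  "spike-in: %d of %d fragments -> %.1f pg sample RNA, %.3g molecules, %.0f mRNAs/cell/day, %.1f mRNAs/particle",
  n_pairs_spike, n_pairs_total, abs_rna$sample_rna_pg,
  abs_rna$sample_molecules, abs_rna$per_cell_per_day,
  abs_rna$mrnas_per_particle))
summary_tab <- data.frame(
  metric = c("pooled_log10_ratio_sd", "median_cv_supernatant",
             "median_cv_lysate", "iou_percent", "sample_rna_pg",
             "mrnas_per_particle"),
  value = c(erd$pooled_sd, cv_sn$median_cv, cv_lys$median_cv,
            ov$iou_percent, abs_rna$sample_rna_pg, abs_rna$mrnas_per_particle)
)
write.table(summary_tab, "results/export_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
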