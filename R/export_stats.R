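# Supernatant-vs-lysate summary statistics: depth normalization, export
# ratios, detection rates, length-binned concordance, replicate CV,
# detection overlap, spike-in absolute quantification, and sample QC.

values_of <- function(x) if (inherits(x, "count_matrix")) x$values else as.matrix(x)

#' Counts-per-million normalization
#'
#' Scales each sample to one million, optionally adding a pseudocount after
#' scaling (for log display).
#'
#' @param counts A [count_matrix()] or matrix of raw counts.
#' @param pseudocount Value added after scaling (e.g. `1e-3` for log plots).
#' @return A [count_matrix()] with unit `"CPM"`.
#' @export
cpm_normalize <- function(counts, pseudocount = 0) {
  vals <- values_of(counts)
  cs <- colSums(vals)
  if (any(cs == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(vals)[cs == 0], collapse = ", "))
  }
  cpm <- sweep(vals, 2, cs, "/") * 1e6 + pseudocount
  meta <- if (inherits(counts, "count_matrix")) counts$sample_meta else NULL
  count_matrix(cpm, meta, unit = "CPM")
}

#' Transcripts-per-million from counts and feature lengths
#'
#' Per feature, the length-normalized read rate is scaled so each sample
#' sums to one million.
#'
#' @param counts A [count_matrix()] or matrix of raw counts.
#' @param lengths Per-feature lengths in nt, in row order or named.
#' @return A [count_matrix()] with unit `"TPM"`.
#' @export
tpm_from_counts <- function(counts, lengths) {
  vals <- values_of(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(vals)]
  stopifnot(length(lengths) == nrow(vals), all(lengths > 0))
  rate <- vals / lengths
  cs <- colSums(rate)
  if (any(cs == 0)) stop("sample(s) with zero total rate")
  tpm <- sweep(rate, 2, cs, "/") * 1e6
  meta <- if (inherits(counts, "count_matrix")) counts$sample_meta else NULL
  count_matrix(tpm, meta, unit = "TPM")
}

#' Renormalize a TPM subset back to one million
#'
#' After subselecting features (e.g. protein-coding genes), rescales each
#' sample so the subset sums to one million again.
#'
#' @param tpm A [count_matrix()] (TPM) or matrix, already subset.
#' @return A [count_matrix()] with unit `"TPM"`.
#' @export
renormalize_tpm <- function(tpm) {
  vals <- values_of(tpm)
  cs <- colSums(vals)
  if (any(cs == 0)) stop("sample(s) with zero total TPM after subsetting")
  out <- sweep(vals, 2, cs, "/") * 1e6
  meta <- if (inherits(tpm, "count_matrix")) tpm$sample_meta else NULL
  count_matrix(out, meta, unit = "TPM")
}

#' Export-ratio distribution across replicate pairs
#'
#' Per matched supernatant/lysate replicate pair, the per-gene export ratio
#' is supernatant divided by lysate expression on the log10 scale, after
#' excluding genes whose lysate expression is below `min_lysate`. Ratios are
#' histogrammed as densities on a shared grid; the summary is the per-bin
#' mean density across replicates with a 95% confidence band
#' (mean +/- 1.96 x SEM).
#'
#' @param sn,lys Matrices or [count_matrix()] objects with matched replicate
#'   columns (same order), same features, in CPM or TPM.
#' @param min_lysate Lysate expression threshold; genes below are excluded
#'   (per replicate pair).
#' @param bins Number of histogram bins.
#' @return List with `breaks`, `density` (bins x replicates), `mean_density`,
#'   `ci_lower`, `ci_upper`, `log10_ratios` (list per replicate), and
#'   `pooled_sd` (sd of all retained log10 ratios).
#' @export
export_ratio_distribution <- function(sn, lys, min_lysate = 1, bins = 70) {
  snv <- values_of(sn); lyv <- values_of(lys)
  stopifnot(nrow(snv) == nrow(lyv), ncol(snv) == ncol(lyv))
  nrep <- ncol(snv)
  ratios <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    keep <- lyv[, r] >= min_lysate & snv[, r] > 0
    ratios[[r]] <- log10(snv[keep, r] / lyv[keep, r])
  }
  all_r <- unlist(ratios)
  if (length(all_r) == 0) stop("no gene passed the lysate expression filter")
  breaks <- seq(min(all_r), max(all_r), length.out = bins + 1)
  breaks[1] <- breaks[1] - 1e-9; breaks[bins + 1] <- breaks[bins + 1] + 1e-9
  dens <- vapply(ratios, function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    h$density
  }, numeric(bins))
  dens <- matrix(dens, nrow = bins)
  mean_d <- rowMeans(dens)
  sem <- apply(dens, 1, stats::sd) / sqrt(nrep)
  list(breaks = breaks, density = dens, mean_density = mean_d,
       ci_lower = mean_d - 1.96 * sem, ci_upper = mean_d + 1.96 * sem,
       log10_ratios = ratios, pooled_sd = stats::sd(all_r))
}

#' Detection rate across source-expression quantiles
#'
#' Genes are ranked by aggregated expression in the source compartment
#' (after excluding genes with aggregated expression below `min_source`),
#' split into `n_quantiles` equal-size groups, and the per-quantile
#' detection rate is the percentage of the group's genes detected (value
#' > 0) in all replicates of the target compartment.
#'
#' @param source,target Matrices or [count_matrix()] objects, same features.
#' @param n_quantiles Number of quantile groups.
#' @param direction `"desc"` (highest expression first) or `"asc"`.
#' @param min_source Aggregated-expression inclusion threshold.
#' @return Data.frame with `quantile`, `rate_percent`, `n_genes`.
#' @export
detection_rate_by_quantile <- function(source, target, n_quantiles = 50,
                                       direction = c("desc", "asc"),
                                       min_source = 1) {
  direction <- match.arg(direction)
  sv <- values_of(source); tv <- values_of(target)
  stopifnot(identical(rownames(sv), rownames(tv)))
  agg <- rowSums(sv)
  keep <- agg >= min_source
  agg <- agg[keep]
  detected <- rowSums(tv[keep, , drop = FALSE] > 0) == ncol(tv)
  # stable tie-break by feature id so quantile groups are deterministic
  ord <- order(agg, rownames(sv)[keep],
               decreasing = (direction == "desc"), method = "radix")
  detected <- detected[ord]
  n <- length(detected)
  grp <- ceiling(seq_len(n) / (n / n_quantiles))
  grp <- pmin(grp, n_quantiles)
  rate <- tapply(detected, grp, mean) * 100
  data.frame(quantile = as.integer(names(rate)),
             rate_percent = as.numeric(rate),
             n_genes = as.integer(table(grp)))
}

#' Length-binned supernatant/lysate Spearman correlation
#'
#' Transcripts passing the expression filter in all replicates of both
#' fractions are binned by length; within each bin, the Spearman correlation
#' is computed for every supernatant-replicate x lysate-replicate pair and
#' summarized as mean +/- sd.
#'
#' @param sn,lys Matrices or [count_matrix()] objects (TPM), same features.
#' @param lengths Per-feature lengths (named or in row order).
#' @param bin_edges Length bin edges in nt.
#' @param min_expr Per-replicate inclusion threshold (exclusive >).
#' @return Data.frame with `bin_start`, `bin_end`, `mean_rho`, `sd_rho`,
#'   `n_transcripts`; bins with fewer than 3 transcripts get `NA` rho.
#' @export
length_binned_spearman <- function(sn, lys, lengths,
                                   bin_edges = seq(0, 10000, by = 1000),
                                   min_expr = 1) {
  snv <- values_of(sn); lyv <- values_of(lys)
  stopifnot(identical(rownames(snv), rownames(lyv)))
  if (!is.null(names(lengths))) lengths <- lengths[rownames(snv)]
  keep <- rowSums(snv > min_expr) == ncol(snv) &
    rowSums(lyv > min_expr) == ncol(lyv)
  snv <- snv[keep, , drop = FALSE]; lyv <- lyv[keep, , drop = FALSE]
  lens <- lengths[keep]
  bin <- cut(lens, breaks = bin_edges, right = TRUE)
  out <- lapply(seq_len(length(bin_edges) - 1), function(b) {
    rows <- which(as.integer(bin) == b)
    n_tx <- length(rows)
    if (n_tx < 3) {
      return(data.frame(bin_start = bin_edges[b], bin_end = bin_edges[b + 1],
                        mean_rho = NA_real_, sd_rho = NA_real_,
                        n_transcripts = n_tx))
    }
    rhos <- as.vector(stats::cor(snv[rows, , drop = FALSE],
                                 lyv[rows, , drop = FALSE],
                                 method = "spearman"))
    data.frame(bin_start = bin_edges[b], bin_end = bin_edges[b + 1],
               mean_rho = mean(rhos), sd_rho = stats::sd(rhos),
               n_transcripts = n_tx)
  })
  do.call(rbind, out)
}

#' Per-gene coefficient of variation across replicates
#'
#' CV = sample sd / mean over replicates (denominator n - 1); genes with
#' mean 0 are excluded.
#'
#' @param mat Matrix or [count_matrix()] restricted to one condition's
#'   replicates.
#' @return List with `cv` (named per-gene CV) and `median_cv`.
#' @export
cv_per_gene <- function(mat) {
  vals <- values_of(mat)
  stopifnot(ncol(vals) >= 2)
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  keep <- m > 0
  cv <- s[keep] / m[keep]
  list(cv = cv, median_cv = stats::median(cv))
}

#' Detection overlap between two gene sets
#'
#' @param set_a,set_b Character vectors of detected gene ids.
#' @return List with `both`, `only_a`, `only_b` (counts),
#'   `iou_percent` (intersection-over-union, percent).
#' @export
detection_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- length(intersect(a, b))
  union_n <- length(union(a, b))
  list(both = both,
       only_a = length(a) - both,
       only_b = length(b) - both,
       iou_percent = if (union_n > 0) 100 * both / union_n else NA_real_)
}

#' Spike-in configuration for absolute RNA quantification
#'
#' @param spike_id Spike-in transcript id.
#' @param spike_mass_pg Spiked-in mass in pg.
#' @param mean_mrna_length_nt Assumed average mRNA length.
#' @param divisions_during_culture Assumed cell divisions during culture.
#' @param monomers_per_particle Gag monomers per particle (for converting an
#'   immunoassay monomer count into particles).
#' @param avg_nt_mass_da Average ribonucleotide residue mass in Da.
#' @return A list of class `spikein_config`.
#' @export
spikein_config <- function(spike_id = "SPIKE1", spike_mass_pg = 1,
                           mean_mrna_length_nt = 1500,
                           divisions_during_culture = 2,
                           monomers_per_particle = 2500,
                           avg_nt_mass_da = 340) {
  stopifnot(spike_mass_pg > 0, mean_mrna_length_nt > 0,
            divisions_during_culture >= 0, monomers_per_particle > 0,
            avg_nt_mass_da > 0)
  structure(list(spike_id = spike_id, spike_mass_pg = spike_mass_pg,
                 mean_mrna_length_nt = mean_mrna_length_nt,
                 divisions_during_culture = divisions_during_culture,
                 monomers_per_particle = monomers_per_particle,
                 avg_nt_mass_da = avg_nt_mass_da),
            class = "spikein_config")
}

AVOGADRO <- 6.02214076e23

#' Absolute RNA quantification from a known-mass spike-in
#'
#' The sample RNA mass is the spike mass scaled by the ratio of non-spike to
#' spike fragments. Mass is converted to molecule numbers via the assumed
#' mean mRNA length and average nucleotide residue mass. The per-cell
#' per-day export rate divides molecules by cell-days: with `n0` seeded
#' cells and `d` divisions over the culture, cell-days =
#' `n0 * sum(2^(0:d))` (7 x n0 for two divisions over three days).
#'
#' @param spike_fragments Fragments mapping to the spike-in transcript.
#' @param sample_fragments Fragments mapping to everything else.
#' @param config A [spikein_config()].
#' @param seeded_cells Seeded cell count (for the per-cell per-day rate);
#'   optional.
#' @param particle_monomers Monomer count from an immunoassay (for mRNAs per
#'   particle); optional.
#' @return List with `sample_rna_pg`, `sample_molecules`, and (when inputs
#'   allow) `per_cell_per_day`, `particle_count`, `mrnas_per_particle`.
#' @export
spikein_absolute_rna <- function(spike_fragments, sample_fragments,
                                 config = spikein_config(),
                                 seeded_cells = NULL,
                                 particle_monomers = NULL) {
  if (spike_fragments <= 0) stop("zero spike-in fragments: cannot calibrate")
  sample_rna_pg <- config$spike_mass_pg * sample_fragments / spike_fragments
  mrna_mass_g <- config$mean_mrna_length_nt * config$avg_nt_mass_da / AVOGADRO
  sample_molecules <- sample_rna_pg * 1e-12 / mrna_mass_g
  out <- list(sample_rna_pg = sample_rna_pg,
              sample_molecules = sample_molecules)
  if (!is.null(seeded_cells)) {
    cell_days <- seeded_cells * sum(2^(0:config$divisions_during_culture))
    out$per_cell_per_day <- sample_molecules / cell_days
  }
  if (!is.null(particle_monomers)) {
    out$particle_count <- particle_monomers / config$monomers_per_particle
    out$mrnas_per_particle <- sample_molecules / out$particle_count
  }
  out
}

#' Drop samples below a total-read threshold
#'
#' @param counts A [count_matrix()] or matrix of raw counts.
#' @param min_reads Minimum column sum (inclusive).
#' @return The input with low-depth samples removed; removed sample ids in
#'   the `removed` attribute.
#' @export
filter_samples_by_reads <- function(counts, min_reads = 1e5) {
  vals <- values_of(counts)
  keep <- colSums(vals) >= min_reads
  if (!any(keep)) stop("all samples fall below the read threshold; review it")
  removed <- colnames(vals)[!keep]
  if (inherits(counts, "count_matrix")) {
    out <- count_matrix(vals[, keep, drop = FALSE],
                        counts$sample_meta[keep, , drop = FALSE],
                        unit = counts$unit)
  } else {
    out <- vals[, keep, drop = FALSE]
  }
  attr(out, "removed") <- removed
  out
}
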