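test_that("CPM columns scale to one million with optional pseudocount", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  cpm <- cpm_normalize(m)
  expect_equal(as.numeric(cpm$values), c(250000, 250000, 500000))
  cpm2 <- cpm_normalize(m, pseudocount = 1e-3)
  expect_equal(as.numeric(cpm2$values), c(250000, 250000, 500000) + 1e-3)
  zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "bad"))
  expect_error(cpm_normalize(zero), "bad")
})

test_that("TPM divides by length before scaling and renormalizes subsets", {
  m <- matrix(c(100, 100), 2, 1, dimnames = list(c("short", "long"), "s1"))
  tpm <- tpm_from_counts(m, c(short = 1000, long = 2000))
  expect_equal(as.numeric(tpm$values), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(colSums(tpm$values), c(s1 = 1e6))
  # random matrices: columns always sum to 1e6
  set.seed(51)
  m2 <- matrix(rpois(60, 50) + 1, 20, 3,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  tpm2 <- tpm_from_counts(m2, rep(1500, 20))
  expect_equal(unname(colSums(tpm2$values)), rep(1e6, 3), tolerance = 1e-6)
  sub <- renormalize_tpm(tpm2$values[1:10, ])
  expect_equal(unname(colSums(sub$values)), rep(1e6, 3), tolerance = 1e-6)
})

test_that("export ratios center at zero for identical fractions and filter low lysate", {
  set.seed(52)
  vals <- matrix(rpois(300, 100) + 1, 100, 3,
                 dimnames = list(paste0("g", 1:100), paste0("r", 1:3)))
  erd <- export_ratio_distribution(vals, vals, min_lysate = 1, bins = 70)
  expect_true(all(abs(unlist(erd$log10_ratios)) < 1e-12))
  # low-lysate gene excluded
  lys <- vals; lys[1, ] <- 0.5
  erd2 <- export_ratio_distribution(vals, lys, min_lysate = 1)
  expect_equal(lengths(erd2$log10_ratios), rep(99L, 3))
  expect_error(export_ratio_distribution(vals, vals * 0, min_lysate = 1),
               "filter")
})

test_that("export-ratio spread recovers the generator parameter within 10%", {
  cfg <- simulation_config(n_genes = 5000, export_log10_ratio_sd = 0.5,
                           mito_fraction = 0, seed = 53)
  txo <- simulate_transcriptome(cfg)
  pc <- simulate_paired_counts(cfg, txo$annotations)
  cpm <- cpm_normalize(pc$counts)
  erd <- export_ratio_distribution(cpm$values[, 1:3], cpm$values[, 4:6])
  expect_equal(erd$pooled_sd, 0.5, tolerance = 0.1)
  # CI band encloses the mean density
  expect_true(all(erd$ci_lower <= erd$mean_density + 1e-12))
  expect_true(all(erd$ci_upper >= erd$mean_density - 1e-12))
})

test_that("detection rates are 100% without dropout and fall with induced dropout", {
  set.seed(54)
  src <- matrix(rexp(600, 1 / 50), 200, 3,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:3)))
  src <- src + 1
  rates <- detection_rate_by_quantile(src, src, n_quantiles = 50)
  expect_true(all(rates$rate_percent == 100))
  # knock out the lowest-expressed half in the target
  tgt <- src
  low <- rank(rowSums(src), ties.method = "first") <= 100
  tgt[low, ] <- 0
  rates2 <- detection_rate_by_quantile(src, tgt, n_quantiles = 50,
                                       direction = "desc")
  expect_true(all(rates2$rate_percent[1:20] == 100))
  expect_true(all(rates2$rate_percent[31:50] == 0))
})

test_that("descending and ascending quantile rates mirror each other", {
  set.seed(55)
  src <- matrix(rexp(300, 1 / 50) + 1, 100, 3,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  tgt <- src * matrix(rbinom(300, 1, 0.8), 100, 3)
  desc <- detection_rate_by_quantile(src, tgt, n_quantiles = 50,
                                     direction = "desc")
  asc <- detection_rate_by_quantile(src, tgt, n_quantiles = 50,
                                    direction = "asc")
  expect_equal(desc$rate_percent, rev(asc$rate_percent))
})

test_that("length-binned Spearman is exact for identity and reversal", {
  set.seed(56)
  n <- 60
  base <- rexp(n, 1 / 100) + 2
  # replicates are monotone transforms of one profile: every supernatant x
  # lysate replicate pair is rank-identical
  vals <- cbind(base, base * 2, base + 5)
  dimnames(vals) <- list(paste0("t", 1:n), paste0("s", 1:3))
  lens <- setNames(rep(c(500, 1500, 2500), each = n / 3), rownames(vals))
  res <- length_binned_spearman(vals, vals, lens,
                                bin_edges = c(0, 1000, 2000, 3000))
  expect_equal(res$mean_rho, rep(1, 3))
  expect_equal(res$sd_rho, rep(0, 3))
  expect_equal(res$n_transcripts, rep(20L, 3))
  # anticorrelated bin: rank-reversing transform on one length stratum
  flip <- vals
  flip[1:20, ] <- max(vals) + 10 - vals[1:20, ]
  res2 <- length_binned_spearman(vals, flip, lens,
                                 bin_edges = c(0, 1000, 2000, 3000))
  expect_equal(res2$mean_rho[1], -1)
  expect_equal(res2$mean_rho[2:3], rep(1, 2))
})

test_that("Spearman bins are invariant to monotone transforms", {
  set.seed(57)
  n <- 30
  a <- matrix(rexp(n * 3) + 2, n, 3, dimnames = list(paste0("t", 1:n), NULL))
  b <- matrix(rexp(n * 3) + 2, n, 3, dimnames = list(paste0("t", 1:n), NULL))
  lens <- setNames(rep(500, n), rownames(a))
  r1 <- length_binned_spearman(a, b, lens, bin_edges = c(0, 1000),
                               min_expr = 0)
  r2 <- length_binned_spearman(a^3, exp(b / max(b)) * 10, lens,
                               bin_edges = c(0, 1000), min_expr = 0)
  expect_equal(r1$mean_rho, r2$mean_rho, tolerance = 1e-12)
})

test_that("per-gene CV uses the sample standard deviation and skips zero means", {
  m <- rbind(c(10, 10, 10), c(10, 20, 30), c(0, 0, 0))
  rownames(m) <- c("flat", "var", "zero")
  colnames(m) <- paste0("s", 1:3)
  res <- cv_per_gene(m)
  expect_equal(unname(res$cv["flat"]), 0)
  expect_false("zero" %in% names(res$cv))
  two <- matrix(c(10, 20), 1, 2, dimnames = list("g", c("a", "b")))
  res2 <- cv_per_gene(two)
  expect_equal(unname(res2$cv), sd(c(10, 20)) / 15, tolerance = 1e-12)
  expect_equal(unname(res2$cv), 0.4714045, tolerance = 1e-6)
})

test_that("detection overlap reports set algebra and IoU", {
  res <- detection_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_equal(res$both, 2)
  expect_equal(res$only_a, 1)
  expect_equal(res$only_b, 1)
  expect_equal(res$iou_percent, 50)
  expect_equal(detection_overlap(c("a", "b"), c("a", "b"))$iou_percent, 100)
  expect_equal(detection_overlap("a", "b")$iou_percent, 0)
})

test_that("spike-in mass arithmetic converts fragments to absolute RNA", {
  cfg <- spikein_config(spike_mass_pg = 1, mean_mrna_length_nt = 1500,
                        avg_nt_mass_da = 340)
  res <- spikein_absolute_rna(100, 9900, cfg)
  expect_equal(res$sample_rna_pg, 99)
  # spike fraction 50% -> sample mass equals spike mass
  expect_equal(spikein_absolute_rna(500, 500, cfg)$sample_rna_pg, 1)
  # molecule conversion: mass / (L * m_nt / N_A)
  expect_equal(res$sample_molecules,
               99e-12 / (1500 * 340 / 6.02214076e23), tolerance = 1e-9)
  # monomer count to particles
  res2 <- spikein_absolute_rna(100, 9900, cfg, particle_monomers = 2.5e6)
  expect_equal(res2$particle_count, 1000)
  # cell-days rule: two divisions -> 7 x seeded cells
  res3 <- spikein_absolute_rna(100, 9900, cfg, seeded_cells = 1e6)
  expect_equal(res3$per_cell_per_day, res$sample_molecules / 7e6)
  expect_error(spikein_absolute_rna(0, 100, cfg), "spike")
})

test_that("spike-in quantification is linear in fragment ratio and mass", {
  cfg <- spikein_config()
  base <- spikein_absolute_rna(100, 1000, cfg)$sample_rna_pg
  expect_equal(spikein_absolute_rna(100, 3000, cfg)$sample_rna_pg, 3 * base)
  cfg2 <- spikein_config(spike_mass_pg = 5)
  expect_equal(spikein_absolute_rna(100, 1000, cfg2)$sample_rna_pg, 5 * base)
})

test_that("sample read-count QC keeps the inclusive boundary", {
  m <- matrix(c(99999, 100000), 1, 2,
              dimnames = list("g", c("low", "ok")))
  out <- filter_samples_by_reads(m, min_reads = 1e5)
  expect_equal(colnames(out), "ok")
  expect_equal(attr(out, "removed"), "low")
  expect_error(filter_samples_by_reads(m, min_reads = 1e9), "threshold")
})
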