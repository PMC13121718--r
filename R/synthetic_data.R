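# Synthetic-data generators. Every generator seeds the RNG from its config
# (and restores the caller's RNG state), so identical configs give identical
# data. The full simulation truth (export ratios, effect labels, spline
# coefficients) is always returned next to the data for recovery tests.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the paired supernatant/lysate simulation
#'
#' Defaults describe the study conditions the generator emulates: biological
#' triplicates per compartment, negative-binomial counts with dispersion
#' 0.05, a sharply peaked log10 export-ratio distribution (sd 0.3), strong
#' mitochondrial depletion in the exported fraction (factor 0.01),
#' exponential 3'-positional bias with a 500 nt decay scale, a 1 pg spike-in
#' transcript, and 100 nt paired-end reads.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene (constant integer).
#' @param length_range Transcript length range in nt, `c(min, max)`.
#' @param n_replicates Replicates per compartment.
#' @param mean_library_size Expected reads per sample.
#' @param dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2); a single value shared across genes.
#' @param export_log10_ratio_sd Spread (sd) of the per-gene log10
#'   supernatant/lysate ratio.
#' @param mito_fraction Proportion of genes flagged mitochondrial.
#' @param mito_depletion_factor Multiplier (<= 1) on supernatant means of
#'   mitochondrial genes.
#' @param three_prime_decay_length Exponential scale (nt) of the supernatant
#'   3'-end positional bias.
#' @param spikein_mass_pg Spiked-in RNA mass in pg.
#' @param spikein_read_fraction Fraction of read pairs drawn from the
#'   spike-in transcript.
#' @param duplicate_rate Proportion of read pairs that are exact duplicates.
#' @param lowcomplexity_rate Proportion of read pairs given homopolymer
#'   sequences.
#' @param read_length Read length in nt.
#' @param fragment_length Fragment length in nt (fixed).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              isoforms_per_gene = 1,
                              length_range = c(500, 5000),
                              n_replicates = 3,
                              mean_library_size = 1e6,
                              dispersion = 0.05,
                              export_log10_ratio_sd = 0.3,
                              mito_fraction = 0.01,
                              mito_depletion_factor = 0.01,
                              three_prime_decay_length = 500,
                              spikein_mass_pg = 1,
                              spikein_read_fraction = 0.01,
                              duplicate_rate = 0.05,
                              lowcomplexity_rate = 0.02,
                              read_length = 100,
                              fragment_length = 300,
                              seed = 1L) {
  stopifnot(
    n_genes >= 1, isoforms_per_gene >= 1,
    length(length_range) == 2,
    n_replicates >= 1, mean_library_size > 0, dispersion >= 0,
    export_log10_ratio_sd >= 0,
    mito_fraction >= 0, mito_fraction <= 1,
    mito_depletion_factor >= 0, mito_depletion_factor <= 1,
    three_prime_decay_length > 0, spikein_mass_pg > 0,
    spikein_read_fraction >= 0, spikein_read_fraction <= 1,
    duplicate_rate >= 0, duplicate_rate <= 1,
    lowcomplexity_rate >= 0, lowcomplexity_rate <= 1,
    read_length >= 1, fragment_length >= read_length
  )
  if (length_range[1] > length_range[2]) {
    stop("length_range min exceeds max")
  }
  structure(as.list(environment()), class = "simulation_config")
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  big <- paste(chars, collapse = "")
  substring(big, seq(1L, by = len, length.out = n),
            seq(len, by = len, length.out = n))
}

#' Simulate a transcriptome with annotations
#'
#' Generates `n_genes` genes with `isoforms_per_gene` isoforms each, lengths
#' uniform over `length_range`, a configured fraction of mitochondrial genes,
#' and one designated spike-in transcript appended at the end.
#'
#' @param config A [simulation_config()].
#' @return List with `sequences` (named character vector of transcript
#'   sequences) and `annotations` (data.frame as from [read_gtf()]).
#' @export
simulate_transcriptome <- function(config) {
  with_seed(config$seed, {
    n_tx <- config$n_genes * config$isoforms_per_gene
    gene_idx <- rep(seq_len(config$n_genes), each = config$isoforms_per_gene)
    tx_id <- sprintf("TX%05d", seq_len(n_tx))
    gene_id <- sprintf("G%05d", gene_idx)
    lens <- config$length_range[1] - 1L +
      sample.int(config$length_range[2] - config$length_range[1] + 1L,
                 n_tx, replace = TRUE)
    n_mito <- round(config$mito_fraction * config$n_genes)
    mito_genes <- if (n_mito > 0) sprintf("G%05d", seq_len(n_mito)) else character(0)
    ann <- data.frame(
      transcript_id = tx_id, gene_id = gene_id, gene_symbol = gene_id,
      length = as.integer(lens), biotype = "protein_coding",
      is_mitochondrial = gene_id %in% mito_genes,
      is_spikein = FALSE, stringsAsFactors = FALSE
    )
    spike_len <- min(max(900L, config$length_range[1]), config$length_range[2])
    ann <- rbind(ann, data.frame(
      transcript_id = "SPIKE1", gene_id = "SPIKEG", gene_symbol = "SPIKEG",
      length = as.integer(spike_len), biotype = "spikein",
      is_mitochondrial = FALSE, is_spikein = TRUE, stringsAsFactors = FALSE
    ))
    seqs <- character(nrow(ann))
    for (i in seq_len(nrow(ann))) seqs[i] <- random_dna(1, ann$length[i])
    names(seqs) <- ann$transcript_id
    list(sequences = seqs, annotations = ann)
  })
}

#' Write simulated transcript sequences as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Simulate paired supernatant/lysate gene counts
#'
#' Per gene, a lysate mean is drawn log-uniform; the supernatant mean is the
#' lysate mean times `10^N(0, export_log10_ratio_sd)`, times the
#' mitochondrial depletion factor for mitochondrial genes. Counts are
#' negative binomial with the configured dispersion after scaling each
#' sample's means to its library size.
#'
#' @param config A [simulation_config()].
#' @param annotations Annotations from [simulate_transcriptome()] (the
#'   spike-in transcript is excluded from the count matrix).
#' @return List with `counts` (a [count_matrix()] of genes x samples, with
#'   supernatant then lysate replicates) and `truth` (data.frame of per-gene
#'   lysate mean, log10 export ratio, and mitochondrial flag).
#' @export
simulate_paired_counts <- function(config, annotations) {
  ann <- annotations[!annotations$is_spikein, , drop = FALSE]
  genes <- unique(ann$gene_id)
  is_mito <- tapply(ann$is_mitochondrial, ann$gene_id, any)[genes]
  n <- length(genes)
  with_seed(config$seed + 1L, {
    base_mean <- 10^stats::runif(n, 0, 3)          # relative lysate abundance
    log10_ratio <- stats::rnorm(n, 0, config$export_log10_ratio_sd)
    sn_mean <- base_mean * 10^log10_ratio *
      ifelse(is_mito, config$mito_depletion_factor, 1)
    nrep <- config$n_replicates
    samples <- c(paste0("SN_", seq_len(nrep)), paste0("LYS_", seq_len(nrep)))
    vals <- matrix(0, n, 2 * nrep, dimnames = list(genes, samples))
    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    for (r in seq_len(nrep)) {
      mu_sn <- sn_mean / sum(sn_mean) * config$mean_library_size
      mu_ly <- base_mean / sum(base_mean) * config$mean_library_size
      draw <- function(mu) {
        if (is.finite(size)) stats::rnbinom(n, size = size, mu = mu)
        else stats::rpois(n, mu)
      }
      vals[, r] <- draw(mu_sn)
      vals[, nrep + r] <- draw(mu_ly)
    }
    meta <- data.frame(
      compartment = rep(c("supernatant", "lysate"), each = nrep),
      condition = "baseline",
      replicate = rep(seq_len(nrep), 2),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = genes, lysate_mean = base_mean,
      log10_export_ratio = log10_ratio,
      is_mitochondrial = as.logical(is_mito),
      stringsAsFactors = FALSE
    )
    list(counts = count_matrix(vals, meta), truth = truth)
  })
}

homopolymer <- function(n, len) {
  if (n == 0) return(character(0))
  strrep(sample(c("A", "C", "G", "T"), n, replace = TRUE), len)
}

#' Simulate aligned read pairs for one compartment
#'
#' Fragments are placed on transcripts in transcript coordinates. For the
#' supernatant the fragment 3'-end distance from the transcript 3' terminus
#' is exponential with scale `three_prime_decay_length` (truncated to the
#' transcript); for the lysate placement is uniform. A configured fraction
#' of pairs are exact duplicates, homopolymer (low-complexity) pairs, or
#' spike-in pairs. All records are flagged proper pairs.
#'
#' @param config A [simulation_config()].
#' @param annotations Annotations from [simulate_transcriptome()].
#' @param compartment `"supernatant"` or `"lysate"`.
#' @param n_pairs Number of read pairs to generate.
#' @param sequences Optional named transcript sequences; when supplied, read
#'   sequences are the actual transcript subsequences, otherwise random.
#' @return An `alignment_records` data.frame (two rows per pair).
#' @export
simulate_aligned_reads <- function(config, annotations, compartment,
                                   n_pairs = 10000, sequences = NULL) {
  stopifnot(compartment %in% c("supernatant", "lysate"))
  rl <- config$read_length
  fl <- config$fragment_length
  usable <- annotations$length >= fl
  if (any(!usable)) {
    warning(sum(!usable), " transcript(s) shorter than the fragment length skipped")
  }
  ann <- annotations[usable, , drop = FALSE]
  if (nrow(ann) == 0) stop("no transcript long enough for the fragment length")
  with_seed(config$seed + 2L + (compartment == "supernatant"), {
    spike_ok <- any(ann$is_spikein)
    n_spike <- if (spike_ok) stats::rbinom(1, n_pairs, config$spikein_read_fraction) else 0L
    host <- ann[!ann$is_spikein, , drop = FALSE]
    idx <- c(sample(seq_len(nrow(host)), n_pairs - n_spike, replace = TRUE),
             rep(which(ann$is_spikein)[1], n_spike))
    tx <- c(host$transcript_id[idx[seq_len(n_pairs - n_spike)]],
            rep(ann$transcript_id[ann$is_spikein][1], n_spike))
    len <- c(host$length[idx[seq_len(n_pairs - n_spike)]],
             rep(ann$length[ann$is_spikein][1], n_spike))
    # fragment 3' end distance from the transcript 3' terminus
    if (compartment == "supernatant") {
      d3 <- stats::rexp(n_pairs, rate = 1 / config$three_prime_decay_length)
      d3 <- pmin(floor(d3), len - fl)
    } else {
      d3 <- floor(stats::runif(n_pairs) * (len - fl + 1))
    }
    frag_end <- len - d3                     # 1-based inclusive end
    frag_start <- frag_end - fl + 1L
    pos1 <- as.integer(frag_start)
    pos2 <- as.integer(frag_end - rl + 1L)
    if (is.null(sequences)) {
      seq1 <- random_dna(n_pairs, rl)
      seq2 <- random_dna(n_pairs, rl)
    } else {
      seq1 <- substring(sequences[tx], pos1, pos1 + rl - 1L)
      seq2 <- substring(sequences[tx], pos2, pos2 + rl - 1L)
    }
    n_low <- round(config$lowcomplexity_rate * n_pairs)
    if (n_low > 0) {
      low_idx <- sample(n_pairs, n_low)
      seq1[low_idx] <- homopolymer(n_low, rl)
      seq2[low_idx] <- homopolymer(n_low, rl)
    }
    n_dup <- round(config$duplicate_rate * n_pairs)
    if (n_dup > 0 && n_pairs > n_dup) {
      dup_to <- sample(n_pairs, n_dup)
      dup_from <- sample(setdiff(seq_len(n_pairs), dup_to), n_dup, replace = TRUE)
      seq1[dup_to] <- seq1[dup_from]; seq2[dup_to] <- seq2[dup_from]
      pos1[dup_to] <- pos1[dup_from]; pos2[dup_to] <- pos2[dup_from]
      tx[dup_to] <- tx[dup_from]
    }
    qname <- sprintf("%s_pair%06d", toupper(substr(compartment, 1, 2)),
                     seq_len(n_pairs))
    rec <- data.frame(
      query_name = rep(qname, each = 2),
      is_read1 = rep(c(TRUE, FALSE), n_pairs),
      is_proper_pair = TRUE,
      reference_name = rep(tx, each = 2),
      position = as.integer(rbind(pos1, pos2)),
      cigar = paste0(rl, "M"),
      sequence = as.character(rbind(seq1, seq2)),
      stringsAsFactors = FALSE
    )
    class(rec) <- c("alignment_records", "data.frame")
    rec
  })
}

#' Configuration for the multi-lineage time-course simulation
#'
#' Defaults emulate a trilineage differentiation sampled daily over a week
#' in biological triplicate, with 10% of genes carrying lineage-specific
#' spline-shaped trajectory deviations.
#'
#' @param lineages Lineage labels (>= 2; the first is the "target").
#' @param time_points Sampling times in days (>= 4 distinct values).
#' @param replicates Replicates per lineage and time point.
#' @param fraction_lineage_specific Proportion of genes with nonzero
#'   trajectory-deviation (delta) coefficients in the target lineage.
#' @param spline_effect_size Natural-log amplitude of the delta deviations.
#' @param constant_shift_effect Natural-log amplitude of constant (beta1)
#'   lineage offsets.
#' @param fraction_constant_shift Proportion of genes with a beta1-only
#'   offset (disjoint from the delta genes).
#' @param baseline_mean Baseline expected count.
#' @param dispersion NB dispersion alpha.
#' @param gamma_sd Sd of the shared (gamma) trajectory coefficients; 0 gives
#'   time-constant genes.
#' @param K Spline basis dimension used to generate trajectories.
#' @param seed Integer seed.
#' @return A list of class `timecourse_config`.
#' @export
timecourse_config <- function(lineages = c("endoderm", "mesoderm", "ectoderm"),
                              time_points = 0:6,
                              replicates = 3,
                              fraction_lineage_specific = 0.1,
                              spline_effect_size = 1.5,
                              constant_shift_effect = 1.0,
                              fraction_constant_shift = 0.1,
                              baseline_mean = 500,
                              dispersion = 0.05,
                              gamma_sd = 0.5,
                              K = 4,
                              seed = 1L) {
  stopifnot(length(lineages) >= 2, length(unique(time_points)) >= 4,
            replicates >= 1,
            fraction_lineage_specific >= 0, fraction_lineage_specific <= 1,
            fraction_constant_shift >= 0, fraction_constant_shift <= 1,
            baseline_mean > 0, dispersion >= 0, gamma_sd >= 0, K >= 1)
  if (length(unique(time_points)) < K + 1) {
    stop("fewer distinct time points than the spline basis needs")
  }
  structure(as.list(environment()), class = "timecourse_config")
}

#' Simulate multi-lineage time-course counts with known truth
#'
#' Counts follow a log-linear negative-binomial model: log mean = baseline +
#' beta1 * target-lineage indicator + shared spline trajectory + delta *
#' indicator * spline basis, with delta nonzero only for the designated
#' lineage-specific fraction of genes. The truth table records each gene's
#' effect class (`"delta"`, `"beta1"` or `"null"`).
#'
#' @param config A [timecourse_config()].
#' @param n_genes Number of genes.
#' @return List with `counts` (a [count_matrix()]), `truth` (gene effect
#'   classes and coefficient amplitudes), and `basis` (the spline basis used
#'   for generation).
#' @export
simulate_timecourse_counts <- function(config, n_genes = 1000) {
  with_seed(config$seed + 10L, {
    tt <- rep(rep(config$time_points, each = config$replicates),
              times = length(config$lineages))
    lin <- rep(config$lineages,
               each = length(config$time_points) * config$replicates)
    repl <- rep(rep(seq_len(config$replicates), times = length(config$time_points)),
                times = length(config$lineages))
    L <- as.numeric(lin == config$lineages[1])
    B <- natural_cubic_spline_basis(tt, K = config$K)
    n_s <- length(tt)
    n_delta <- round(config$fraction_lineage_specific * n_genes)
    n_beta1 <- min(round(config$fraction_constant_shift * n_genes),
                   n_genes - n_delta)
    class_vec <- c(rep("delta", n_delta), rep("beta1", n_beta1),
                   rep("null", n_genes - n_delta - n_beta1))
    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    vals <- matrix(0L, n_genes, n_s)
    truth_b1 <- numeric(n_genes)
    truth_delta <- matrix(0, n_genes, config$K)
    gamma_all <- matrix(stats::rnorm(n_genes * config$K, 0, config$gamma_sd),
                        n_genes, config$K)
    for (g in seq_len(n_genes)) {
      b1 <- if (class_vec[g] == "beta1")
        sample(c(-1, 1), 1) * config$constant_shift_effect else 0
      delta <- if (class_vec[g] == "delta")
        stats::rnorm(config$K, 0, config$spline_effect_size) else rep(0, config$K)
      truth_b1[g] <- b1
      truth_delta[g, ] <- delta
      eta <- log(config$baseline_mean) + b1 * L +
        drop(B %*% gamma_all[g, ]) + L * drop(B %*% delta)
      mu <- exp(eta - mean(eta) + log(config$baseline_mean))
      vals[g, ] <- if (is.finite(size)) stats::rnbinom(n_s, size = size, mu = mu)
      else stats::rpois(n_s, mu)
    }
    dimnames(vals) <- list(
      sprintf("G%05d", seq_len(n_genes)),
      sprintf("%s_d%g_r%d", substr(lin, 1, 4), tt, repl)
    )
    meta <- data.frame(lineage = lin, time_days = tt, replicate = repl,
                       compartment = "supernatant", stringsAsFactors = FALSE)
    truth <- data.frame(
      gene_id = rownames(vals), effect_class = class_vec,
      beta1 = truth_b1, stringsAsFactors = FALSE
    )
    truth$delta <- truth_delta
    list(counts = count_matrix(vals, meta), truth = truth, basis = B)
  })
}

#' Simulate a two-condition comparison with known log2 fold changes
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group, length-2 integer (unbalanced
#'   designs supported), reference group first.
#' @param true_lfc Per-gene true log2 fold change (group 2 vs group 1);
#'   recycled to `n_genes`.
#' @param dispersion NB dispersion alpha.
#' @param base_mean Expected baseline count (single value, or per-gene).
#' @param seed Integer seed.
#' @return List with `counts` (a [count_matrix()] with `condition` metadata
#'   `"ref"`/`"alt"`) and `truth` (per-gene true log2 fold change).
#' @export
simulate_two_condition <- function(n_genes, n_per_group, true_lfc = 0,
                                   dispersion = 0.05, base_mean = 500,
                                   seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2))
  true_lfc <- rep_len(true_lfc, n_genes)
  base_mean <- rep_len(base_mean, n_genes)
  with_seed(seed + 20L, {
    n1 <- n_per_group[1]; n2 <- n_per_group[2]
    mu1 <- matrix(base_mean, n_genes, n1)
    mu2 <- matrix(base_mean * 2^true_lfc, n_genes, n2)
    mu <- cbind(mu1, mu2)
    size <- if (dispersion > 0) 1 / dispersion else Inf
    vals <- if (is.finite(size)) {
      matrix(stats::rnbinom(length(mu), size = size, mu = mu), n_genes)
    } else matrix(stats::rpois(length(mu), mu), n_genes)
    dimnames(vals) <- list(sprintf("G%05d", seq_len(n_genes)),
                           c(paste0("ref_", seq_len(n1)), paste0("alt_", seq_len(n2))))
    meta <- data.frame(condition = rep(c("ref", "alt"), c(n1, n2)),
                       replicate = c(seq_len(n1), seq_len(n2)),
                       stringsAsFactors = FALSE)
    list(counts = count_matrix(vals, meta),
         truth = data.frame(gene_id = rownames(vals), true_lfc = true_lfc))
  })
}
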