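# 3'-anchored coverage profiling: dominant-isoform selection, per-position
# depth in transcript coordinates, area-under-the-curve normalization, and
# metagene aggregation relative to the transcript end site (TES).

#' Select dominant isoforms per gene
#'
#' A gene's dominant isoform is the transcript accounting for at least
#' `threshold` of the gene's summed TPM. Genes without such an isoform (and
#' genes with total TPM 0) are absent from the result.
#'
#' @param quant Data.frame as from [read_quant_table()].
#' @param gene_map Named character vector mapping transcript id to gene id.
#' @param threshold Minimum expression share (inclusive).
#' @return Data.frame with columns `gene_id`, `transcript_id`, `share`,
#'   `tpm`.
#' @export
select_dominant_isoforms <- function(quant, gene_map, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  gene <- unname(gene_map[quant$transcript_id])
  if (anyNA(gene)) stop("transcript(s) missing from gene_map: ",
                        quant$transcript_id[is.na(gene)][1])
  total <- tapply(quant$tpm, gene, sum)
  share <- quant$tpm / as.numeric(total[gene])
  hit <- !is.na(share) & share >= threshold & total[gene] > 0
  out <- data.frame(
    gene_id = gene[hit],
    transcript_id = quant$transcript_id[hit],
    share = share[hit],
    tpm = quant$tpm[hit],
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' Per-position read depth on transcripts
#'
#' Depth at position i is the number of records whose reference-consuming
#' CIGAR operations (M, =, X, D, N) span i. Since all reference-consuming
#' operations are contiguous in transcript space, each record covers the
#' interval `[position, position + reference span - 1]`.
#'
#' @param records An `alignment_records` data.frame in transcript
#'   coordinates.
#' @param annotations Annotation data.frame (for transcript lengths).
#' @param transcripts Optional transcript subset (e.g. dominant isoforms or
#'   the most abundant transcripts); default: all annotated transcripts with
#'   at least one record.
#' @return Named list of `coverage_profile` objects (one per transcript):
#'   lists with `transcript_id`, `length`, `depth` (full-length integer
#'   vector, zeros included). Records on unknown transcripts are skipped and
#'   counted in the `n_skipped` attribute.
#' @export
per_position_depth <- function(records, annotations, transcripts = NULL) {
  lens <- stats::setNames(annotations$length, annotations$transcript_id)
  if (is.null(transcripts)) {
    transcripts <- intersect(unique(records$reference_name), names(lens))
  }
  known <- records$reference_name %in% names(lens)
  n_skipped <- sum(!known)
  rec <- records[known & records$reference_name %in% transcripts, , drop = FALSE]
  span <- vapply(rec$cigar, cigar_reference_span, numeric(1), USE.NAMES = FALSE)
  # fast path: uniform CIGARs share one span value
  idx <- split(seq_len(nrow(rec)), rec$reference_name)
  profiles <- lapply(transcripts, function(tx) {
    L <- as.integer(lens[[tx]])
    depth <- integer(L)
    rows <- idx[[tx]]
    if (!is.null(rows)) {
      starts <- pmax(rec$position[rows], 1L)
      ends <- pmin(rec$position[rows] + as.integer(span[rows]) - 1L, L)
      valid <- starts <= ends & starts <= L
      delta <- integer(L + 1L)
      st <- tabulate(starts[valid], nbins = L)
      en <- tabulate(ends[valid] + 1L, nbins = L + 1L)
      delta[seq_len(L)] <- st
      delta <- delta - en
      depth <- cumsum(delta[seq_len(L)])
    }
    structure(list(transcript_id = tx, length = L, depth = depth),
              class = "coverage_profile")
  })
  names(profiles) <- transcripts
  attr(profiles, "n_skipped") <- n_skipped
  profiles
}

#' Area-under-the-curve normalize a coverage profile
#'
#' Each position's depth is divided by the transcript's total depth and
#' rescaled by the transcript length, so the normalized coverage averages
#' exactly 1 per position.
#'
#' @param profile A `coverage_profile` from [per_position_depth()].
#' @return The profile with a `normalized` vector added.
#' @export
auc_normalize <- function(profile) {
  total <- sum(profile$depth)
  if (total <= 0) {
    warning("transcript ", profile$transcript_id,
            " has zero total depth; excluded from normalization")
    return(NULL)
  }
  profile$normalized <- profile$depth / total * profile$length
  profile
}

#' AUC-normalize a list of profiles, dropping zero-depth transcripts
#'
#' @param profiles List of `coverage_profile` objects.
#' @return List of normalized profiles (zero-depth transcripts removed).
#' @export
auc_normalize_all <- function(profiles) {
  out <- lapply(profiles, function(p) suppressWarnings(auc_normalize(p)))
  dropped <- vapply(out, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " zero-depth transcript(s) excluded from normalization")
  }
  out[!dropped]
}

#' 3'-anchored metagene coverage profile
#'
#' Each transcript's normalized coverage is anchored at its 3' terminus
#' (distance 0 = last transcript position) and aggregated into bins over
#' `[0, window)` nt upstream of the TES. Transcripts shorter than the window
#' contribute only to the bins they reach; the per-bin contributing
#' transcript count tracks that dropout.
#'
#' @param profiles List of normalized `coverage_profile` objects (possibly
#'   pooled across replicates).
#' @param window Window size in nt upstream of the TES.
#' @param bin_size Bin width in nt.
#' @param group Label for the profile group (e.g. compartment).
#' @return A `metagene_profile`: list with `bin_start`, `bin_end` (distances
#'   from the TES), `mean_coverage`, `n_transcripts`, `group`.
#' @export
metagene_3prime <- function(profiles, window = 3000, bin_size = 10,
                            group = NA_character_) {
  if (window < bin_size) stop("window smaller than bin_size")
  n_bins <- floor(window / bin_size)
  sums <- numeric(n_bins)
  npos <- numeric(n_bins)       # position-contributions per bin
  n_tx <- integer(n_bins)       # transcripts reaching each bin
  for (p in profiles) {
    if (is.null(p$normalized)) stop("profiles must be AUC-normalized first")
    L <- p$length
    m <- min(L, window)
    # distance d from the TES maps to position L - d
    vals <- p$normalized[L - seq_len(m) + 1L]       # d = 0 .. m-1
    bin <- (seq_len(m) - 1L) %/% bin_size + 1L   # contiguous 1..max(bin)
    nb <- max(bin)
    sums[seq_len(nb)] <- sums[seq_len(nb)] + as.numeric(rowsum(vals, bin))
    npos[seq_len(nb)] <- npos[seq_len(nb)] + tabulate(bin, nbins = nb)
    n_tx[seq_len(nb)] <- n_tx[seq_len(nb)] + 1L
  }
  mean_cov <- ifelse(npos > 0, sums / npos, NA_real_)
  structure(list(
    bin_start = (seq_len(n_bins) - 1L) * bin_size,
    bin_end = seq_len(n_bins) * bin_size,
    mean_coverage = mean_cov,
    n_transcripts = n_tx,
    group = group
  ), class = "metagene_profile")
}

#' Per-bin supernatant/lysate coverage ratio
#'
#' Relative apparent enrichment: the supernatant mean binned coverage
#' divided by the lysate mean binned coverage. Bins with zero or missing
#' lysate coverage are reported as `NA` (undefined), not infinity.
#'
#' @param supernatant,lysate `metagene_profile` objects with identical bin
#'   structure.
#' @return Data.frame with `bin_start`, `bin_end`, `ratio`.
#' @export
coverage_ratio <- function(supernatant, lysate) {
  if (!identical(supernatant$bin_start, lysate$bin_start) ||
      !identical(supernatant$bin_end, lysate$bin_end)) {
    stop("metagene profiles have different bin structures")
  }
  denom <- lysate$mean_coverage
  ratio <- ifelse(!is.na(denom) & denom > 0,
                  supernatant$mean_coverage / denom, NA_real_)
  data.frame(bin_start = supernatant$bin_start,
             bin_end = supernatant$bin_end,
             ratio = ratio)
}
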