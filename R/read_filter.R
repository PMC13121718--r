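# Read-pair quality filter: k-mer complexity, CIGAR mapped-stretch, proper
# pairing, and exact-duplicate removal for name-linked paired alignments.

#' k-mer filter configuration
#'
#' @param k k-mer length. The low-complexity criterion is insensitive to the
#'   exact choice near the default: homopolymer and short-repeat artifacts
#'   fail at any standard short-read k.
#' @param min_unique_fraction Minimum fraction of k-mer positions whose
#'   k-mer occurs exactly once within the read; pairs below are dropped.
#' @param min_mapped_stretch Minimum length (nt) of the longest run of
#'   consecutive mapped CIGAR operations.
#' @param cigar_check_enabled Whether the mapped-stretch check is applied.
#' @return A list of class `kmer_filter_config`.
#' @export
kmer_filter_config <- function(k = 21, min_unique_fraction = 0.8,
                               min_mapped_stretch = 80,
                               cigar_check_enabled = TRUE) {
  stopifnot(k >= 1, min_unique_fraction > 0, min_unique_fraction <= 1,
            min_mapped_stretch >= 0)
  structure(list(k = as.integer(k),
                 min_unique_fraction = min_unique_fraction,
                 min_mapped_stretch = as.integer(min_mapped_stretch),
                 cigar_check_enabled = isTRUE(cigar_check_enabled)),
            class = "kmer_filter_config")
}

#' Fraction of uniquely occurring k-mers in a read
#'
#' All `len - k + 1` overlapping k-mers are extracted and tabulated; the
#' returned value is the proportion of k-mer positions whose k-mer occurs
#' exactly once in the read. Low values flag low-complexity (e.g.
#' homopolymer or short-repeat) sequences.
#'
#' @param sequence Read sequence.
#' @param k k-mer length.
#' @return Proportion in `[0, 1]`. Sequences shorter than `k` return 0 with
#'   a warning (such reads always fail the filter).
#' @export
kmer_unique_fraction <- function(sequence, k = 21) {
  n <- nchar(sequence)
  if (n < k) {
    warning("sequence shorter than k; unique fraction defined as 0")
    return(0)
  }
  npos <- n - k + 1L
  kmers <- substring(sequence, seq_len(npos), seq_len(npos) + k - 1L)
  multi <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  sum(!multi) / npos
}

#' Longest consecutive mapped stretch of a CIGAR string
#'
#' Maximum summed length over maximal runs of mapped operations
#' (M, =, X); any other operation breaks the run.
#'
#' @param cigar CIGAR string (or a parsed op table from [parse_cigar()]).
#' @return Length in nt (0 for an empty CIGAR).
#' @export
longest_mapped_stretch <- function(cigar) {
  ops <- if (is.data.frame(cigar)) cigar else parse_cigar(cigar)
  if (nrow(ops) == 0) return(0L)
  mapped <- ops$op %in% c("M", "=", "X")
  run <- 0L
  best <- 0L
  for (i in seq_len(nrow(ops))) {
    if (mapped[i]) {
      run <- run + ops$len[i]
      if (run > best) best <- run
    } else {
      run <- 0L
    }
  }
  best
}

# vectorized over records; avoids per-record parse_cigar calls for the
# common single-op case
longest_mapped_stretch_vec <- function(cigars) {
  out <- integer(length(cigars))
  simple <- grepl("^[0-9]+M$", cigars)
  out[simple] <- as.integer(sub("M$", "", cigars[simple]))
  for (i in which(!simple)) out[i] <- longest_mapped_stretch(cigars[i])
  out
}

#' Filter read pairs by complexity, mapped stretch and proper pairing
#'
#' A pair is retained iff both mates have a k-mer unique fraction at or
#' above the threshold, both (when the CIGAR check is enabled) have a
#' longest mapped stretch of at least `min_mapped_stretch`, and both are
#' flagged proper pairs. Records without exactly one mate of each kind
#' (by `query_name`) are dropped and counted as unpaired.
#'
#' @param records An `alignment_records` data.frame.
#' @param config A [kmer_filter_config()].
#' @return List with `records` (retained records, original order) and
#'   `report`: `pairs_in`, `pairs_out`, `dropped_low_complexity`,
#'   `dropped_short_stretch`, `dropped_improper_pair`, `dropped_unpaired`.
#'   A pair failing several criteria is counted once per criterion.
#' @export
filter_pairs <- function(records, config = kmer_filter_config()) {
  if (nrow(records) == 0) {
    return(list(records = records,
                report = list(pairs_in = 0L, pairs_out = 0L,
                              dropped_low_complexity = 0L,
                              dropped_short_stretch = 0L,
                              dropped_improper_pair = 0L,
                              dropped_unpaired = 0L)))
  }
  qn <- records$query_name
  tab <- table(qn)
  r1 <- tapply(records$is_read1, qn, sum)
  complete <- names(tab)[tab == 2L & r1[names(tab)] == 1L]
  unpaired <- !(qn %in% complete)
  n_unpaired_reads <- sum(unpaired)
  rec <- records[!unpaired, , drop = FALSE]
  pairs_in <- length(complete)

  frac <- vapply(rec$sequence, function(s) {
    if (nchar(s) < config$k) 0 else kmer_unique_fraction(s, config$k)
  }, numeric(1), USE.NAMES = FALSE)
  ok_kmer <- frac >= config$min_unique_fraction
  ok_cigar <- if (config$cigar_check_enabled) {
    longest_mapped_stretch_vec(rec$cigar) >= config$min_mapped_stretch
  } else rep(TRUE, nrow(rec))
  ok_proper <- rec$is_proper_pair

  pair_ok  <- tapply(ok_kmer & ok_cigar & ok_proper, rec$query_name, all)
  fail_kmer   <- tapply(!ok_kmer, rec$query_name, any)
  fail_cigar  <- tapply(!ok_cigar, rec$query_name, any)
  fail_proper <- tapply(!ok_proper, rec$query_name, any)

  keep <- rec$query_name %in% names(pair_ok)[pair_ok]
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_records", "data.frame")
  list(records = out,
       report = list(pairs_in = pairs_in,
                     pairs_out = sum(pair_ok),
                     dropped_low_complexity = sum(fail_kmer),
                     dropped_short_stretch = sum(fail_cigar),
                     dropped_improper_pair = sum(fail_proper),
                     dropped_unpaired = n_unpaired_reads))
}

#' Remove exact duplicate read pairs
#'
#' Among pairs whose (mate-1 sequence, mate-2 sequence) are identical, only
#' the first encountered (input order) is kept, correcting for PCR
#' amplification excess.
#'
#' @param records An `alignment_records` data.frame of complete pairs.
#' @return List with `records` (retained) and `n_removed` (pairs removed).
#' @export
dedup_pairs <- function(records) {
  if (nrow(records) == 0) return(list(records = records, n_removed = 0L))
  qn <- records$query_name
  first_order <- !duplicated(qn)
  pair_names <- qn[first_order]
  s1 <- s2 <- character(length(pair_names))
  names(s1) <- names(s2) <- pair_names
  is1 <- records$is_read1
  s1[qn[is1]] <- records$sequence[is1]
  s2[qn[!is1]] <- records$sequence[!is1]
  key <- paste(s1[pair_names], s2[pair_names], sep = "|")
  keep_pairs <- pair_names[!duplicated(key)]
  out <- records[qn %in% keep_pairs, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_records", "data.frame")
  list(records = out, n_removed = length(pair_names) - length(keep_pairs))
}
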